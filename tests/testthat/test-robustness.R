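test_that("perfect within/zero across co-clustering gives silhouette 1", {
  # two clusters always recovered in every run
  runs <- rep(list(1:6), 5)
  labs <- rep(list(c(1L, 1L, 1L, 2L, 2L, 2L)), 5)
  st <- accumulate_cocluster(runs, labs, 6)
  s <- silhouette_from_frequency(st, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(unname(s), rep(1, 6))
})

test_that("singleton clusters score 0 and one-cluster input warns", {
  runs <- rep(list(1:4), 3)
  labs <- rep(list(c(1L, 1L, 1L, 2L)), 3)
  st <- accumulate_cocluster(runs, labs, 4)
  s <- silhouette_from_frequency(st, c(1L, 1L, 1L, 2L))
  expect_equal(unname(s[4]), 0)

  expect_warning(
    s1 <- silhouette_from_frequency(st, rep(1L, 4)),
    "fewer than 2 clusters")
  expect_equal(unname(s1), rep(0, 4))
})

test_that("silhouettes equal the brute-force dense computation", {
  set.seed(77)
  for (trial in 1:6) {
    n <- sample(15:60, 1)
    k <- sample(2:4, 1)
    fix <- random_runs_fixture(n, n_runs = 7, size = floor(0.8 * n), k = k)
    st <- accumulate_cocluster(fix$runs, fix$labels, n)
    ref_labels <- sample.int(k, n, replace = TRUE)
    if (length(unique(ref_labels)) < 2) next
    d <- dense_distance_reference(fix$runs, fix$labels, n)
    oracle <- brute_silhouette(d, ref_labels)
    for (bs in c(4L, 1024L)) {
      got <- silhouette_from_frequency(st, ref_labels, block_size = bs)
      expect_equal(unname(got), oracle, tolerance = 1e-12)
    }
  }
})

test_that("five-cell toy store matches the explicit dense silhouette", {
  runs <- list(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L), c(1L, 3L, 4L, 5L))
  labs <- list(c(1L, 1L, 2L, 2L), c(1L, 1L, 1L, 2L), c(1L, 2L, 2L, 2L))
  st <- accumulate_cocluster(runs, labs, 5)
  ref <- c(1L, 1L, 2L, 2L, 2L)
  d <- dense_distance_reference(runs, labs, 5)
  expect_equal(unname(silhouette_from_frequency(st, ref)),
               brute_silhouette(d, ref), tolerance = 1e-12)
})

test_that("per_cluster_scores aggregates by group mean in decreasing-size
           order", {
  sil <- c(1, 1, 1, 0.5, 0.7)
  labels <- c(2L, 2L, 2L, 1L, 1L)
  sc <- per_cluster_scores(sil, labels)
  expect_equal(sc$cluster, c(2L, 1L))      # larger cluster first
  expect_equal(sc$score, c(1, 0.6))
  expect_equal(sc$size, c(3L, 2L))

  set.seed(3)
  sil2 <- runif(30, -1, 1)
  lab2 <- sample.int(4, 30, replace = TRUE)
  sc2 <- per_cluster_scores(sil2, lab2)
  oracle <- tapply(sil2, lab2, mean)
  expect_equal(sc2$score[match(names(oracle), sc2$cluster)],
               as.numeric(oracle))
})

test_that("constant scores give a degenerate point interval", {
  expect_message(
    ci <- bootstrap_median_ci(rep(0.8, 6), n_boot = 1000, seed = 1),
    "falling back to the percentile")
  expect_equal(as.numeric(ci), c(0.8, 0.8, 0.8))
})

test_that("BCa endpoints agree with the boot package oracle", {
  skip_if_not_installed("boot")
  cases <- list(
    c(0.2, 0.4, 0.6, 0.8, 1.0),
    withr::with_seed(10, runif(10, 0.3, 1)),
    withr::with_seed(30, rbeta(30, 5, 2)))
  for (scores in cases) {
    ci <- bootstrap_median_ci(scores, n_boot = 25000, seed = 4)
    expect_identical(attr(ci, "method"), "bca")
    oracle <- withr::with_seed(5, boot_bca_reference(scores, 25000))
    expect_lt(abs(ci["lower"] - oracle[1]), 0.02)
    expect_lt(abs(ci["upper"] - oracle[2]), 0.02)
    expect_true(ci["lower"] <= ci["median"] &&
                  ci["median"] <= ci["upper"])
  }
})

test_that("bootstrap interval is deterministic given the seed and rejects
           empty input", {
  s <- c(0.1, 0.5, 0.9, 0.7)
  expect_identical(bootstrap_median_ci(s, n_boot = 2000, seed = 8),
                   bootstrap_median_ci(s, n_boot = 2000, seed = 8))
  expect_error(bootstrap_median_ci(numeric(0)),
               class = "robustclust_validation_error")
})

test_that("threshold is the maximal CI lower bound and grows monotonically", {
  recs <- tibble::tibble(parameter = c(1, 2, 3),
                         n_clusters = c(3L, 4L, 5L),
                         median = c(0.9, 0.85, 0.7),
                         ci_lower = c(0.85, 0.80, 0.60))
  expect_equal(compute_threshold(recs), 0.85)
  expect_equal(compute_threshold(recs[1, ]), 0.85)
  # adding a record can only raise or keep the threshold
  for (extra in c(0.1, 0.83, 0.99)) {
    recs2 <- rbind(recs, tibble::tibble(parameter = 9, n_clusters = 2L,
                                        median = extra, ci_lower = extra))
    expect_gte(compute_threshold(recs2), compute_threshold(recs))
  }
})

test_that("the decision rule reproduces the hand-enumerated sweep", {
  recs <- tibble::tibble(parameter = c(0.5, 1.0, 2.0),
                         n_clusters = c(3L, 5L, 9L),
                         median = c(0.90, 0.88, 0.70),
                         ci_lower = c(0.85, 0.80, 0.60))
  sel <- select_parameter(recs)
  expect_equal(sel$threshold, 0.85)
  expect_setequal(sel$candidates, c(0.5, 1.0))
  expect_equal(sel$parameter, 1.0)
  expect_equal(sel$n_clusters, 5L)
})

test_that("selection handles singletons, ties, and is stable under removal
           of non-candidates", {
  single <- tibble::tibble(parameter = 0.7, n_clusters = 4L,
                           median = 0.8, ci_lower = 0.75)
  expect_equal(select_parameter(single)$parameter, 0.7)

  tie <- tibble::tibble(parameter = c(1.0, 2.0), n_clusters = c(4L, 4L),
                        median = c(0.9, 0.9), ci_lower = c(0.8, 0.8))
  expect_equal(select_parameter(tie)$parameter, 1.0)   # smallest wins

  recs <- tibble::tibble(parameter = c(0.5, 1.0, 2.0),
                         n_clusters = c(3L, 5L, 9L),
                         median = c(0.90, 0.88, 0.70),
                         ci_lower = c(0.85, 0.80, 0.60))
  sel_full <- select_parameter(recs)
  pruned <- recs[recs$median >= sel_full$threshold, ]
  expect_equal(select_parameter(pruned)$parameter, sel_full$parameter)
  # the selected median always clears the threshold
  chosen <- recs[recs$parameter == sel_full$parameter, ]
  expect_gte(chosen$median, sel_full$threshold)
})
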