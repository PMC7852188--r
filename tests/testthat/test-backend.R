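test_that("preprocess_reduce honours the shape contract and determinism", {
  set.seed(11)
  counts <- matrix(rpois(100 * 30, 5), nrow = 100,
                   dimnames = list(sprintf("c%03d", 1:100),
                                   sprintf("g%02d", 1:30)))
  cfg <- backend_config(n_hvg = 30, n_dims = 10, knn_k = 5)
  red <- preprocess_reduce(counts, cfg)
  expect_s3_class(red, "reduced_space")
  expect_identical(dim(red$coords), c(100L, 10L))
  expect_identical(rownames(red$coords), rownames(counts))
  expect_identical(red$coords, preprocess_reduce(counts, cfg)$coords)
})

test_that("identical expression profiles map to identical coordinates", {
  profile_a <- c(10, 0, 3, 7, 1, 4)
  profile_b <- c(0, 8, 2, 1, 9, 5)
  counts <- rbind(profile_a, profile_a, profile_b, profile_b,
                  profile_a, profile_b)
  rownames(counts) <- paste0("c", 1:6)
  colnames(counts) <- paste0("g", 1:6)
  red <- preprocess_reduce(counts, backend_config(n_hvg = 6, n_dims = 2))
  expect_equal(red$coords[1, ], red$coords[2, ])
  expect_equal(red$coords[2, ], red$coords[5, ])
  expect_equal(red$coords[3, ], red$coords[4, ])
  expect_false(isTRUE(all.equal(red$coords[1, ], red$coords[3, ])))
})

test_that("first-component scores match a dense eigendecomposition", {
  counts <- matrix(c(5, 0, 2, 1,
                     6, 1, 3, 0,
                     0, 7, 1, 4,
                     1, 8, 0, 5,
                     4, 1, 9, 2,
                     2, 2, 8, 3), nrow = 6, byrow = TRUE,
                   dimnames = list(paste0("c", 1:6), paste0("g", 1:4)))
  cfg <- backend_config(n_hvg = 4, n_dims = 2, normalize_total = 100)
  red <- preprocess_reduce(counts, cfg)

  # oracle: standardize the same normalised matrix, eigendecompose its
  # covariance, project
  x <- log1p(counts / rowSums(counts) * 100)
  x <- scale(x)
  ev <- eigen(cov(x), symmetric = TRUE)
  oracle_pc1 <- as.numeric(x %*% ev$vectors[, 1])
  got <- red$coords[, 1]
  agree <- min(max(abs(got - oracle_pc1)), max(abs(got + oracle_pc1)))
  expect_lt(agree, 1e-10)
})

test_that("dimensionality and validity errors are explicit", {
  # every cell identical: all features have zero variance after scaling
  counts <- matrix(rep(c(3, 1, 0, 5, 2), each = 10), nrow = 10,
                   dimnames = list(paste0("c", 1:10), paste0("g", 1:5)))
  expect_error(
    preprocess_reduce(counts, backend_config(n_hvg = 5, n_dims = 4)),
    class = "robustclust_dimensionality_error")
  bad <- counts; bad[1, 1] <- NA
  expect_error(preprocess_reduce(bad, backend_config()),
               class = "robustclust_validation_error")
  neg <- counts; neg[1, 1] <- -3
  expect_error(preprocess_reduce(neg, backend_config()),
               class = "robustclust_validation_error")
})

test_that("graph_cluster separates well-separated blobs and respects the
           resolution limit", {
  set.seed(21)
  coords <- rbind(matrix(rnorm(200 * 10), ncol = 10),
                  matrix(rnorm(200 * 10, mean = 6), ncol = 10))
  truth <- rep(1:2, each = 200)
  labels <- graph_cluster(coords, resolution = 1, knn_k = 15, seed = 3)
  expect_length(labels, 400)
  expect_equal(max(labels), 2)
  expect_true(all(table(labels, truth) %in% c(0, 200)))

  one_blob <- coords[1:200, ]
  low <- graph_cluster(one_blob, resolution = 0.01, knn_k = 10, seed = 3)
  expect_equal(max(low), 1)
})

test_that("graph_cluster is deterministic given a seed and local to the
           subset", {
  set.seed(5)
  coords <- rbind(matrix(rnorm(60 * 3), ncol = 3),
                  matrix(rnorm(60 * 3, 8), ncol = 3),
                  matrix(rnorm(40 * 3, 30), ncol = 3))  # unrelated cells
  sub <- 1:120
  l1 <- graph_cluster(coords, subset = sub, resolution = 1, knn_k = 8,
                      seed = 99)
  l2 <- graph_cluster(coords, subset = sub, resolution = 1, knn_k = 8,
                      seed = 99)
  expect_identical(l1, l2)
  # locality: replace the out-of-subset cells entirely
  coords2 <- coords
  coords2[121:160, ] <- matrix(rnorm(40 * 3, -50), ncol = 3)
  l3 <- graph_cluster(coords2, subset = sub, resolution = 1, knn_k = 8,
                      seed = 99)
  expect_identical(l1, l3)
})

test_that("graph_cluster validates its parameters", {
  coords <- matrix(rnorm(20), ncol = 2)
  expect_error(graph_cluster(coords, resolution = -1, knn_k = 3),
               class = "robustclust_validation_error")
  expect_error(graph_cluster(coords, resolution = 1, knn_k = 15),
               class = "robustclust_parameter_error")
  expect_error(graph_cluster(coords, subset = integer(0), resolution = 1,
                             knn_k = 3),
               class = "robustclust_validation_error")
})

test_that("community detection attains the exhaustive modularity optimum on
           toy graphs", {
  # two triangles joined by a single bridge edge
  g1 <- igraph::make_graph(c(1,2, 2,3, 1,3, 4,5, 5,6, 4,6, 3,4),
                           directed = FALSE)
  # two squares joined by a bridge
  g2 <- igraph::make_graph(c(1,2, 2,3, 3,4, 1,4, 5,6, 6,7, 7,8, 5,8, 4,5),
                           directed = FALSE)
  for (res in c(0.5, 1)) {
    for (g in list(g1, g2)) {
      best <- brute_best_modularity(g, res)
      memb <- withr::with_seed(1, igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity", resolution = res,
        n_iterations = 10)))
      expect_equal(igraph::modularity(g, memb, resolution = res), best$q,
                   tolerance = 1e-12)
    }
  }
})

test_that("run_backend dispatches parameters and enforces the callable
           contract", {
  set.seed(31)
  counts <- matrix(rpois(80 * 40, 5), nrow = 80,
                   dimnames = list(paste0("c", 1:80), paste0("g", 1:40)))
  cfg <- backend_config(n_hvg = 40, n_dims = 10, knn_k = 8)
  red <- preprocess_reduce(counts, cfg)

  via_dispatch <- run_backend(counts, parameter_name = "resolution",
                              parameter_value = 1, base_config = cfg,
                              seed = 4)
  direct <- graph_cluster(red, resolution = 1, knn_k = 8, seed = 4)
  expect_identical(unname(via_dispatch), unname(direct))

  via_dims <- run_backend(counts, parameter_name = "n_dims",
                          parameter_value = 5, base_config = cfg, seed = 4,
                          resolution = 1)
  red5 <- preprocess_reduce(counts, backend_config(n_hvg = 40, n_dims = 5,
                                                   knn_k = 8))
  expect_identical(unname(via_dims),
                   unname(graph_cluster(red5, resolution = 1, knn_k = 8,
                                        seed = 4)))

  constant <- function(x, subset, value, seed) rep(0L, length(subset))
  labs <- run_backend(counts, subset = 1:30, parameter_name = "callable",
                      parameter_value = NULL, backend = constant)
  expect_identical(unname(labs), rep(1L, 30))

  broken <- function(x, subset, value, seed) rep(0L, 2)
  expect_error(run_backend(counts, parameter_name = "callable",
                           backend = broken),
               class = "robustclust_contract_error")
  expect_error(run_backend(counts, parameter_name = "bogus"),
               class = "robustclust_configuration_error")
})
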