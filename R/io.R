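# Readers and writers: 10x-style Matrix Market triplets, dense CSV/TSV
# matrices, label TSVs, and the sweep results directory.

#' Read an expression matrix
#'
#' `mtx10x` expects a directory holding `matrix.mtx(.gz)`,
#' `barcodes.tsv(.gz)` and `features.tsv(.gz)` (or `genes.tsv(.gz)`) in the
#' 10x triplet layout, genes in rows; the matrix is transposed to cells x
#' genes on read.  `csv`/`tsv` expect a dense matrix with cell ids in the
#' first column and gene ids in the header.  Duplicate feature names are
#' made unique by suffixing.
#'
#' @param path Directory (`mtx10x`) or file (`csv`/`tsv`).
#' @param format One of `"mtx10x"`, `"csv"`, `"tsv"`.
#' @return Cells x genes matrix (sparse for `mtx10x`) with cell and gene
#'   ids as dimnames.
#' @export
read_counts <- function(path, format = c("mtx10x", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx10x") {
    find_one <- function(stem) {
      for (f in c(file.path(path, stem), file.path(path, paste0(stem, ".gz")))) {
        if (file.exists(f)) return(f)
      }
      abort(sprintf("no %s(.gz) under %s.", stem, path),
            class = "robustclust_format_error")
    }
    mtx <- Matrix::readMM(find_one("matrix.mtx"))
    barcodes <- read.delim(find_one("barcodes.tsv"), header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    feat_file <- tryCatch(find_one("features.tsv"),
                          error = function(e) find_one("genes.tsv"))
    feat <- read.delim(feat_file, header = FALSE, stringsAsFactors = FALSE)
    feature_names <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
    if (ncol(mtx) != length(barcodes)) {
      abort(sprintf(
        "matrix has %d columns but %d barcodes were read.",
        ncol(mtx), length(barcodes)), class = "robustclust_format_error")
    }
    if (nrow(mtx) != length(feature_names)) {
      abort(sprintf(
        "matrix has %d rows but %d features were read.",
        nrow(mtx), length(feature_names)), class = "robustclust_format_error")
    }
    counts <- Matrix::t(mtx)
    dimnames(counts) <- list(barcodes, make.unique(feature_names))
    counts <- as(counts, "CsparseMatrix")
  } else {
    delim <- if (format == "csv") "," else "\t"
    df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    cell_ids <- as.character(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
    mode(counts) <- "numeric"
    dimnames(counts) <- list(cell_ids, make.unique(colnames(df)[-1]))
  }
  validate_counts(counts, "input matrix")
  counts
}

#' Read/write a cell label TSV
#'
#' Two-column TSV with header `cell_id`, `label`.
#'
#' @param path File path.
#' @return `read_labels`: named vector of labels.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  setNames(df[[2]], as.character(df[[1]]))
}

#' @rdname read_labels
#' @param labels Named label vector.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(tibble(cell_id = names(labels) %||%
                            as.character(seq_along(labels)),
                          label = unname(labels)), path)
  invisible(path)
}

#' Write a sweep results directory
#'
#' Serialises a [cluster_sweep()] result as one directory:
#' `manifest.json` (configuration, seeds, software version),
#' `records.tsv` (per-parameter medians and CIs),
#' `selection.json` (threshold, candidates, selected value),
#' `scores.tsv` (per-cluster robustness scores),
#' `silhouettes.tsv` (per-cell silhouettes and reference labels),
#' `frequency_cluster_means.tsv` (cluster-averaged co-clustering
#' frequencies at the selected value, long form), and, when `plots = TRUE`,
#' `plots/` with the silhouette distribution and co-clustering heatmap.
#'
#' @param sweep A `cluster_sweep`.
#' @param dir Output directory (created if needed).
#' @param plots Also write figure files.
#' @param input Optional description of the input (recorded in the
#'   manifest).
#' @return `dir`, invisibly.
#' @export
write_sweep_results <- function(sweep, dir, plots = TRUE, input = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sel <- sweep$selection

  manifest <- list(
    input = input %||% "in-memory matrix",
    parameter = sweep$parameter,
    grid = sweep$records$parameter,
    reps = sweep$reps, fraction = sweep$fraction,
    n_boot = sweep$n_boot, conf = sweep$conf,
    backend_config = unclass(sweep$config),
    reduce_per_subsample = sweep$reduce_per_subsample,
    seed = sweep$seed, n_cells = sweep$n_cells,
    missing_pairs = sweep$missing_pairs,
    version = sweep$version,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  readr::write_tsv(sweep$records, file.path(dir, "records.tsv"))
  readr::write_tsv(sweep$scores, file.path(dir, "scores.tsv"))
  readr::write_tsv(sweep$silhouettes, file.path(dir, "silhouettes.tsv"))

  jsonlite::write_json(
    list(threshold = sel$threshold, parameter = sel$parameter,
         n_clusters = sel$n_clusters, candidates = sel$candidates,
         records = sweep$records[, c("parameter", "n_clusters", "median",
                                     "ci_lower", "ci_upper", "ci_method")]),
    file.path(dir, "selection.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns")

  cm <- sweep$cluster_means[[as.character(sel$parameter)]]
  readr::write_tsv(
    tibble(cluster_a = rep(rownames(cm), times = ncol(cm)),
           cluster_b = rep(colnames(cm), each = nrow(cm)),
           mean_frequency = as.numeric(cm)),
    file.path(dir, "frequency_cluster_means.tsv"))

  if (plots) {
    pdir <- file.path(dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    try({
      ggplot2::ggsave(file.path(pdir, "silhouette_distribution.png"),
                      plot_silhouette_distribution(sweep),
                      width = 7, height = 5, dpi = 150)
      ggplot2::ggsave(file.path(pdir, "cocluster_heatmap.png"),
                      plot_cocluster_heatmap(sweep),
                      width = 6, height = 5, dpi = 150)
    }, silent = TRUE)
  }
  invisible(dir)
}

#' Read back a sweep results directory
#'
#' @param dir Directory written by [write_sweep_results()].
#' @return List with `records`, `scores`, `silhouettes` tibbles,
#'   `selection` list, and `manifest` list.
#' @export
read_sweep_results <- function(dir) {
  list(
    records = readr::read_tsv(file.path(dir, "records.tsv"),
                              show_col_types = FALSE, progress = FALSE),
    scores = readr::read_tsv(file.path(dir, "scores.tsv"),
                             show_col_types = FALSE, progress = FALSE),
    silhouettes = readr::read_tsv(file.path(dir, "silhouettes.tsv"),
                                  show_col_types = FALSE, progress = FALSE),
    selection = jsonlite::read_json(file.path(dir, "selection.json"),
                                    simplifyVector = TRUE),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE))
}

#' Write a simulated dataset as a 10x-style triplet directory
#'
#' Emits `matrix.mtx`, `barcodes.tsv`, `features.tsv` (genes in rows) plus
#' `truth_labels.tsv`, so simulated data exercise the same readers as real
#' data.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_mtx <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::t(as(as(Matrix::Matrix(sim$counts, sparse = TRUE),
                       "generalMatrix"), "CsparseMatrix"))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sim$counts), file.path(dir, "barcodes.tsv"))
  feat <- colnames(sim$counts)
  writeLines(paste(feat, feat, "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  write_labels(sim$labels, file.path(dir, "truth_labels.tsv"))
  invisible(dir)
}
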