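# Fisher-z functional connectivity over the canonical pair order.

#' Fisher-z connectivity vector of one scan
#'
#' Entry `k` is `atanh(r)` with `r` the Pearson correlation of the region
#' pair `(i, j)` mapped by [pair_index()]. Correlations are clipped to
#' `1 - 1e-12` in absolute value before the transform, so perfectly
#' (anti)correlated pairs yield large finite z values (|z| > 13) rather than
#' infinities. A constant region is an error naming the region — connectivity
#' is undefined there and silent `NaN`s would poison downstream vectors.
#'
#' @param x A `T x R` numeric timeseries matrix with `T >= 3`.
#' @return A numeric vector of length `R(R-1)/2` in canonical pair order.
#' @examples
#' set.seed(1)
#' fc_vector(matrix(rnorm(60), ncol = 3))
#' @export
fc_vector <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 3) {
    abort("fc_vector() needs at least 3 timepoints.",
          class = "fcrepro_parameter_error")
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    abort(paste0("constant timecourse for region(s): ",
                 paste(bad, collapse = ", ")),
          class = "fcrepro_degenerate_region_error")
  }
  r <- upper_pairs(cor(x))
  atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
}

#' Connectivity matrix of a collection (scans by pairs)
#'
#' Computes [fc_vector()] for every scan and stacks them into a
#' `n_scans x P` matrix with `scan_id` row names — the working representation
#' for contrasts, permutation loops and classifiers.
#'
#' @param scans A scan collection.
#' @return A numeric matrix, rows named by `scan_id`.
#' @export
fc_matrix <- function(scans) {
  scans <- validate_collection(scans)
  p <- pair_count(ncol(scans$timeseries[[1]]))
  vs <- vapply(scans$timeseries, fc_vector, numeric(p))
  out <- t(matrix(vs, nrow = p))
  rownames(out) <- scans$scan_id
  out
}

#' Tidy per-pair connectivity table
#'
#' Long format: one row per (scan, pair) with the canonical index, the two
#' region ids, and the Fisher-z connectivity.
#'
#' @param scans A scan collection.
#' @return A tibble with columns `scan_id`, `k`, `roi_i`, `roi_j`, `z`.
#' @export
fc_table <- function(scans) {
  scans <- validate_collection(scans)
  ids <- region_ids(scans)
  idx <- pair_index(length(ids))
  x <- fc_matrix(scans)
  tibble(
    scan_id = rep(scans$scan_id, each = nrow(idx)),
    k = rep(idx$k, times = nrow(scans)),
    roi_i = rep(ids[idx$i], times = nrow(scans)),
    roi_j = rep(ids[idx$j], times = nrow(scans)),
    z = as.vector(t(x))
  )
}

#' Persist / load connectivity tables
#'
#' `write_fc_table()` writes the long format of [fc_table()];
#' `read_fc_matrix()` reconstructs the wide scans-by-pairs matrix from such a
#' file.
#'
#' @param fc A tibble as returned by [fc_table()].
#' @param path TSV file path.
#' @return `read_fc_matrix()` returns a numeric matrix with scan-id rownames.
#' @export
write_fc_table <- function(fc, path) {
  readr::write_tsv(fc, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fc_table
#' @export
read_fc_matrix <- function(path) {
  fc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  wide <- tidyr::pivot_wider(fc[, c("scan_id", "k", "z")],
                             names_from = "k", values_from = "z")
  out <- as.matrix(wide[, -1])
  rownames(out) <- wide$scan_id
  out
}
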