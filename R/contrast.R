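# Mass-univariate NC-vs-PD contrast: Welch t and two-sided p per region
# pair. The sign convention throughout is t > 0 <=> mean FC(NC) > mean
# FC(PD), matching the "FC decrease in PD" reading of positive t.

# Vectorised Welch statistics over the columns of X (samples x pairs).
# g is logical, TRUE for the NC rows. Variances use the two-pass formula
# (centred within group) for accuracy. Zero pooled variance at a pair
# yields t = 0, p = 1 (df NA).
welch_t_stats <- function(x, g) {
  n1 <- sum(g)
  n2 <- sum(!g)
  stopifnot(n1 >= 2, n2 >= 2)
  x1 <- x[g, , drop = FALSE]
  x2 <- x[!g, , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  x1c <- sweep(x1, 2, m1)
  x2c <- sweep(x2, 2, m2)
  v1 <- colSums(x1c * x1c) / (n1 - 1)
  v2 <- colSums(x2c * x2c) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_val <- rep(0, ncol(x))
  df <- rep(NA_real_, ncol(x))
  p <- rep(1, ncol(x))
  ok <- se2 > 0
  t_val[ok] <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df[ok] <- se2[ok]^2 /
    ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * pt(abs(t_val[ok]), df[ok], lower.tail = FALSE)
  list(t = t_val, df = df, p = p, n_nc = n1, n_pd = n2)
}

#' Edgewise Welch contrast between the NC and PD groups
#'
#' Runs an unequal-variance two-sample t-test at every region pair of the
#' collection's Fisher-z connectivity, with scans as samples (each scan one
#' observation; replicate scans pool into their subject's group) or,
#' optionally, subject-mean FC vectors as samples.
#'
#' @param scans A scan collection containing both groups.
#' @param fc Optional precomputed [fc_matrix()] for these scans (rows must
#'   align with `scans`); computed when `NULL`.
#' @param sample_unit `"scan"` (default) treats every scan as a sample;
#'   `"subject_mean"` first averages each subject's FC vectors.
#' @param contrast_label Free-text label (e.g. `"NC-PD"`, `"NC0-PD0"`).
#' @return An object of class `fc_contrast`: per-pair `t`, Welch df, and
#'   two-sided `p`, plus group sizes and dataset id. `tidy()` gives the
#'   per-pair tibble, `glance()` a one-row summary.
#' @examples
#' sim <- simulate_cohort(sim_config(n_regions = 6, n_subjects_nc = 4,
#'                                   n_subjects_pd = 4, n_timepoints = 60))
#' welch_contrast(sim$scans)
#' @export
welch_contrast <- function(scans, fc = NULL,
                           sample_unit = c("scan", "subject_mean"),
                           contrast_label = "NC-PD") {
  scans <- validate_collection(scans)
  sample_unit <- match.arg(sample_unit)
  if (is.null(fc)) fc <- fc_matrix(scans)
  stopifnot(nrow(fc) == nrow(scans))
  group <- scans$group
  if (sample_unit == "subject_mean") {
    agg <- rowsum(fc, group = scans$subject_id) /
      as.vector(table(scans$subject_id))
    subj_group <- scans$group[match(rownames(agg), scans$subject_id)]
    fc <- agg
    group <- subj_group
  }
  g <- group == "NC"
  if (sum(g) < 2 || sum(!g) < 2) {
    abort("welch_contrast() needs at least 2 samples per group.",
          class = "fcrepro_contrast_error")
  }
  st <- welch_t_stats(fc, g)
  ids <- region_ids(scans)
  idx <- pair_index(length(ids))
  structure(list(
    pairs = tibble(k = idx$k, roi_i = ids[idx$i], roi_j = ids[idx$j],
                   t = st$t, df = st$df, p = st$p),
    n_nc = st$n_nc, n_pd = st$n_pd,
    dataset_id = paste(unique(scans$dataset_id), collapse = "+"),
    contrast_label = contrast_label,
    sample_unit = sample_unit
  ), class = "fc_contrast")
}

#' @export
print.fc_contrast <- function(x, ...) {
  cat(sprintf("<fc_contrast> %s on %s: %d NC vs %d PD samples, %d pairs\n",
              x$contrast_label, x$dataset_id, x$n_nc, x$n_pd,
              nrow(x$pairs)))
  print(utils::head(x$pairs), ...)
  invisible(x)
}

#' @export
tidy.fc_contrast <- function(x, ...) x$pairs

#' @export
glance.fc_contrast <- function(x, ...) {
  tibble(dataset_id = x$dataset_id, contrast_label = x$contrast_label,
         n_nc = x$n_nc, n_pd = x$n_pd, n_pairs = nrow(x$pairs),
         min_p = min(x$pairs$p))
}

#' Direction-stratified p-values
#'
#' Restricts a contrast's two-sided p-values to the pairs whose t has the
#' requested sign: `"plus"` keeps pairs with `t > 0` (FC decrease in PD under
#' the NC-minus-PD convention), `"minus"` keeps `t < 0`. Other pairs are
#' marked excluded (`NA`). Pairs with t exactly 0 are excluded from both
#' directions.
#'
#' @param contrast An `fc_contrast`.
#' @param direction `"plus"` or `"minus"`.
#' @return The per-pair tibble with columns `k`, `t`, `p` and `included`
#'   (logical); `p` is `NA` where excluded.
#' @export
directional_p <- function(contrast, direction = c("plus", "minus")) {
  stopifnot(inherits(contrast, "fc_contrast"))
  direction <- match.arg(direction)
  keep <- if (direction == "plus") contrast$pairs$t > 0 else
    contrast$pairs$t < 0
  out <- contrast$pairs[, c("k", "t", "p")]
  out$included <- keep
  out$p[!keep] <- NA_real_
  out
}

#' Persist a contrast as TSV
#' @param contrast An `fc_contrast`.
#' @param path TSV file path.
#' @export
write_contrast <- function(contrast, path) {
  stopifnot(inherits(contrast, "fc_contrast"))
  readr::write_tsv(contrast$pairs, path, progress = FALSE)
  invisible(path)
}
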