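# Cross-dataset edge consistency: for each region pair whose contrast t has
# the same sign in every dataset, the worst (largest) per-dataset p-value;
# the minimum of those max(p) over pairs; and a joint permutation test of
# that minimum.

# Vectorised statistic used both for the observed table and inside the
# permutation loop: t_mat and p_mat are P x K (pairs by datasets).
min_max_p_stat <- function(t_mat, p_mat, direction) {
  keep <- if (direction == "plus") {
    rowSums(t_mat > 0) == ncol(t_mat)
  } else {
    rowSums(t_mat < 0) == ncol(t_mat)
  }
  if (!any(keep)) {
    return(1)
  }
  min(apply(p_mat[keep, , drop = FALSE], 1, max))
}

#' Direction-stratified max(p) table across datasets
#'
#' For each pair whose t-value carries the required sign in *every* contrast,
#' the largest (least significant) of the per-dataset two-sided p-values.
#' Pairs failing the sign condition anywhere are dropped. The table is sorted
#' ascending by `max_p` (ties broken by pair index), so the first row is the
#' edge with the best worst-case significance.
#'
#' @param contrasts A list of [welch_contrast()] results over the same
#'   parcellation (>= 2).
#' @param direction `"plus"` (t > 0 everywhere, FC decrease in PD) or
#'   `"minus"`.
#' @return A tibble with `k`, `roi_i`, `roi_j`, `max_p`, and per-dataset
#'   `p_<id>` / `t_<id>` columns.
#' @export
max_p_table <- function(contrasts, direction = c("plus", "minus")) {
  direction <- match.arg(direction)
  stopifnot(length(contrasts) >= 2,
            all(vapply(contrasts, inherits, logical(1), "fc_contrast")))
  ks <- lapply(contrasts, function(cc) cc$pairs$k)
  if (!all(vapply(ks[-1], identical, logical(1), ks[[1]]))) {
    abort("contrasts do not share the same pair indexing.",
          class = "fcrepro_schema_error")
  }
  t_mat <- vapply(contrasts, function(cc) cc$pairs$t,
                  numeric(nrow(contrasts[[1]]$pairs)))
  p_mat <- vapply(contrasts, function(cc) cc$pairs$p,
                  numeric(nrow(contrasts[[1]]$pairs)))
  ids <- vapply(seq_along(contrasts), function(i) {
    id <- contrasts[[i]]$dataset_id
    if (is.null(id) || id == "") paste0("ds", i) else id
  }, character(1))
  ids <- make.unique(ids)
  keep <- if (direction == "plus") rowSums(t_mat > 0) == ncol(t_mat) else
    rowSums(t_mat < 0) == ncol(t_mat)
  base <- contrasts[[1]]$pairs[keep, c("k", "roi_i", "roi_j")]
  base$max_p <- apply(p_mat[keep, , drop = FALSE], 1, max)
  for (i in seq_along(ids)) {
    base[[paste0("p_", ids[i])]] <- p_mat[keep, i]
  }
  for (i in seq_along(ids)) {
    base[[paste0("t_", ids[i])]] <- t_mat[keep, i]
  }
  base[order(base$max_p, base$k), ]
}

#' Minimum over pairs of the cross-dataset max(p)
#'
#' The scalar summary of [max_p_table()]: the best worst-case significance
#' any single edge achieves across all datasets. An empty retained set (no
#' pair is sign-consistent) yields 1, the most conservative value.
#'
#' @inheritParams max_p_table
#' @return A single p-value-scale number in `(0, 1]`.
#' @export
min_max_p <- function(contrasts, direction = c("plus", "minus")) {
  direction <- match.arg(direction)
  tab <- max_p_table(contrasts, direction)
  if (nrow(tab) == 0) {
    inform("no sign-consistent pair in this direction; min(max(p)) := 1")
    return(1)
  }
  tab$max_p[1]
}

#' Permutation test of min(max(p))
#'
#' The observed `min(max(p))` is biased by the minimum over thousands of
#' edges, so its significance is assessed jointly: the disease labels are
#' permuted independently within each collection (subject level by default),
#' all contrasts recomputed, and the statistic recomputed for the same
#' direction. The p-value is the fraction of permutations whose statistic is
#' <= the observed one (ties count).
#'
#' @param collections A list of >= 2 scan collections over one parcellation.
#' @param direction `"plus"` or `"minus"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed or `NULL`.
#' @param perm_unit `"subject"` or `"scan"`.
#' @return An object of class `fc_consistency` with the ranked observed
#'   table, `min_max_p`, its permutation p-value, and the null sample.
#' @export
consistency_permutation_test <- function(collections,
                                         direction = c("plus", "minus"),
                                         n_perm = 1000, seed = NULL,
                                         perm_unit = c("subject", "scan")) {
  direction <- match.arg(direction)
  perm_unit <- match.arg(perm_unit)
  check_count(n_perm, min = 1)
  stopifnot(length(collections) >= 2)
  samples <- lapply(collections, contrast_samples)
  contrasts <- lapply(seq_along(collections), function(i) {
    welch_contrast(collections[[i]], fc = samples[[i]]$fc)
  })
  ranked <- max_p_table(contrasts, direction)
  obs <- if (nrow(ranked) == 0) 1 else ranked$max_p[1]
  n_pairs <- nrow(contrasts[[1]]$pairs)
  null_sample <- with_seed_if(seed, vapply(seq_len(n_perm), function(it) {
    t_mat <- matrix(0, n_pairs, length(samples))
    p_mat <- matrix(1, n_pairs, length(samples))
    for (i in seq_along(samples)) {
      g <- permute_group(samples[[i]]$subject, samples[[i]]$group, perm_unit)
      st <- welch_t_stats(samples[[i]]$fc, g == "NC")
      t_mat[, i] <- st$t
      p_mat[, i] <- st$p
    }
    min_max_p_stat(t_mat, p_mat, direction)
  }, numeric(1)))
  structure(list(
    direction = direction,
    ranked_pairs = ranked,
    min_max_p = obs,
    p_of_min_max_p = sum(null_sample <= obs) / n_perm,
    n_permutations = n_perm,
    null_sample = null_sample
  ), class = "fc_consistency")
}

#' @export
print.fc_consistency <- function(x, ...) {
  cat(sprintf(
    "<fc_consistency> direction %s: min(max(p)) = %.4g, p = %.4g (N = %d)\n",
    x$direction, x$min_max_p, x$p_of_min_max_p, x$n_permutations))
  cat(sprintf("  %d sign-consistent pair(s)\n", nrow(x$ranked_pairs)))
  invisible(x)
}

#' @export
tidy.fc_consistency <- function(x, ...) x$ranked_pairs

#' @export
glance.fc_consistency <- function(x, ...) {
  tibble(direction = x$direction, min_max_p = x$min_max_p,
         p_of_min_max_p = x$p_of_min_max_p,
         n_retained = nrow(x$ranked_pairs),
         n_permutations = x$n_permutations)
}
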