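# The core statistic: reproducibility R between the t-vectors of two
# group contrasts, its dual-permutation p-value, and the random split engine
# (heterogeneous split-subjects vs homogeneous split-replicates).

#' Reproducibility between two contrast t-vectors
#'
#' The Pearson correlation of two edgewise t-vectors, each viewed as a vector
#' over all region pairs. Values near 1 mean the two datasets (or splits)
#' rank and sign their group differences alike.
#'
#' @param t_a,t_b Numeric vectors of equal length `P >= 3`; typically the
#'   `t` column of two [welch_contrast()] results.
#' @return A single correlation in `[-1, 1]`.
#' @export
reproducibility_r <- function(t_a, t_b) {
  if (length(t_a) != length(t_b) || length(t_a) < 3) {
    abort("t-vectors must have equal length >= 3.",
          class = "fcrepro_parameter_error")
  }
  if (sd(t_a) == 0 || sd(t_b) == 0) {
    abort("reproducibility is undefined for a constant t-vector.",
          class = "fcrepro_degenerate_error")
  }
  cor(t_a, t_b)
}

# Reduce a collection to the sample table used by the permutation engine:
# the FC rows, one group label per row, and the exchangeable-unit id.
contrast_samples <- function(scans, fc = NULL,
                             sample_unit = c("scan", "subject_mean")) {
  sample_unit <- match.arg(sample_unit)
  scans <- validate_collection(scans)
  if (is.null(fc)) fc <- fc_matrix(scans)
  if (sample_unit == "subject_mean") {
    fc <- rowsum(fc, group = scans$subject_id) /
      as.vector(table(scans$subject_id))
    subject <- rownames(fc)
    group <- scans$group[match(subject, scans$subject_id)]
  } else {
    subject <- scans$subject_id
    group <- scans$group
  }
  list(fc = fc, subject = subject, group = group)
}

# One random relabelling of the groups. At subject level all scans of a
# subject move together (the exchangeable unit when replicates exist); at
# scan level each scan is relabelled independently of its siblings.
permute_group <- function(subject, group, perm_unit) {
  if (perm_unit == "scan") {
    return(sample(group))
  }
  subj <- unique(subject)
  subj_group <- group[match(subj, subject)]
  perm <- sample(subj_group)
  perm[match(subject, subj)]
}

#' Permutation p-value of the reproducibility between two collections
#'
#' Computes the observed reproducibility `R` between the NC-vs-PD contrast
#' t-vectors of collections `a` and `b`, then permutes the group labels
#' independently in the two collections `n_perm` times (subject level by
#' default: all scans of a subject carry the same permuted label),
#' recomputing both contrasts and their correlation each time. The p-value
#' is the plain fraction of permutations whose correlation meets or exceeds
#' the observed one, so `p = 0` is attainable; the add-one corrected value
#' `(N p + 1) / (N + 1)` is carried alongside.
#'
#' @param a,b Scan collections with at least 2 scans per group each.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed, or `NULL` to use the ambient RNG stream.
#' @param perm_unit `"subject"` (default) or `"scan"`.
#' @param sample_unit Passed to the contrast; see [welch_contrast()].
#' @param fc_a,fc_b Optional precomputed [fc_matrix()] values.
#' @return An object of class `fc_repro` with the observed `r_value`, the
#'   permutation `p_perm` (and corrected companion), the null sample, and the
#'   two t-vectors. `tidy()` exports the per-pair scatter; `glance()` the
#'   one-row summary; `autoplot()` the t-vs-t scatter-plot.
#' @export
permutation_p <- function(a, b, n_perm = 1000, seed = NULL,
                          perm_unit = c("subject", "scan"),
                          sample_unit = c("scan", "subject_mean"),
                          fc_a = NULL, fc_b = NULL) {
  perm_unit <- match.arg(perm_unit)
  sample_unit <- match.arg(sample_unit)
  check_count(n_perm, min = 1)
  sa <- contrast_samples(a, fc_a, sample_unit)
  sb <- contrast_samples(b, fc_b, sample_unit)
  for (s in list(sa, sb)) {
    if (sum(s$group == "NC") < 2 || sum(s$group == "PD") < 2) {
      abort("each collection needs at least 2 samples per group.",
            class = "fcrepro_contrast_error")
    }
  }
  t_a <- welch_t_stats(sa$fc, sa$group == "NC")$t
  t_b <- welch_t_stats(sb$fc, sb$group == "NC")$t
  r_obs <- reproducibility_r(t_a, t_b)
  null_sample <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
    ga <- permute_group(sa$subject, sa$group, perm_unit)
    gb <- permute_group(sb$subject, sb$group, perm_unit)
    cor(welch_t_stats(sa$fc, ga == "NC")$t,
        welch_t_stats(sb$fc, gb == "NC")$t)
  }, numeric(1)))
  p <- sum(null_sample >= r_obs) / n_perm
  structure(list(
    r_value = r_obs,
    p_perm = p,
    p_perm_corrected = (n_perm * p + 1) / (n_perm + 1),
    n_permutations = n_perm,
    null_sample = null_sample,
    dataset_pair = c(a$dataset_id[1], b$dataset_id[1]),
    perm_unit = perm_unit,
    t_a = t_a,
    t_b = t_b
  ), class = "fc_repro")
}

#' @export
print.fc_repro <- function(x, ...) {
  cat(sprintf(
    "<fc_repro> %s vs %s: R = %.4f, p_perm = %.4g (N = %d, corrected %.4g)\n",
    x$dataset_pair[1], x$dataset_pair[2], x$r_value, x$p_perm,
    x$n_permutations, x$p_perm_corrected))
  invisible(x)
}

#' @export
tidy.fc_repro <- function(x, ...) {
  tibble(k = seq_along(x$t_a), t_a = x$t_a, t_b = x$t_b)
}

#' @export
glance.fc_repro <- function(x, ...) {
  tibble(dataset_a = x$dataset_pair[1], dataset_b = x$dataset_pair[2],
         r_value = x$r_value, p_perm = x$p_perm,
         p_perm_corrected = x$p_perm_corrected,
         n_permutations = x$n_permutations)
}

#' Random split of a collection into two halves
#'
#' Two split modes probe different questions:
#' * `"split_subjects"` (heterogeneous): within each group the subjects are
#'   randomly partitioned into halves of near-equal size (side 1 takes the
#'   extra subject when odd), every subject's scans staying together. Low
#'   reproducibility across such splits signals disease heterogeneity.
#' * `"split_replicates"` (homogeneous): every subject appears on both sides
#'   through disjoint replicate scans (assignment randomised per subject, and
#'   balanced when there are more than two replicates). These halves share
#'   subjects, so only technical noise separates them.
#'
#' @param scans A scan collection; `split_subjects` needs >= 4 subjects per
#'   group, `split_replicates` needs >= 2 replicates for every subject.
#' @param mode `"split_subjects"` or `"split_replicates"`.
#' @param seed Integer seed or `NULL`.
#' @return A list of two scan collections, `side1` and `side2`.
#' @export
make_split <- function(scans, mode = c("split_subjects", "split_replicates"),
                       seed = NULL) {
  mode <- match.arg(mode)
  scans <- validate_collection(scans)
  with_seed_if(seed, {
    if (mode == "split_subjects") {
      side1_subjects <- character()
      for (grp in c("NC", "PD")) {
        subj <- unique(scans$subject_id[scans$group == grp])
        if (length(subj) < 4) {
          abort(sprintf(
            "split_subjects needs >= 4 subjects per group; group %s has %d (%s).",
            grp, length(subj), paste(subj, collapse = ", ")),
            class = "fcrepro_split_error")
        }
        subj <- sample(subj)
        side1_subjects <- c(side1_subjects,
                            subj[seq_len(ceiling(length(subj) / 2))])
      }
      on_side1 <- scans$subject_id %in% side1_subjects
    } else {
      reps <- table(scans$subject_id)
      if (any(reps < 2)) {
        abort(paste0("split_replicates needs >= 2 replicate scans per ",
                     "subject; offending subject(s): ",
                     paste(names(reps)[reps < 2], collapse = ", ")),
              class = "fcrepro_split_error")
      }
      on_side1 <- logical(nrow(scans))
      for (subj in unique(scans$subject_id)) {
        rows <- which(scans$subject_id == subj)
        rows <- sample(rows)
        on_side1[rows[seq_len(ceiling(length(rows) / 2))]] <- TRUE
      }
    }
    list(side1 = scans[on_side1, ], side2 = scans[!on_side1, ])
  })
}

#' Batch of random splits with per-split permutation tests
#'
#' Draws `n_splits` random splits of one collection, runs [permutation_p()]
#' between the halves of each, and aggregates the per-split reproducibility
#' values and p-values into the summaries used to judge heterogeneity: the
#' median `R` and the fraction of splits that fail to reproduce at each
#' `alpha` level.
#'
#' @inheritParams make_split
#' @param n_splits Number of random splits.
#' @param n_perm Permutations per split.
#' @param alpha Non-reproducibility thresholds to summarise (fractions of
#'   splits with `p_perm > alpha`).
#' @param perm_unit Passed to [permutation_p()].
#' @return An object of class `fc_split_batch`; `tidy()` returns the
#'   per-split tibble, `glance()` the summary row, `autoplot()` the
#'   complementary CDF of the per-split p-values and R values.
#' @export
split_batch <- function(scans, mode = c("split_subjects", "split_replicates"),
                        n_splits = 200, n_perm = 1000, seed = NULL,
                        alpha = c(0.01, 0.05),
                        perm_unit = c("subject", "scan")) {
  mode <- match.arg(mode)
  perm_unit <- match.arg(perm_unit)
  check_count(n_splits, min = 1)
  scans <- validate_collection(scans)
  fc <- fc_matrix(scans)
  res <- with_seed_if(seed, {
    purrr::map(seq_len(n_splits), function(i) {
      halves <- make_split(scans, mode, seed = NULL)
      in1 <- scans$scan_id %in% halves$side1$scan_id
      pr <- permutation_p(halves$side1, halves$side2, n_perm = n_perm,
                          seed = NULL, perm_unit = perm_unit,
                          fc_a = fc[in1, , drop = FALSE],
                          fc_b = fc[!in1, , drop = FALSE])
      tibble(split = i, r_value = pr$r_value, p_perm = pr$p_perm)
    })
  })
  splits <- bind_rows(res)
  frac_above <- vapply(alpha, function(a) mean(splits$p_perm > a), numeric(1))
  structure(list(
    mode = mode,
    splits = splits,
    n_splits = n_splits,
    n_perm = n_perm,
    median_r = median(splits$r_value),
    alpha = alpha,
    frac_nonreproducible = stats::setNames(frac_above, paste0("p>", alpha)),
    seed = seed
  ), class = "fc_split_batch")
}

#' @export
print.fc_split_batch <- function(x, ...) {
  cat(sprintf("<fc_split_batch> mode = %s, %d splits x %d permutations\n",
              x$mode, x$n_splits, x$n_perm))
  cat(sprintf("  median R = %.3f\n", x$median_r))
  for (nm in names(x$frac_nonreproducible)) {
    cat(sprintf("  fraction %s: %.3f\n", nm, x$frac_nonreproducible[[nm]]))
  }
  invisible(x)
}

#' @export
tidy.fc_split_batch <- function(x, ...) x$splits

#' @export
glance.fc_split_batch <- function(x, ...) {
  out <- tibble(mode = x$mode, n_splits = x$n_splits, n_perm = x$n_perm,
                median_r = x$median_r)
  for (nm in names(x$frac_nonreproducible)) {
    out[[paste0("frac_", gsub(">", "_gt_", nm))]] <-
      x$frac_nonreproducible[[nm]]
  }
  out
}
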