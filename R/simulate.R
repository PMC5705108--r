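# Synthetic multi-subject cohort generator: the ground-truth engine behind
# every downstream test. Subjects carry a target correlation matrix built
# from a shared low-rank baseline plus (for patients) a subtype effect in
# Fisher-z space plus subject-level z jitter; each replicate scan adds scan-
# level z jitter and samples a multivariate-normal timeseries whose
# stationary cross-region correlation equals the scan target exactly.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic cohort. Defaults are
#' chosen to resemble a modest clinical resting-state cohort: 150 timepoints
#' at TR = 2 s, two replicate scans per subject, disease effects of
#' `delta_z = 0.35` on a small set of edges, and subject/scan variance
#' components of 0.1 / 0.05 on the Fisher-z scale.
#'
#' @param n_regions Number of regions `R`.
#' @param n_timepoints Timepoints `T` per scan.
#' @param tr_seconds Repetition time in seconds.
#' @param n_subjects_nc,n_subjects_pd Subjects per group.
#' @param n_replicates Replicate scans per subject.
#' @param base_structure_rank Latent factor count of the baseline correlation
#'   (see [make_base_correlation()]); default `min(10, n_regions)`.
#' @param effect_pairs Disease effects: a list with one entry per PD subtype,
#'   each a `list(pairs = <canonical pair indices>, delta_z = <signed shift>)`.
#'   An empty list means no group difference.
#' @param subtype_proportions Mixing weights over PD subtypes (must sum to 1);
#'   defaults to equal weights over `effect_pairs`.
#' @param sigma_subject,sigma_scan Standard deviations of the subject- and
#'   replicate-level random effects on off-diagonal Fisher-z entries.
#' @param ar1_coefficient AR(1) coefficient in (-1, 1) for optional temporal
#'   autocorrelation; 0 gives temporally white series.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param base_seed Seed of the baseline correlation matrix only (defaults to
#'   `seed`). Give several datasets the same `base_seed`, `effect_pairs` and
#'   distinct `seed`s to emulate independent cohorts drawn from one
#'   underlying connectome.
#' @param dataset_id Identifier stamped on every scan.
#' @return A validated list of class `fc_sim_config`.
#' @export
sim_config <- function(n_regions = 90, n_timepoints = 150, tr_seconds = 2,
                       n_subjects_nc = 15, n_subjects_pd = 15,
                       n_replicates = 2, base_structure_rank = NULL,
                       effect_pairs = list(),
                       subtype_proportions = NULL,
                       sigma_subject = 0.1, sigma_scan = 0.05,
                       ar1_coefficient = 0, seed = 1, base_seed = NULL,
                       dataset_id = "sim") {
  check_count(n_regions, min = 2)
  check_count(n_timepoints, min = 3)
  check_scalar(tr_seconds, lower = 1e-12)
  check_count(n_subjects_nc, min = 1)
  check_count(n_subjects_pd, min = 1)
  check_count(n_replicates, min = 1)
  if (is.null(base_structure_rank)) {
    base_structure_rank <- min(10L, n_regions)
  }
  check_count(base_structure_rank, min = 1)
  if (base_structure_rank > n_regions) {
    abort("`base_structure_rank` must not exceed `n_regions`.",
          class = "fcrepro_parameter_error")
  }
  check_scalar(sigma_subject, lower = 0)
  check_scalar(sigma_scan, lower = 0)
  check_scalar(ar1_coefficient, lower = -1 + 1e-9, upper = 1 - 1e-9)
  p_max <- pair_count(n_regions)
  if (!is.list(effect_pairs)) {
    abort("`effect_pairs` must be a list of list(pairs=, delta_z=) entries.",
          class = "fcrepro_parameter_error")
  }
  for (ef in effect_pairs) {
    if (!is.list(ef) || is.null(ef$pairs) || is.null(ef$delta_z)) {
      abort("each `effect_pairs` entry needs `pairs` and `delta_z`.",
            class = "fcrepro_parameter_error")
    }
    if (length(ef$pairs) && (min(ef$pairs) < 1 || max(ef$pairs) > p_max)) {
      abort(sprintf("effect pair indices must lie in 1..%d.", p_max),
            class = "fcrepro_parameter_error")
    }
    check_scalar(ef$delta_z, what = "delta_z")
  }
  n_sub <- length(effect_pairs)
  if (is.null(subtype_proportions)) {
    subtype_proportions <- if (n_sub > 0) rep(1 / n_sub, n_sub) else numeric()
  }
  if (n_sub > 0) {
    if (length(subtype_proportions) != n_sub ||
        abs(sum(subtype_proportions) - 1) > 1e-9 ||
        any(subtype_proportions < 0)) {
      abort("`subtype_proportions` must be nonnegative and sum to 1.",
            class = "fcrepro_parameter_error")
    }
  }
  structure(list(
    n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = as.numeric(tr_seconds),
    n_subjects_nc = as.integer(n_subjects_nc),
    n_subjects_pd = as.integer(n_subjects_pd),
    n_replicates = as.integer(n_replicates),
    base_structure_rank = as.integer(base_structure_rank),
    effect_pairs = effect_pairs,
    subtype_proportions = as.numeric(subtype_proportions),
    sigma_subject = as.numeric(sigma_subject),
    sigma_scan = as.numeric(sigma_scan),
    ar1_coefficient = as.numeric(ar1_coefficient),
    seed = as.integer(seed),
    base_seed = as.integer(base_seed %||% seed),
    dataset_id = as.character(dataset_id)
  ), class = "fc_sim_config")
}

#' Draw a random set of affected edges
#'
#' Convenience builder for one `effect_pairs` entry: `n_pairs` distinct
#' canonical pair indices drawn uniformly, all shifted by the same `delta_z`.
#'
#' @inheritParams pair_index
#' @param n_pairs Number of affected edges.
#' @param delta_z Signed Fisher-z shift shared by the edges.
#' @param seed Integer seed.
#' @return A `list(pairs = , delta_z = )` suitable for [sim_config()].
#' @export
sample_effect_pairs <- function(n_regions, n_pairs = 20, delta_z = 0.35,
                                seed = 1) {
  p <- pair_count(n_regions)
  check_count(n_pairs, min = 1)
  if (n_pairs > p) {
    abort("`n_pairs` exceeds the number of region pairs.",
          class = "fcrepro_parameter_error")
  }
  pairs <- with_seed_if(seed, sort(sample.int(p, n_pairs)))
  list(pairs = pairs, delta_z = delta_z)
}

# Sample n x R rows from N(0, C); eigen square root tolerates the exactly
# semidefinite targets the repair projection can produce.
rmvn_corr <- function(n, corr_mat) {
  e <- eigen(corr_mat, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  root <- e$vectors %*% (sqrt(vals) * t(e$vectors))
  matrix(rnorm(n * nrow(corr_mat)), nrow = n) %*% root
}

# AR(1) recursion that preserves the cross-region correlation target in
# stationarity: innovations are already correlated, filtering is per region.
ar1_filter <- function(x, phi) {
  if (phi == 0) return(x)
  scale <- sqrt(1 - phi^2)
  out <- x
  for (t in 2:nrow(x)) {
    out[t, ] <- phi * out[t - 1, ] + scale * x[t, ]
  }
  out
}

#' Simulate a synthetic scan collection with known ground truth
#'
#' Generates one dataset of NC and PD subjects with `n_replicates` scans each,
#' per the hierarchy described in [sim_config()]. Patients are assigned to a
#' subtype by the configured proportions; their target correlation matrix is
#' the baseline shifted in Fisher-z space at that subtype's edges. Subject-
#' and scan-level Gaussian jitter on the z scale (repaired to valid
#' correlation matrices) provides the variance components that the
#' split-subjects / split-replicates analyses exploit.
#'
#' @param config A [sim_config()].
#' @return A list of class `fc_simulation` with elements
#'   * `scans`: a scan-collection tibble (one row per scan; metadata columns
#'     plus a `timeseries` list-column of `T x R` matrices),
#'   * `truth`: a list with `subtypes` (tibble subject_id/subtype),
#'     `effects` (tibble subtype/k/delta_z over truly affected pairs), and
#'     `scan_targets` (named list of per-scan target correlation matrices).
#' @examples
#' sim <- simulate_cohort(sim_config(n_regions = 8, n_subjects_nc = 3,
#'                                   n_subjects_pd = 3, n_timepoints = 40))
#' sim$scans
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "fc_sim_config")) {
    abort("`config` must come from sim_config().",
          class = "fcrepro_parameter_error")
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    base <- make_base_correlation(cfg$n_regions, cfg$base_structure_rank,
                                  seed = cfg$base_seed)
    n_sub <- length(cfg$effect_pairs)
    subtype_targets <- c(
      list(base),
      lapply(cfg$effect_pairs, function(ef) {
        apply_effect_in_z(base, ef$pairs, ef$delta_z)
      })
    )
    subjects <- tibble(
      subject_id = c(sprintf("NC%02d", seq_len(cfg$n_subjects_nc)),
                     sprintf("PD%02d", seq_len(cfg$n_subjects_pd))),
      group = rep(c("NC", "PD"), c(cfg$n_subjects_nc, cfg$n_subjects_pd))
    )
    subjects$subtype <- ifelse(subjects$group == "NC", 0L, NA_integer_)
    n_pd <- cfg$n_subjects_pd
    subjects$subtype[subjects$group == "PD"] <- if (n_sub > 0) {
      sample.int(n_sub, n_pd, replace = TRUE, prob = cfg$subtype_proportions)
    } else {
      rep(0L, n_pd)
    }
    region_ids <- as.character(seq_len(cfg$n_regions))
    rows <- vector("list", nrow(subjects) * cfg$n_replicates)
    targets <- vector("list", length(rows))
    target_names <- character(length(rows))
    idx <- 0L
    for (s in seq_len(nrow(subjects))) {
      subj_target <- subtype_targets[[subjects$subtype[s] + 1L]]
      subj_target <- perturb_correlation_z(subj_target, cfg$sigma_subject)
      for (rep_i in seq_len(cfg$n_replicates)) {
        idx <- idx + 1L
        scan_target <- perturb_correlation_z(subj_target, cfg$sigma_scan)
        x <- rmvn_corr(cfg$n_timepoints, scan_target)
        x <- ar1_filter(x, cfg$ar1_coefficient)
        colnames(x) <- region_ids
        scan_id <- sprintf("%s_%s_s%d", cfg$dataset_id,
                           subjects$subject_id[s], rep_i)
        rows[[idx]] <- tibble(
          scan_id = scan_id,
          subject_id = subjects$subject_id[s],
          group = subjects$group[s],
          dataset_id = cfg$dataset_id,
          replicate_index = rep_i,
          low_motion = TRUE,
          tr_seconds = cfg$tr_seconds,
          timeseries = list(x)
        )
        targets[[idx]] <- scan_target
        target_names[idx] <- scan_id
      }
    }
    names(targets) <- target_names
    effects <- if (n_sub > 0) {
      bind_rows(lapply(seq_len(n_sub), function(i) {
        tibble(subtype = i, k = as.integer(cfg$effect_pairs[[i]]$pairs),
               delta_z = cfg$effect_pairs[[i]]$delta_z)
      }))
    } else {
      tibble(subtype = integer(), k = integer(), delta_z = numeric())
    }
    structure(list(
      scans = validate_collection(bind_rows(rows)),
      truth = list(
        subtypes = subjects[, c("subject_id", "group", "subtype")],
        effects = effects,
        base_correlation = base,
        scan_targets = targets
      ),
      config = cfg
    ), class = "fc_simulation")
  })
}
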