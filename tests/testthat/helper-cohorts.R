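# Small cohort builders shared across test files.

tiny_cohort <- function(seed = 1, n_regions = 8, nc = 4, pd = 4,
                        n_replicates = 2, n_timepoints = 60,
                        effect_pairs = list(), dataset_id = "tiny", ...) {
  simulate_cohort(sim_config(
    n_regions = n_regions, n_timepoints = n_timepoints,
    n_subjects_nc = nc, n_subjects_pd = pd, n_replicates = n_replicates,
    effect_pairs = effect_pairs, seed = seed, dataset_id = dataset_id, ...
  ))
}

# Build a scan-collection tibble directly from a list of matrices, for tests
# that need exact control over the values.
manual_collection <- function(mats, group, subject_id = NULL,
                              dataset_id = "manual", tr = 2) {
  n <- length(mats)
  subject_id <- subject_id %||% sprintf("S%02d", seq_len(n))
  mats <- lapply(mats, function(m) {
    if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
    m
  })
  reps <- stats::ave(seq_len(n), subject_id, FUN = seq_along)
  tibble::tibble(
    scan_id = sprintf("%s_scan%02d", dataset_id, seq_len(n)),
    subject_id = subject_id,
    group = group,
    dataset_id = dataset_id,
    replicate_index = as.integer(reps),
    low_motion = TRUE,
    tr_seconds = tr,
    timeseries = mats
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force enumeration oracle for the canonical upper-triangle order
upper_pairs_oracle <- function(m) {
  out <- numeric(0)
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):ncol(m)) out <- c(out, m[i, j])
  }
  out
}

# textbook Welch t-test computed long-hand on two samples
welch_oracle <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_val <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t_val, df = df, p = 2 * stats::pt(abs(t_val), df,
                                             lower.tail = FALSE))
}
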