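test_that("make_base_correlation yields valid, deterministic correlation matrices", {
  c2 <- make_base_correlation(2, rank = 1, seed = 99)
  expect_equal(diag(c2), c(1, 1))
  expect_lt(abs(c2[1, 2]), 1)

  c5 <- make_base_correlation(5, rank = 5, seed = 1)
  expect_gte(min(eigen(c5, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)

  c90 <- make_base_correlation(90, rank = 10, seed = 7)
  expect_identical(c90, t(c90))
  expect_true(all(abs(c90[upper.tri(c90)]) < 1))

  expect_identical(make_base_correlation(20, 3, seed = 5),
                   make_base_correlation(20, 3, seed = 5))
  expect_error(make_base_correlation(5, 6, seed = 1),
               class = "fcrepro_parameter_error")
})

test_that("apply_effect_in_z shifts exactly in z-space and repairs validity", {
  c0 <- make_base_correlation(4, 2, seed = 2)
  expect_identical(apply_effect_in_z(c0, pairs = c(1, 3), delta_z = 0), c0)

  ident <- diag(3)
  shifted <- apply_effect_in_z(ident, pairs = 1, delta_z = 0.3)
  expect_equal(shifted[1, 2], tanh(0.3), tolerance = 1e-12)

  # push a 3x3 matrix into invalidity; the repaired result must be PSD
  c3 <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  out <- apply_effect_in_z(c3, pairs = 1, delta_z = 1)
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(out), rep(1, 3))

  degen <- diag(2)
  degen[1, 2] <- degen[2, 1] <- 1
  expect_error(apply_effect_in_z(degen, pairs = 1, delta_z = 0.1),
               class = "fcrepro_degenerate_error")
})

test_that("nearest_correlation projects an indefinite matrix onto a valid one", {
  m <- matrix(c(1, 0.95, -0.95, 0.95, 1, 0.95, -0.95, 0.95, 1), 3, 3)
  expect_lt(min(eigen(m, only.values = TRUE)$values), 0)
  out <- nearest_correlation(m)
  expect_gte(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(diag(out), rep(1, 3))
  # idempotent on an already-valid matrix
  c0 <- make_base_correlation(6, 3, seed = 4)
  expect_equal(nearest_correlation(c0), c0, tolerance = 1e-7)
})

test_that("simulate_cohort produces the declared cohort structure", {
  sim <- tiny_cohort(seed = 2, nc = 4, pd = 4, n_replicates = 2)
  scans <- sim$scans
  expect_equal(nrow(scans), 16)
  expect_equal(as.vector(table(scans$group)), c(8, 8))
  reps <- tapply(scans$replicate_index, scans$subject_id, sort)
  expect_true(all(vapply(reps, identical, logical(1), c(1L, 2L))))

  # two disjoint subtypes partition the patients
  ef <- list(list(pairs = 1:3, delta_z = 0.4),
             list(pairs = 4:6, delta_z = 0.4))
  sim2 <- tiny_cohort(seed = 9, nc = 4, pd = 10, effect_pairs = ef)
  subtype <- sim2$truth$subtypes
  expect_equal(sum(subtype$subtype[subtype$group == "PD"] %in% 1:2), 10)
  expect_true(all(subtype$subtype[subtype$group == "NC"] == 0))
})

test_that("identical configurations reproduce bit-identical cohorts", {
  cfg <- sim_config(n_regions = 6, n_timepoints = 30, n_subjects_nc = 2,
                    n_subjects_pd = 2, seed = 123,
                    effect_pairs = list(list(pairs = 1:2, delta_z = 0.3)))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$scans$timeseries, s2$scans$timeseries)
  expect_identical(s1$truth, s2$truth)
})

test_that("scan targets are valid correlation matrices", {
  sim <- tiny_cohort(seed = 31, n_regions = 10, nc = 2, pd = 2,
                     sigma_subject = 0.2, sigma_scan = 0.1,
                     effect_pairs = list(list(pairs = 1:5, delta_z = 0.5)))
  for (tg in sim$truth$scan_targets) {
    expect_equal(diag(tg), rep(1, 10))
    expect_gte(min(eigen(tg, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("AR(1) filtering preserves the cross-region correlation target", {
  sim <- simulate_cohort(sim_config(
    n_regions = 4, n_timepoints = 30000, n_subjects_nc = 1,
    n_subjects_pd = 1, n_replicates = 1, sigma_subject = 0, sigma_scan = 0,
    ar1_coefficient = 0.6, seed = 77
  ))
  x <- sim$scans$timeseries[[1]]
  target <- sim$truth$scan_targets[[1]]
  expect_lt(max(abs(cor(x) - target)), 0.04)
  # and the series really is autocorrelated
  expect_gt(cor(x[-1, 1], x[-nrow(x), 1]), 0.4)
})

test_that("planted effects surface in downstream group t-values", {
  ef <- sample_effect_pairs(12, n_pairs = 20, delta_z = 0.5, seed = 4)
  sim <- simulate_cohort(sim_config(
    n_regions = 12, n_timepoints = 150, n_subjects_nc = 20,
    n_subjects_pd = 20, n_replicates = 1, sigma_subject = 0.05,
    sigma_scan = 0.05, effect_pairs = list(ef), seed = 21
  ))
  ct <- welch_contrast(sim$scans)
  affected <- ct$pairs$k %in% ef$pairs
  wt <- stats::wilcox.test(abs(ct$pairs$t[affected]),
                           abs(ct$pairs$t[!affected]),
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  # NC - PD convention: positive delta_z raises PD connectivity, so t < 0
  expect_lt(mean(ct$pairs$t[affected]), 0)
})

test_that("subtype mixing attenuates pooled-group t-values", {
  ef1 <- list(pairs = 1:10, delta_z = 0.5)
  ef2 <- list(pairs = 21:30, delta_z = 0.5)
  homo <- simulate_cohort(sim_config(
    n_regions = 12, n_timepoints = 150, n_subjects_nc = 16,
    n_subjects_pd = 16, n_replicates = 1, effect_pairs = list(ef1),
    seed = 8, base_seed = 100
  ))
  mixed <- simulate_cohort(sim_config(
    n_regions = 12, n_timepoints = 150, n_subjects_nc = 16,
    n_subjects_pd = 16, n_replicates = 1,
    effect_pairs = list(ef1, ef2), seed = 8, base_seed = 100
  ))
  t_homo <- welch_contrast(homo$scans)$pairs$t
  t_mixed <- welch_contrast(mixed$scans)$pairs$t
  expect_gt(mean(abs(t_homo[ef1$pairs])), mean(abs(t_mixed[ef1$pairs])))
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(subtype_proportions = c(0.5, 0.6),
                          effect_pairs = list(list(pairs = 1, delta_z = 0.1),
                                              list(pairs = 2, delta_z = 0.1))),
               class = "fcrepro_parameter_error")
  expect_error(sim_config(n_regions = 4,
                          effect_pairs = list(list(pairs = 7, delta_z = 0.1))),
               class = "fcrepro_parameter_error")
  expect_error(sim_config(ar1_coefficient = 1),
               class = "fcrepro_parameter_error")
})
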