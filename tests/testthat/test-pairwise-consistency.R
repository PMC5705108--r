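# builds an fc_contrast by hand for table-level tests
fake_contrast <- function(t_vals, p_vals, id) {
  structure(list(
    pairs = tibble::tibble(k = seq_along(t_vals),
                           roi_i = as.character(seq_along(t_vals)),
                           roi_j = as.character(seq_along(t_vals) + 1),
                           t = t_vals, df = 10, p = p_vals),
    n_nc = 5, n_pd = 5, dataset_id = id, contrast_label = "NC-PD",
    sample_unit = "scan"
  ), class = "fc_contrast")
}

test_that("max_p_table keeps only sign-consistent pairs, sorted by max p", {
  c1 <- fake_contrast(c(2.0, 1.5, -1.0), c(0.01, 0.001, 0.2), "d1")
  c2 <- fake_contrast(c(1.0, -2.0, -1.2), c(0.02, 0.5, 0.3), "d2")
  tab <- max_p_table(list(c1, c2), "plus")
  expect_equal(tab$k, 1)
  expect_equal(tab$max_p, 0.02)
  tabm <- max_p_table(list(c1, c2), "minus")
  expect_equal(tabm$k, 3)
  expect_equal(tabm$max_p, 0.3)

  # identical contrasts: max_p is the single-dataset directional p
  tab2 <- max_p_table(list(c1, c1), "plus")
  expect_equal(tab2$max_p, c1$pairs$p[c1$pairs$t > 0][order(
    c1$pairs$p[c1$pairs$t > 0])])
})

test_that("max_p_table matches a brute-force double loop on random input", {
  set.seed(60)
  ids <- c("a", "b", "c")
  contrasts <- lapply(ids, function(id) {
    fake_contrast(rnorm(20), runif(20), id)
  })
  for (dir in c("plus", "minus")) {
    tab <- max_p_table(contrasts, dir)
    want_sign <- if (dir == "plus") 1 else -1
    oracle <- list()
    for (k in 1:20) {
      ts <- sapply(contrasts, function(cc) cc$pairs$t[k])
      ps <- sapply(contrasts, function(cc) cc$pairs$p[k])
      if (all(sign(ts) == want_sign)) {
        oracle[[length(oracle) + 1]] <- c(k = k, max_p = max(ps))
      }
    }
    odf <- as.data.frame(do.call(rbind, oracle))
    odf <- odf[order(odf$max_p, odf$k), ]
    expect_equal(tab$k, odf$k, ignore_attr = TRUE)
    expect_equal(tab$max_p, odf$max_p, ignore_attr = TRUE)
    expect_equal(min_max_p(contrasts, dir), min(odf$max_p))
  }
})

test_that("an empty retained set gives min(max(p)) = 1 by convention", {
  c1 <- fake_contrast(c(1, 2), c(0.1, 0.1), "d1")
  c2 <- fake_contrast(c(-1, -2), c(0.1, 0.1), "d2")
  expect_message(val <- min_max_p(list(c1, c2), "plus"))
  expect_equal(val, 1)
})

test_that("adding a dataset only shrinks the retained set and raises max_p", {
  set.seed(61)
  contrasts <- lapply(1:3, function(i) {
    fake_contrast(rnorm(30), runif(30), paste0("d", i))
  })
  t2 <- max_p_table(contrasts[1:2], "plus")
  t3 <- max_p_table(contrasts, "plus")
  expect_true(all(t3$k %in% t2$k))
  joined <- merge(t2[, c("k", "max_p")], t3[, c("k", "max_p")], by = "k")
  expect_true(all(joined$max_p.y >= joined$max_p.x))
})

test_that("swapping group labels swaps the plus and minus analyses exactly", {
  simA <- tiny_cohort(seed = 62, nc = 3, pd = 3, n_replicates = 1,
                      n_timepoints = 40, dataset_id = "A")
  simB <- tiny_cohort(seed = 63, nc = 3, pd = 3, n_replicates = 1,
                      n_timepoints = 40, dataset_id = "B")
  colls <- list(simA$scans, simB$scans)
  flipped <- lapply(colls, function(x) {
    x$group <- ifelse(x$group == "NC", "PD", "NC")
    x
  })
  res_plus <- consistency_permutation_test(colls, "plus", n_perm = 30,
                                           seed = 4)
  res_minus_flipped <- consistency_permutation_test(flipped, "minus",
                                                    n_perm = 30, seed = 4)
  expect_equal(res_plus$min_max_p, res_minus_flipped$min_max_p,
               tolerance = 1e-12)
  expect_equal(res_plus$ranked_pairs$k, res_minus_flipped$ranked_pairs$k)
  expect_equal(res_plus$null_sample, res_minus_flipped$null_sample,
               tolerance = 1e-12)
})

test_that("a strong planted effect is detected while pure noise is not", {
  ef <- list(pairs = 3L, delta_z = 1.2)
  colls <- lapply(1:3, function(i) {
    simulate_cohort(sim_config(
      n_regions = 6, n_timepoints = 120, n_subjects_nc = 8,
      n_subjects_pd = 8, n_replicates = 1, effect_pairs = list(ef),
      sigma_subject = 0.05, sigma_scan = 0, seed = 70 + i, base_seed = 7,
      dataset_id = paste0("d", i)
    ))$scans
  })
  # delta_z > 0 raises PD connectivity, so the effect shows in "minus"
  res <- consistency_permutation_test(colls, "minus", n_perm = 200, seed = 5)
  expect_equal(res$ranked_pairs$k[1], 3)
  expect_lte(res$p_of_min_max_p, 0.05)

  null_colls <- lapply(1:3, function(i) {
    simulate_cohort(sim_config(
      n_regions = 6, n_timepoints = 120, n_subjects_nc = 8,
      n_subjects_pd = 8, n_replicates = 1, sigma_subject = 0.05,
      sigma_scan = 0, seed = 80 + i, base_seed = 7,
      dataset_id = paste0("n", i)
    ))$scans
  })
  res0 <- consistency_permutation_test(null_colls, "minus", n_perm = 200,
                                       seed = 6)
  expect_gt(res0$p_of_min_max_p, 0.05)
})
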