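test_that("extract_roi_timecourses averages exactly over label voxels", {
  # one label covering everything, constant image
  img <- array(5, dim = c(2, 2, 1, 3))
  atl <- array(1L, dim = c(2, 2, 1))
  out <- extract_roi_timecourses(img, atl)
  expect_equal(dim(out), c(3, 1))
  expect_true(all(out == 5))

  # two single-voxel labels carry their own series through
  img2 <- array(0, dim = c(2, 1, 1, 3))
  img2[1, 1, 1, ] <- c(1, 2, 3)
  img2[2, 1, 1, ] <- c(10, 20, 30)
  atl2 <- array(c(1L, 2L), dim = c(2, 1, 1))
  out2 <- extract_roi_timecourses(img2, atl2)
  expect_equal(unname(out2), cbind(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(colnames(out2), c("1", "2"))

  # random image, 3 labels: match the brute-force voxel loop
  set.seed(10)
  img3 <- array(rnorm(4 * 4 * 4 * 10), dim = c(4, 4, 4, 10))
  atl3 <- array(sample(0:3, 64, replace = TRUE), dim = c(4, 4, 4))
  out3 <- extract_roi_timecourses(img3, atl3)
  for (lab in 1:3) {
    vox <- which(atl3 == lab, arr.ind = TRUE)
    oracle <- sapply(1:10, function(t) {
      mean(img3[cbind(vox, t)])
    })
    expect_equal(unname(out3[, as.character(lab)]), oracle)
  }

  expect_error(extract_roi_timecourses(img3, array(0L, dim = c(4, 4, 4))),
               class = "fcrepro_empty_parcellation_error")
  expect_error(extract_roi_timecourses(img3, array(1L, dim = c(2, 2, 2))),
               class = "fcrepro_shape_error")
})

test_that("global signal regression orthogonalises against the global mean", {
  # identical columns regress to zero
  a <- rnorm(30)
  x <- cbind(a, a, a)
  expect_lt(max(abs(global_signal_regress(x))), 1e-10)

  # exact negatives: global signal vanishes, output is the demeaned input
  b <- rnorm(30)
  y <- cbind(b, -b)
  expect_equal(global_signal_regress(y), scale(y, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-10)

  # random matrix matches the normal-equations oracle
  set.seed(20)
  z <- matrix(rnorm(500), ncol = 5)
  g <- rowMeans(z)
  d <- cbind(1, g)
  oracle <- z - d %*% solve(crossprod(d), crossprod(d, z))
  res <- global_signal_regress(z)
  expect_equal(res, oracle, tolerance = 1e-10, ignore_attr = TRUE)

  # the residual global signal is numerically zero
  expect_lt(max(abs(rowMeans(res) %*% res)), 1e-8)
})

test_that("ideal bandpass passes in-band tones and kills out-of-band power", {
  tr <- 2
  t_idx <- 0:199
  in_band <- sin(2 * pi * 0.05 * t_idx * tr)
  out_band <- sin(2 * pi * 0.2 * t_idx * tr)
  x <- cbind(in_band, out_band)
  filt <- ideal_bandpass(x, 0.01, 0.1, tr_seconds = tr)
  expect_lt(max(abs(filt[, 1] - (in_band - mean(in_band)))), 1e-8)
  expect_lt(max(abs(filt[, 2])), 1e-8)

  # white noise: spectrum after filtering is exactly zero outside the band
  set.seed(30)
  w <- matrix(rnorm(200), ncol = 1)
  fw <- ideal_bandpass(w, 0.02, 0.08, tr_seconds = tr)
  spec <- Mod(stats::fft(fw[, 1]))^2
  freq <- pmin(0:199, 200 - (0:199)) / (200 * tr)
  expect_lt(max(spec[freq < 0.02 | freq > 0.08]), 1e-16)
  expect_gt(sum(spec[freq >= 0.02 & freq <= 0.08]), 0)

  # idempotence
  expect_equal(ideal_bandpass(fw, 0.02, 0.08, tr_seconds = tr), fw,
               tolerance = 1e-8)

  # a band falling strictly between DFT grid frequencies is empty
  expect_error(ideal_bandpass(w, 0.2401, 0.2424, tr_seconds = tr),
               class = "fcrepro_empty_band_error")
})

test_that("double-TR decimation keeps odd samples and doubles TR", {
  x <- matrix(1:12, ncol = 2)  # columns (1..6), (7..12)
  out <- decimate_double_tr(x)
  expect_equal(out, matrix(c(1, 3, 5, 7, 9, 11), ncol = 2))

  const <- matrix(1, nrow = 4, ncol = 2)
  expect_equal(nrow(decimate_double_tr(const)), 2)

  sim <- tiny_cohort(seed = 12, nc = 2, pd = 2, n_timepoints = 20)
  dec <- decimate_double_tr(sim$scans)
  expect_equal(dec$tr_seconds, sim$scans$tr_seconds * 2)
  expect_equal(nrow(dec$timeseries[[1]]), 10)

  # decimating white noise does not induce spurious correlation
  set.seed(40)
  long <- matrix(rnorm(20000), ncol = 2)
  r_before <- cor(long)[1, 2]
  r_after <- cor(decimate_double_tr(long))[1, 2]
  expect_lt(abs(r_before), 3 / sqrt(10000))
  expect_lt(abs(r_after), 3 / sqrt(5000))
})

test_that("scan collections round-trip through the TSV layout", {
  sim <- tiny_cohort(seed = 14, n_regions = 4, nc = 2, pd = 1,
                     n_replicates = 1, n_timepoints = 20)
  dir <- withr::local_tempdir()
  write_scan_collection(sim$scans, dir)
  back <- read_scan_collection(dir)
  expect_equal(back[, c("scan_id", "subject_id", "group", "dataset_id",
                        "replicate_index", "low_motion", "tr_seconds")],
               sim$scans[, c("scan_id", "subject_id", "group", "dataset_id",
                             "replicate_index", "low_motion", "tr_seconds")])
  for (i in seq_len(nrow(back))) {
    expect_lt(max(abs(back$timeseries[[i]] - sim$scans$timeseries[[i]])),
              1e-12)
  }
})

test_that("malformed collections are rejected with informative errors", {
  sim <- tiny_cohort(seed = 15, n_regions = 3, nc = 2, pd = 1,
                     n_replicates = 1, n_timepoints = 10)
  bad_group <- sim$scans
  bad_group$group[2] <- "PDX"
  expect_error(validate_collection(bad_group),
               regexp = "PDX", class = "fcrepro_validation_error")

  bad_cols <- sim$scans
  bad_cols$timeseries[[1]] <- bad_cols$timeseries[[1]][, 1:2]
  expect_error(validate_collection(bad_cols),
               class = "fcrepro_schema_error")

  dir <- withr::local_tempdir()
  write_scan_collection(sim$scans, dir)
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"),
                          show_col_types = FALSE)
  meta$group[1] <- "PDX"
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"))
  expect_error(read_scan_collection(dir),
               regexp = meta$scan_id[1], class = "fcrepro_validation_error")
})
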