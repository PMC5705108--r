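# Lightweight temporal operations applied uniformly to every scan of a
# collection: global signal regression, ideal frequency-domain filtering,
# and double-TR decimation. Each is an S3 generic with a matrix method (one
# scan) and a data.frame method (whole collection, mapped over the
# timeseries list-column).

#' Extract mean ROI timecourses from a 4D image and a labelled atlas
#'
#' Column `k` of the result is, at each timepoint, the spatial mean of the
#' image over the voxels carrying atlas label `k`. Labels are nonnegative
#' integers with 0 = background; columns are ordered by ascending label id,
#' and labels with no voxels are dropped with a warning. Inputs may be arrays
#' or paths to NIfTI files (read via the RNifti package).
#'
#' @param image_4d A 4D numeric array (`x, y, z, t`) or a NIfTI file path.
#' @param atlas A 3D integer-labelled array on the same spatial grid, or a
#'   NIfTI file path.
#' @param expected_labels Optional integer vector of labels the parcellation
#'   should contain; labels among these with zero voxels trigger a warning.
#' @return A `T x R` matrix with region-id column names.
#' @export
extract_roi_timecourses <- function(image_4d, atlas, expected_labels = NULL) {
  if (is.character(image_4d)) image_4d <- as.array(RNifti::readNifti(image_4d))
  if (is.character(atlas)) atlas <- as.array(RNifti::readNifti(atlas))
  image_4d <- as.array(image_4d)
  atlas <- as.array(atlas)
  if (length(dim(image_4d)) != 4) {
    abort("`image_4d` must be a 4D array.", class = "fcrepro_shape_error")
  }
  if (!identical(dim(image_4d)[1:3], dim(atlas)[1:3]) ||
      length(dim(atlas)) != 3) {
    abort("image and atlas must share the same 3D spatial grid.",
          class = "fcrepro_shape_error")
  }
  labels <- as.integer(round(atlas))
  if (any(labels < 0)) {
    abort("atlas labels must be nonnegative integers (0 = background).",
          class = "fcrepro_parameter_error")
  }
  keep <- labels > 0
  if (!any(keep)) {
    abort("atlas contains only background voxels.",
          class = "fcrepro_empty_parcellation_error")
  }
  n_t <- dim(image_4d)[4]
  mat <- matrix(image_4d, ncol = n_t)  # voxels x time
  lab <- labels[keep]
  sums <- rowsum(mat[keep, , drop = FALSE], group = lab)  # labels x time
  counts <- as.vector(table(lab))
  out <- t(sums / counts)
  colnames(out) <- rownames(sums)
  if (!is.null(expected_labels)) {
    empty <- setdiff(as.integer(expected_labels), unique(lab))
    if (length(empty)) {
      warn(paste0("dropping label(s) with zero voxels: ",
                  paste(empty, collapse = ", ")))
    }
  }
  out
}

#' Global signal regression
#'
#' Regresses the cross-region mean timecourse (plus intercept) out of every
#' region's timecourse by least squares, the standard "GSR" denoising step.
#' After the operation every column is orthogonal to the global signal. A
#' constant global signal degenerates to intercept-only regression, i.e.
#' column demeaning.
#'
#' @param x A `T x R` timeseries matrix, or a scan collection (the operation
#'   is applied to every scan).
#' @param ... Unused.
#' @return Same shape as the input.
#' @export
global_signal_regress <- function(x, ...) UseMethod("global_signal_regress")

#' @export
global_signal_regress.matrix <- function(x, ...) {
  if (nrow(x) <= 2) {
    abort("global signal regression needs more than 2 timepoints.",
          class = "fcrepro_parameter_error")
  }
  g <- rowMeans(x)
  design <- if (sd(g) < .Machine$double.eps * max(1, abs(mean(g)))) {
    matrix(1, nrow(x), 1)
  } else {
    cbind(1, g)
  }
  res <- stats::lm.fit(design, x)$residuals
  dimnames(res) <- dimnames(x)
  res
}

#' @export
global_signal_regress.data.frame <- function(x, ...) {
  x <- validate_collection(x)
  x$timeseries <- lapply(x$timeseries, global_signal_regress.matrix)
  x
}

#' Ideal frequency-domain bandpass filter
#'
#' Zeroes discrete-Fourier coefficients at frequencies strictly below
#' `low_hz` or strictly above `high_hz` and inverse-transforms, per column.
#' The DC component is removed whenever `low_hz > 0`. `high_hz = NULL` keeps
#' everything up to Nyquist (a pure highpass). The filter is idempotent.
#'
#' @param x A `T x R` matrix or a scan collection.
#' @param low_hz Lower band edge in Hz (>= 0).
#' @param high_hz Upper band edge in Hz, or `NULL` for Nyquist.
#' @param tr_seconds Sampling interval; taken from the collection metadata
#'   when `x` is a collection.
#' @param ... Unused.
#' @return Same shape as the input.
#' @export
ideal_bandpass <- function(x, low_hz, high_hz = NULL, ...) {
  UseMethod("ideal_bandpass")
}

#' @export
ideal_bandpass.matrix <- function(x, low_hz, high_hz = NULL,
                                  tr_seconds = 1, ...) {
  n_t <- nrow(x)
  nyquist <- 1 / (2 * tr_seconds)
  check_scalar(low_hz, lower = 0)
  hi <- if (is.null(high_hz)) nyquist else check_scalar(high_hz)
  if (!(low_hz < hi && hi <= nyquist + 1e-12)) {
    abort("need 0 <= low_hz < high_hz <= Nyquist.",
          class = "fcrepro_parameter_error")
  }
  # frequency of DFT bin m (0-based) is min(m, n - m) / (n * tr)
  m <- 0:(n_t - 1)
  freq <- pmin(m, n_t - m) / (n_t * tr_seconds)
  keep <- freq >= low_hz & freq <= hi
  if (low_hz > 0) keep[1] <- FALSE
  if (!any(keep)) {
    abort("the requested band excludes every available frequency.",
          class = "fcrepro_empty_band_error")
  }
  co <- stats::mvfft(x)
  co[!keep, ] <- 0
  out <- Re(stats::mvfft(co, inverse = TRUE)) / n_t
  dimnames(out) <- dimnames(x)
  out
}

#' @export
ideal_bandpass.data.frame <- function(x, low_hz, high_hz = NULL, ...) {
  x <- validate_collection(x)
  x$timeseries <- purrr::map2(x$timeseries, x$tr_seconds, function(m, tr) {
    ideal_bandpass.matrix(m, low_hz, high_hz, tr_seconds = tr)
  })
  x
}

#' Double-TR decimation
#'
#' Emulates a scan acquired at twice the repetition time by keeping every
#' second timepoint (the first, third, ... samples) and doubling
#' `tr_seconds` — the probe used to test whether the repetition time drives
#' reproducibility differences.
#'
#' @param x A `T x R` matrix (`T >= 4`) or a scan collection.
#' @param ... Unused.
#' @return Same shape as the input, with `floor((T + 1) / 2)` timepoints.
#' @export
decimate_double_tr <- function(x, ...) UseMethod("decimate_double_tr")

#' @export
decimate_double_tr.matrix <- function(x, ...) {
  if (nrow(x) < 4) {
    abort("decimation needs at least 4 timepoints.",
          class = "fcrepro_parameter_error")
  }
  x[seq(1, nrow(x), by = 2), , drop = FALSE]
}

#' @export
decimate_double_tr.data.frame <- function(x, ...) {
  x <- validate_collection(x)
  x$timeseries <- lapply(x$timeseries, decimate_double_tr.matrix)
  x$tr_seconds <- x$tr_seconds * 2
  x
}
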