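# Correlation-matrix construction and repair for the synthetic cohort.

#' Low-rank-plus-diagonal baseline correlation matrix
#'
#' Draws a random `R x R` correlation matrix with `rank` latent factors:
#' `S = W W' + diag(u)` with `W` an `R x rank` standard-normal loading matrix
#' and `u` positive, rescaled to unit diagonal. The diagonal component keeps
#' every off-diagonal correlation strictly inside (-1, 1) while the low-rank
#' part gives the block-like structure typical of parcellated resting-state
#' connectomes.
#'
#' @param n_regions Number of regions `R` (>= 2).
#' @param rank Number of latent factors, `1 <= rank <= n_regions`.
#' @param seed Integer seed; the matrix is a deterministic function of
#'   `(n_regions, rank, seed)`.
#' @return A symmetric positive-semidefinite correlation matrix with unit
#'   diagonal.
#' @examples
#' c0 <- make_base_correlation(5, rank = 2, seed = 1)
#' range(c0[upper.tri(c0)])
#' @export
make_base_correlation <- function(n_regions, rank, seed) {
  r <- check_count(n_regions, min = 2, what = "n_regions")
  check_count(rank, min = 1, what = "rank")
  if (rank > r) {
    abort("`rank` must not exceed `n_regions`.",
          class = "fcrepro_parameter_error")
  }
  with_seed_if(seed, {
    w <- matrix(rnorm(r * rank), nrow = r)
    u <- runif(r, min = 0.5, max = 1.5) * rank
    s <- tcrossprod(w) + diag(u, nrow = r)
    d <- 1 / sqrt(diag(s))
    m <- s * tcrossprod(d)
    diag(m) <- 1
    (m + t(m)) / 2
  })
}

#' Nearest correlation matrix by alternating projections
#'
#' Projects a symmetric matrix onto the set of valid correlation matrices by
#' alternating between the positive-semidefinite cone (eigenvalue clipping at
#' zero) and the unit-diagonal affine set, with Dykstra's correction.
#' Convergence is declared at Frobenius-norm change below `tol`.
#'
#' @param m Symmetric matrix to repair.
#' @param tol Frobenius-norm convergence tolerance.
#' @param max_iter Iteration budget; exceeding it is an error (the caller
#'   names the offending scan).
#' @return The nearest correlation matrix (symmetric, unit diagonal, smallest
#'   eigenvalue >= 0 up to numerical round-off).
#' @export
nearest_correlation <- function(m, tol = 1e-8, max_iter = 100) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  y <- (m + t(m)) / 2
  ds <- matrix(0, nrow(y), ncol(y))
  for (iter in seq_len(max_iter)) {
    r <- y - ds
    e <- eigen(r, symmetric = TRUE)
    x <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    x <- (x + t(x)) / 2
    ds <- x - r
    y_new <- x
    diag(y_new) <- 1
    converged <- sqrt(sum((y_new - y)^2)) < tol
    y <- y_new
    if (converged) {
      # final clean-up: clip residual negative eigenvalues, restore unit
      # diagonal by congruence (which preserves positive semidefiniteness)
      e <- eigen(y, symmetric = TRUE)
      x <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
      x <- (x + t(x)) / 2
      d <- 1 / sqrt(pmax(diag(x), .Machine$double.eps))
      out <- x * tcrossprod(d)
      diag(out) <- 1
      return(out)
    }
  }
  abort("nearest_correlation() did not converge within the iteration budget.",
        class = "fcrepro_simulation_error")
}

#' Shift selected pair correlations in Fisher-z space
#'
#' Adds `delta_z` to the Fisher-z transform of the correlations at the given
#' canonical pair indices, maps back through `tanh`, and repairs the result to
#' the nearest valid correlation matrix. This is how group and subtype effects
#' are planted in the synthetic cohort: effects are additive on the z scale,
#' the scale on which connectivity contrasts are computed.
#'
#' @param corr_mat A correlation matrix.
#' @param pairs Integer canonical pair indices (see [pair_index()]).
#' @param delta_z Signed z-space shift applied to every pair in `pairs`.
#' @return A valid correlation matrix equal to `corr_mat` away from the
#'   affected pairs (up to the repair projection).
#' @examples
#' c0 <- diag(3)
#' c1 <- apply_effect_in_z(c0, pairs = 1, delta_z = 0.3)
#' c1[1, 2]  # tanh(0.3)
#' @export
apply_effect_in_z <- function(corr_mat, pairs, delta_z) {
  stopifnot(is.matrix(corr_mat), nrow(corr_mat) == ncol(corr_mat))
  r <- nrow(corr_mat)
  p <- pair_count(r)
  pairs <- as.integer(pairs)
  if (length(pairs) && (min(pairs) < 1 || max(pairs) > p)) {
    abort(sprintf("pair indices must lie in 1..%d.", p),
          class = "fcrepro_parameter_error")
  }
  check_scalar(delta_z, what = "delta_z")
  if (delta_z == 0 || length(pairs) == 0) {
    return(corr_mat)
  }
  v <- upper_pairs(corr_mat)
  if (any(abs(v[pairs]) >= 1)) {
    abort("cannot shift a pair whose correlation is already +/-1.",
          class = "fcrepro_degenerate_error")
  }
  v[pairs] <- tanh(atanh(v[pairs]) + delta_z)
  out <- pairs_to_matrix(v, r)
  e_min <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (e_min < -1e-12) out <- nearest_correlation(out)
  out
}

# Symmetric z-space Gaussian jitter of the off-diagonal, repaired to a valid
# correlation matrix; the noise model for subject- and scan-level deviations.
perturb_correlation_z <- function(corr_mat, sigma) {
  if (sigma == 0) {
    return(corr_mat)
  }
  r <- nrow(corr_mat)
  v <- upper_pairs(corr_mat)
  v <- pmin(pmax(v, -1 + 1e-12), 1 - 1e-12)
  v <- tanh(atanh(v) + rnorm(length(v), sd = sigma))
  out <- pairs_to_matrix(v, r)
  e_min <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (e_min < -1e-12) out <- nearest_correlation(out)
  out
}
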