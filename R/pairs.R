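#' Canonical region-pair index
#'
#' Every edgewise quantity in this package (Fisher-z connectivity, contrast
#' t-vectors, consistency tables) is stored as a length-`P` vector over the
#' `P = R(R-1)/2` unordered region pairs of an `R`-region parcellation, in a
#' single canonical order: pairs `(i, j)` with `i < j` sorted
#' lexicographically, i.e. `(1,2), (1,3), ..., (1,R), (2,3), ...`. Indices are
#' 1-based: `k` runs over `1..P` and region indices over `1..R`.
#'
#' @param n_regions Number of regions `R` (>= 2).
#' @return A tibble with columns `k`, `i`, `j` (one row per pair, in canonical
#'   order).
#' @examples
#' pair_index(4)
#' @export
pair_index <- function(n_regions) {
  check_count(n_regions, min = 2, what = "n_regions")
  r <- as.integer(n_regions)
  i <- rep.int(seq_len(r - 1L), times = (r - 1L):1L)
  j <- sequence((r - 1L):1L) + i
  tibble(k = seq_along(i), i = i, j = j)
}

#' Number of region pairs
#'
#' `pair_count(R)` is `R(R-1)/2`, the number of unordered region pairs; e.g.
#' the 116-region AAL parcellation has 6670 pairs.
#'
#' @inheritParams pair_index
#' @return A single number.
#' @examples
#' pair_count(116)
#' @export
pair_count <- function(n_regions) {
  check_count(n_regions, min = 2, what = "n_regions")
  n_regions * (n_regions - 1) / 2
}

# Extract the canonical pair vector from a symmetric R x R matrix.
# t(M)[lower.tri(M)] walks the upper triangle row by row, which is exactly
# the lexicographic (i, j) order of pair_index().
upper_pairs <- function(m) {
  t(m)[lower.tri(m)]
}

# Inverse of upper_pairs(): symmetric matrix with unit diagonal.
pairs_to_matrix <- function(v, n_regions) {
  idx <- pair_index(n_regions)
  m <- diag(n_regions)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  m
}
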