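# Internal argument checks and seed plumbing.

utils::globalVariables("y")

check_count <- function(x, min = 1, what = deparse(substitute(x))) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x %% 1 != 0 || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s, got %s.",
                  what, min, deparse(x)),
          class = "fcrepro_parameter_error")
  }
  invisible(as.integer(x))
}

check_scalar <- function(x, what = deparse(substitute(x)),
                         lower = -Inf, upper = Inf) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  what, lower, upper),
          class = "fcrepro_parameter_error")
  }
  invisible(as.numeric(x))
}

# Evaluate `expr` under `seed` when given, restoring the caller's RNG state;
# with seed = NULL the expression consumes the ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage seed stream: a small string hash folded with the
# global seed, kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(global_seed, stage_name) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage_name))) {
    h <- (h * 131 + ch) %% 1013904223
  }
  as.integer((as.numeric(global_seed) %% 1013904223 * 69069 + h) %% 2147483647)
}
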