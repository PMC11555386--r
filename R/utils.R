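# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Restores (or removes) the caller's .Random.seed afterwards so that
# seeded simulation calls do not disturb the session RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

#' Truncate (not round) to a fixed number of decimal places
#'
#' Display helper used when reporting equivalent diameters: stored values
#' keep full precision and truncation/rounding is applied only at the
#' reporting stage.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` truncated towards zero at `digits` decimals.
#' @export
#' @examples
#' trunc_decimals(0.0357, 3) # 0.035
trunc_decimals <- function(x, digits = 3) {
  trunc(x * 10^digits) / 10^digits
}

# Draw from a normal(mean, sd) truncated below at `min`, by quantile inversion.
rtnorm_min <- function(n, mean, sd, min) {
  if (sd <= 0) return(rep(mean, n))
  p0 <- pnorm(min, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}
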