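## Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## z-score; constant vectors map to 0 rather than NaN so that degenerate
## regressors fail rank checks downstream instead of poisoning the design.
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

## Truncated-normal draw on [lo, hi] via inverse-CDF; vectorised over mean.
rtnorm <- function(n, mean, sd, lo, hi) {
  if (any(sd < 0)) stop("sd must be >= 0")
  if (all(sd == 0)) return(clip(rep_len(mean, n), lo, hi))
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, a, b)
  clip(stats::qnorm(u, mean, sd), lo, hi)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

check_range <- function(x, lo, hi, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  if (any(x < lo | x > hi))
    stop(sprintf("'%s' must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  invisible(x)
}

## log-sum-exp over a numeric vector/array
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
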