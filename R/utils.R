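# Internal numeric helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable when a ~ b
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)  # equality (single-SNP locus) has zero mass left
  a + log1p(-exp(b - a))
}

# Two-sided normal p-value from z, computed in log space so that extreme
# signals (|z| ~ 12 gives p ~ 1e-31) never underflow prematurely.
#' @keywords internal
z_to_log10p <- function(z) {
  (stats::pnorm(-abs(z), log.p = TRUE) + log(2)) / log(10)
}

#' @keywords internal
z_to_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

# chi-square(1) quantile of the median under the null
CHISQ1_MEDIAN <- 0.4549364231195728  # qchisq(0.5, df = 1)

Z_95 <- 1.959964  # two-sided 95% normal quantile, as used in CI printing

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Effective sample size for a case-control study: the size of a balanced
# study with equal power, 4 / (1/n_cases + 1/n_controls).
#' @export
effective_n <- function(n_cases, n_controls) {
  stopifnot(all(n_cases > 0), all(n_controls > 0))
  4 / (1 / n_cases + 1 / n_controls)
}

# Deterministic per-stage seed derivation from one global integer seed.
# Offsets are fixed small primes per consumer; kept below 2^31.
#' @keywords internal
substream_seed <- function(seed, offset) {
  (as.integer(seed) %% 2000000011L + offset * 7919L) %% 2147483647L
}
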