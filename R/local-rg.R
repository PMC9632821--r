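# Local SNP heritability and cross-trait genetic covariance at a locus,
# from standardized marginal effects and the locus LD matrix: quadratic
# forms of the effect vectors in the truncated eigenbasis of R, with the
# noise bias removed analytically. Standardization convention: b_std =
# z / sqrt(N), which removes the allele-frequency scale.

# Truncated eigenbasis of a (clipped) LD matrix.
#' @keywords internal
ld_eigen <- function(R, k = NULL, trace_prop = 0.995, k_max = 50L) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  pos <- e$values > 1e-8
  if (is.null(k)) {
    cum <- cumsum(e$values[pos]) / sum(e$values[pos])
    k <- min(which(cum >= trace_prop)[1], k_max, sum(pos))
  }
  if (k > sum(pos))
    stop("k = ", k, " exceeds the positive-eigenvalue count ", sum(pos))
  list(U = e$vectors[, seq_len(k), drop = FALSE],
       lambda = e$values[seq_len(k)], k = k)
}

#' Local SNP heritability from standardized effects
#'
#' With R = U L U' and q_k the quadratic form of b_std over the top-k
#' eigencomponents, the estimator is h2_local = (N q_k - k) / (N - k);
#' it is unbiased and may legitimately be negative at null loci. The SE
#' comes from the asymptotic variance of the (scaled) non-central
#' chi-square quadratic form with the estimate plugged in.
#'
#' @param betas_std standardized effects, b_std = z / sqrt(N).
#' @param R locus LD matrix (symmetrized and eigen-clipped internally).
#' @param N sample size.
#' @param k eigencomponent count; default: smallest k explaining >= 99.5%
#'   of the positive trace, capped at 50.
#' @return list with `h2`, `se`, `k`.
#' @export
local_h2 <- function(betas_std, R, N, k = NULL) {
  ei <- ld_eigen(R, k)
  wproj <- drop(crossprod(ei$U, betas_std)) / sqrt(ei$lambda)
  q <- sum(wproj^2)
  h2 <- (N * q - ei$k) / (N - ei$k)
  ncp <- N * max(h2, 0)
  se <- sqrt((2 * ei$k + 4 * ncp)) / (N - ei$k)
  list(h2 = h2, se = se, k = ei$k)
}

#' Local cross-trait genetic covariance and correlation
#'
#' gencov = b1' U_k L_k^-1 U_k' b2 - k rho Ns / (N1 N2); the second term
#' removes the noise covariance induced by sample overlap (zero for
#' disjoint cohorts, the default). The local correlation
#' gencov / sqrt(h2_1 h2_2) is reported only when both local
#' heritabilities are positive; the covariance itself is always reported.
#' The two-sided p-value is a Wald test with the asymptotic variance of
#' the bilinear form (estimates plugged in).
#'
#' @param b1_std,b2_std standardized effects z/sqrt(N) on identical SNPs
#'   and alleles.
#' @param R locus LD matrix.
#' @param N1,N2 per-trait sample sizes.
#' @param overlap c(Ns = shared samples, rho = phenotypic correlation).
#' @param k eigencomponent count (default as [local_h2()]).
#' @return object of class `local_rg_result`: locus k, per-trait local h2
#'   (with SEs), `gencov`, `gencov_se`, `corr` (NA when undefined),
#'   `p_gencov`.
#' @export
local_gencov <- function(b1_std, b2_std, R, N1, N2,
                         overlap = c(Ns = 0, rho = 0), k = NULL) {
  stopifnot(length(b1_std) == length(b2_std))
  ei <- ld_eigen(R, k)
  w1 <- drop(crossprod(ei$U, b1_std)) / sqrt(ei$lambda)
  w2 <- drop(crossprod(ei$U, b2_std)) / sqrt(ei$lambda)
  Ns <- unname(overlap["Ns"]); rho <- unname(overlap["rho"])
  cc <- Ns * rho / sqrt(N1 * N2)
  gencov <- sum(w1 * w2) - ei$k * rho * Ns / (N1 * N2)
  h1 <- (N1 * sum(w1^2) - ei$k) / (N1 - ei$k)
  h2 <- (N2 * sum(w2^2) - ei$k) / (N2 - ei$k)
  # Var(w1'w2) for independent-mean gaussian vectors with per-component
  # noise correlation cc; genetic parts plugged in (clipped at 0)
  vg <- (N1 * max(h1, 0) + N2 * max(h2, 0) +
           2 * sqrt(N1 * N2) * cc * gencov + ei$k * (1 + cc^2)) / (N1 * N2)
  gencov_se <- sqrt(max(vg, .Machine$double.eps))
  corr <- if (h1 > 0 && h2 > 0) gencov / sqrt(h1 * h2) else NA_real_
  structure(list(
    k = ei$k,
    h2_local_1 = h1, h2_local_1_se = sqrt(2 * ei$k + 4 * N1 * max(h1, 0)) / (N1 - ei$k),
    h2_local_2 = h2, h2_local_2_se = sqrt(2 * ei$k + 4 * N2 * max(h2, 0)) / (N2 - ei$k),
    gencov = gencov, gencov_se = gencov_se,
    corr_local = corr,
    p_gencov = z_to_p(gencov / gencov_se)
  ), class = "local_rg_result")
}

#' @export
print.local_rg_result <- function(x, ...) {
  cat(sprintf("Local genetic covariance (k = %d components)\n", x$k))
  cat(sprintf("  h2_local: %.3g (%.2g) / %.3g (%.2g)\n",
              x$h2_local_1, x$h2_local_1_se, x$h2_local_2, x$h2_local_2_se))
  cat(sprintf("  gencov = %.3g (se %.2g, p = %.3g)", x$gencov, x$gencov_se,
              x$p_gencov))
  if (!is.na(x$corr_local)) cat(sprintf(", corr = %.3f", x$corr_local))
  cat("\n")
  invisible(x)
}
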