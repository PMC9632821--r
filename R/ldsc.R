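# Genome-wide genetic correlation by LD score regression.
#
# Single-trait model:   E[chi2_j] = 1 + a + N h2 l_j / M
# Cross-trait model:    E[z1j z2j] = rho_Ns/sqrt(N1 N2) + sqrt(N1 N2) rho_g l_j / M
# Slopes are estimated by a two-step heteroskedasticity-weighted regression
# and standard errors by a delete-one block jackknife over contiguous
# genomic blocks. The intercepts absorb confounding and sample overlap, so
# neither needs to be known in advance.

#' LD scores from a reference panel
#'
#' l_j = sum over SNPs k within `window_bp` of the adjusted squared
#' correlation r2_adj = r2 - (1 - r2) / (n_ref - 2) (the unbiased
#' small-sample adjustment; for a theoretical panel with `n_ref = Inf` the
#' raw r2 is used). Cross-block correlation is zero by construction.
#'
#' @param ld_ref an `ld_reference`.
#' @param window_bp window half-width in bp (default 1 Mb).
#' @return data.frame with `snp_id`, `ell`, `maf`.
#' @export
ld_scores <- function(ld_ref, window_bp = 1e6) {
  adj <- function(r2) {
    if (is.finite(ld_ref$n_ref)) r2 - (1 - r2) / (ld_ref$n_ref - 2) else r2
  }
  ell <- numeric(length(ld_ref$snp_ids))
  off <- 0L
  for (R in ld_ref$R_blocks) {
    idx <- off + seq_len(nrow(R))
    r2 <- adj(R^2)
    inwin <- abs(outer(ld_ref$pos[idx], ld_ref$pos[idx], "-")) <= window_bp
    ell[idx] <- rowSums(r2 * inwin)
    off <- off + nrow(R)
  }
  data.frame(snp_id = ld_ref$snp_ids, ell = ell,
             maf = pmin(ld_ref$freqs, 1 - ld_ref$freqs),
             stringsAsFactors = FALSE)
}

# Weighted simple regression y ~ 1 + x with a delete-one block jackknife.
# Returns full-sample coefficients and per-block leave-one-out coefficients.
#' @keywords internal
jackknife_wls <- function(x, y, w, blocks) {
  X <- cbind(1, x, deparse.level = 0)
  xtx <- function(i) crossprod(X[i, , drop = FALSE] * w[i], X[i, , drop = FALSE])
  xty <- function(i) crossprod(X[i, , drop = FALSE] * w[i], y[i])
  per_a <- lapply(blocks, xtx)
  per_c <- lapply(blocks, xty)
  A <- Reduce(`+`, per_a)
  C <- Reduce(`+`, per_c)
  coef_full <- drop(solve(A, C))
  loo <- t(vapply(seq_along(blocks), function(b) {
    drop(solve(A - per_a[[b]], C - per_c[[b]]))
  }, numeric(2)))
  list(coef = coef_full, loo = loo)
}

#' @keywords internal
make_blocks <- function(m, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, m %/% 2L))
  cuts <- floor(seq(0, m, length.out = n_blocks + 1L))
  lapply(seq_len(n_blocks), function(b) (cuts[b] + 1L):cuts[b + 1L])
}

#' @keywords internal
jackknife_se <- function(theta_loo, theta_hat) {
  nb <- length(theta_loo)
  sqrt((nb - 1) / nb * sum((theta_loo - mean(theta_loo))^2))
}

#' SNP heritability by LD score regression
#'
#' Regresses chi-square statistics on N l_j / M with a free intercept; the
#' slope is h2. Two-step weighting (1/l, then 1/(l * E[chi2]^2) with the
#' first-pass fit plugged in); chi-square statistics above
#' max(80, 0.001 N) are excluded as outliers; jackknife SE over contiguous
#' blocks.
#'
#' @param z per-SNP z-scores.
#' @param ell LD score table from [ld_scores()] or a numeric vector.
#' @param N per-SNP (or scalar) sample size.
#' @param M number of SNPs the heritability is spread over (default:
#'   length of z).
#' @param n_blocks jackknife block count (default 200, reduced
#'   proportionally for small SNP sets).
#' @return list with `h2`, `h2_se`, `intercept`, `intercept_se`, and the
#'   per-block leave-one-out estimates.
#' @export
ldsc_h2 <- function(z, ell, N, M = length(z), n_blocks = 200L) {
  if (is.data.frame(ell)) ell <- ell$ell
  stopifnot(length(z) == length(ell), M > 0)
  N <- rep_len(N, length(z))
  chi2 <- z^2
  cap <- max(80, 0.001 * stats::median(N))
  keep <- chi2 <= cap
  x <- (N * ell / M)[keep]
  y <- chi2[keep]
  l <- pmax(ell[keep], 1)
  m <- length(y)
  if (m < 2L * 2L) stop("too few SNPs for jackknife")
  blocks <- make_blocks(m, n_blocks)
  if (length(blocks) > m) stop("fewer SNPs than jackknife blocks")
  step1 <- jackknife_wls(x, y, 1 / l, blocks)
  mu <- pmax(step1$coef[1] + step1$coef[2] * x, 0.1)
  w <- 1 / (l * mu^2)
  fit <- jackknife_wls(x, y, w, blocks)
  list(h2 = fit$coef[2], h2_se = jackknife_se(fit$loo[, 2], fit$coef[2]),
       intercept = fit$coef[1],
       intercept_se = jackknife_se(fit$loo[, 1], fit$coef[1]),
       loo = fit$loo, keep = keep, blocks = blocks)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the z-score products z1 z2 on sqrt(N1 N2) l_j / M; the slope
#' is the genetic covariance rho_g and the free intercept absorbs sample
#' overlap. rg = rho_g / sqrt(h2_1 h2_2) with both heritabilities fitted by
#' [ldsc_h2()] on the same SNPs; the SE and p-value of rg come from a
#' block jackknife of the full ratio (slope and both heritabilities
#' re-estimated with each block deleted).
#'
#' @param z1,z2 aligned per-SNP z-scores (harmonized to a common effect
#'   allele).
#' @param ell LD score table or vector.
#' @param N1,N2 per-SNP or scalar sample sizes.
#' @param M SNP count normalizing the per-SNP heritability.
#' @param maf optional per-SNP minor allele frequencies; SNPs with
#'   maf <= `maf_min` are removed before fitting.
#' @param maf_min common-variant bound (default 0.01).
#' @param n_blocks jackknife block count (default 200).
#' @return object of class `ldsc_fit`: h2 for both traits, gencov, rg with
#'   jackknife SE and p, and the three intercepts.
#' @export
ldsc_rg <- function(z1, z2, ell, N1, N2, M = length(z1), maf = NULL,
                    maf_min = 0.01, n_blocks = 200L) {
  if (is.data.frame(ell)) {
    if (is.null(maf)) maf <- ell$maf
    ell <- ell$ell
  }
  stopifnot(length(z1) == length(z2), length(z1) == length(ell))
  N1 <- rep_len(N1, length(z1)); N2 <- rep_len(N2, length(z1))
  if (!is.null(maf)) {
    keep <- maf > maf_min
    z1 <- z1[keep]; z2 <- z2[keep]; ell <- ell[keep]
    N1 <- N1[keep]; N2 <- N2[keep]
  }
  m <- length(z1)
  blocks <- make_blocks(m, n_blocks)
  h1 <- ldsc_h2_on_blocks(z1, ell, N1, M, blocks)
  h2 <- ldsc_h2_on_blocks(z2, ell, N2, M, blocks)
  x <- sqrt(N1 * N2) * ell / M
  # winsorize products at the same cap as the single-trait chi-squares so
  # that regressing a trait on itself recovers rg = 1
  cap <- max(80, 0.001 * sqrt(stats::median(N1) * stats::median(N2)))
  y <- pmin(pmax(z1 * z2, -cap), cap)
  l <- pmax(ell, 1)
  step1 <- jackknife_wls(x, y, 1 / l, blocks)
  # heteroskedasticity weights from the fitted single-trait and cross models
  mu1 <- pmax(1 + N1 * h1$coef[2] * ell / M, 0.1)
  mu2 <- pmax(1 + N2 * h2$coef[2] * ell / M, 0.1)
  mu12 <- step1$coef[1] + step1$coef[2] * x
  w <- 1 / (l * (mu1 * mu2 + mu12^2))
  cross <- jackknife_wls(x, y, w, blocks)
  gencov <- cross$coef[2]
  rg_point <- function(g, a, b) {
    if (a <= 0 || b <= 0) return(NA_real_)
    g / sqrt(a * b)
  }
  rg <- rg_point(gencov, h1$coef[2], h2$coef[2])
  rg_loo <- vapply(seq_along(blocks), function(b) {
    rg_point(cross$loo[b, 2], h1$loo[b, 2], h2$loo[b, 2])
  }, numeric(1))
  rg_se <- if (anyNA(rg_loo) || is.na(rg)) NA_real_ else
    jackknife_se(rg_loo, rg)
  gencov_se <- jackknife_se(cross$loo[, 2], gencov)
  structure(list(
    h2_1 = h1$coef[2], h2_1_se = jackknife_se(h1$loo[, 2], h1$coef[2]),
    h2_2 = h2$coef[2], h2_2_se = jackknife_se(h2$loo[, 2], h2$coef[2]),
    gencov = gencov, gencov_se = gencov_se,
    rg = rg, rg_se = rg_se,
    rg_p = if (is.na(rg_se)) NA_real_ else z_to_p(rg / rg_se),
    intercept_1 = h1$coef[1], intercept_2 = h2$coef[1],
    intercept_cross = cross$coef[1],
    n_snps = m, defined = !is.na(rg)
  ), class = "ldsc_fit")
}

# single-trait fit reusing externally fixed blocks (no outlier refiltering,
# so the cross-trait jackknife deletes identical SNP sets in all three fits)
#' @keywords internal
ldsc_h2_on_blocks <- function(z, ell, N, M, blocks) {
  x <- N * ell / M
  cap <- max(80, 0.001 * stats::median(N))
  y <- pmin(z^2, cap)  # winsorize outliers so block structure is preserved
  l <- pmax(ell, 1)
  step1 <- jackknife_wls(x, y, 1 / l, blocks)
  mu <- pmax(step1$coef[1] + step1$coef[2] * x, 0.1)
  jackknife_wls(x, y, 1 / (l * mu^2), blocks)
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("LDSC cross-trait fit over %d SNPs\n", x$n_snps))
  cat(sprintf("  h2_1 = %.4f (%.4f)   h2_2 = %.4f (%.4f)\n",
              x$h2_1, x$h2_1_se, x$h2_2, x$h2_2_se))
  cat(sprintf("  gencov = %.4f (%.4f)\n", x$gencov, x$gencov_se))
  if (x$defined) {
    cat(sprintf("  rg = %.3f (se %.3f, p = %.3g)\n", x$rg, x$rg_se, x$rg_p))
  } else {
    cat("  rg undefined (non-positive heritability estimate)\n")
  }
  cat(sprintf("  intercepts: %.3f / %.3f / cross %.3f\n",
              x$intercept_1, x$intercept_2, x$intercept_cross))
  invisible(x)
}
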