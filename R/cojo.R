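# Conditional and joint analysis of marginal GWAS effects with a reference
# LD panel: approximate stepwise model selection ("slct"), joint effect
# estimation, and conditional marginal statistics ("cond"). The algebra is
# the standard summary-statistics normal-equations approximation: with
# per-SNP diagonal D_j = 2 f_j (1 - f_j) N_j standing in for x_j' x_j and
# off-diagonal elements r_jk sqrt(D_j D_k) from reference LD, the joint
# effects are solve(B, D * b_marginal) and the residual variance comes from
# a median-aggregated reconstruction of y'y.

#' @keywords internal
cojo_setup <- function(sumstats, ld_ref, n = NULL, window_bp = 10e6) {
  ss <- sumstats
  idx <- match(ss$snp_id, ld_ref$snp_ids)
  keep <- !is.na(idx)
  ss <- ss[keep, , drop = FALSE]
  idx <- idx[keep]
  if (nrow(ss) == 0L) stop("no summary-statistics SNPs found in the LD reference")
  ord <- order(idx)  # reference (genomic) order, matching ld_subset below
  ss <- ss[ord, , drop = FALSE]
  idx <- idx[ord]
  # frequency consistency guard against panel mismatch
  fr <- ld_ref$freqs[idx]
  if (any(is.finite(fr))) {
    bad <- is.finite(fr) & abs(ss$freq_a1 - fr) > 0.2
    if (any(bad)) {
      message("dropping ", sum(bad), " SNP(s) with |freq - ref freq| > 0.2")
      ss <- ss[!bad, , drop = FALSE]
      idx <- idx[!bad]
    }
  }
  if (is.null(n)) {
    if (all(is.finite(ss$n_cases) & is.finite(ss$n_controls))) {
      n <- effective_n(ss$n_cases, ss$n_controls)
    } else stop("per-SNP sample size unavailable; supply `n`")
  }
  n <- rep_len(n, nrow(ss))
  D <- 2 * ss$freq_a1 * (1 - ss$freq_a1) * n
  yty <- stats::median(D * ss$beta^2 + D * ss$se^2 * (n - 1))
  R <- as.matrix(ld_subset(ld_ref, ss$snp_id))
  # SNPs farther apart than the window are treated as unlinked
  far <- abs(outer(ss$pos, ss$pos, "-")) >= window_bp |
    outer(ss$chrom, ss$chrom, "!=")
  R[far] <- 0
  diag(R) <- 1
  sD <- sqrt(D)
  list(ss = ss, n = n, D = D, w = D * ss$beta, yty = yty,
       B = R * outer(sD, sD), R = R, nbar = stats::median(n))
}

#' @keywords internal
cojo_joint_fit <- function(setup, sel) {
  k <- length(sel)
  B <- setup$B[sel, sel, drop = FALSE]
  if (rcond(B) < 1e-8) return(NULL)
  Binv <- solve(B)
  bJ <- drop(Binv %*% setup$w[sel])
  sigma2 <- max((setup$yty - sum(bJ * setup$w[sel])) / (setup$nbar - k), 1e-12)
  se <- sqrt(sigma2 * diag(Binv))
  z <- bJ / se
  list(sel = sel, bJ = bJ, bJ_se = se, pJ = z_to_p(z),
       log10_pJ = z_to_log10p(z), sigma2 = sigma2, Binv = Binv)
}

# Conditional marginal statistics of SNPs `rest` given selected set `sel`.
#' @keywords internal
cojo_conditional <- function(setup, sel, rest, fit = NULL) {
  if (length(sel) == 0L) {
    z <- setup$ss$beta[rest] / setup$ss$se[rest]
    return(data.frame(idx = rest, beta_c = setup$ss$beta[rest],
                      se_c = setup$ss$se[rest], p_c = z_to_p(z),
                      log10_p_c = z_to_log10p(z)))
  }
  if (is.null(fit)) fit <- cojo_joint_fit(setup, sel)
  if (is.null(fit)) stop("ill-conditioned joint system for the conditioning set")
  Bcs <- setup$B[rest, sel, drop = FALSE]      # candidate x selected
  proj <- Bcs %*% fit$Binv                      # (r x k)
  dstar <- setup$D[rest] - rowSums(proj * Bcs)
  ok <- dstar > 1e-8 * setup$D[rest]
  beta_c <- se_c <- rep(NA_real_, length(rest))
  wc <- setup$w[rest] - drop(proj %*% setup$w[sel])
  beta_c[ok] <- wc[ok] / dstar[ok]
  se_c[ok] <- sqrt(fit$sigma2 / dstar[ok])
  z <- beta_c / se_c
  data.frame(idx = rest, beta_c = beta_c, se_c = se_c,
             p_c = z_to_p(z), log10_p_c = z_to_log10p(z))
}

#' Approximate stepwise selection of independently associated SNPs
#'
#' Iteratively adds the SNP with the smallest conditional p-value, refits
#' the joint model from marginal effects plus reference LD after each
#' addition, skips candidates in strong LD (r^2 above the collinearity
#' cutoff) with any selected SNP, treats SNPs farther apart than
#' `window_bp` as unlinked, and backward-eliminates selected SNPs whose
#' joint p-value rises above the cutoff.
#'
#' @param sumstats locus summary-statistics table (validated, with
#'   frequencies and case/control counts or an explicit `n`).
#' @param ld_ref `ld_reference` covering the SNPs.
#' @param p_cut stepwise p-value cutoff (default 1e-5).
#' @param collinearity r^2 cutoff above which a candidate is skipped
#'   (default 0.9).
#' @param window_bp distance beyond which LD is taken as zero (default 10 Mb).
#' @param n effective sample size override (scalar or per SNP).
#' @return object of class `cojo_model`: `selected` data.frame (snp_id,
#'   position, alleles, freq, marginal beta/se/p, bJ, bJ_se, pJ),
#'   `settings`, and `conditioned_marginals` -- one table per selected
#'   signal, conditioning on the other index SNPs.
#' @export
cojo_select <- function(sumstats, ld_ref, p_cut = 1e-5, collinearity = 0.9,
                        window_bp = 10e6, n = NULL) {
  setup <- cojo_setup(sumstats, ld_ref, n = n, window_bp = window_bp)
  m <- nrow(setup$ss)
  excluded <- logical(m)
  sel <- integer(0)
  fit <- NULL
  for (iter in seq_len(50L)) {
    rest <- setdiff(which(!excluded), sel)
    if (length(rest) == 0L) break
    if (length(sel) > 0L) {
      r2 <- (setup$R[rest, sel, drop = FALSE])^2
      collinear <- apply(r2, 1, max) > collinearity
      excluded[rest[collinear]] <- TRUE
      rest <- rest[!collinear]
      if (length(rest) == 0L) break
    }
    cond <- cojo_conditional(setup, sel, rest, fit = fit)
    ok <- !is.na(cond$p_c)
    if (!any(ok)) break
    cond <- cond[ok, , drop = FALSE]
    best <- cond[order(cond$log10_p_c, setup$ss$pos[cond$idx]), ][1L, ]
    if (best$p_c >= p_cut) break
    cand_fit <- cojo_joint_fit(setup, c(sel, best$idx))
    if (is.null(cand_fit)) {            # ill-conditioned: skip and log
      message("skipping ill-conditioned candidate ",
              setup$ss$snp_id[best$idx])
      excluded[best$idx] <- TRUE
      next
    }
    sel <- c(sel, best$idx)
    fit <- cand_fit
    # backward elimination
    while (length(sel) > 1L && max(fit$pJ) > p_cut) {
      drop_i <- which.max(fit$pJ)
      excluded[sel[drop_i]] <- TRUE
      sel <- sel[-drop_i]
      fit <- cojo_joint_fit(setup, sel)
    }
  }
  if (length(sel) == 0L) {
    model <- structure(list(
      selected = data.frame(), settings = list(p_cut = p_cut,
        collinearity = collinearity, window_bp = window_bp),
      conditioned_marginals = list()), class = "cojo_model")
    return(model)
  }
  fit <- cojo_joint_fit(setup, sel)
  ord <- order(setup$ss$pos[sel])
  sel <- sel[ord]
  fit <- cojo_joint_fit(setup, sel)
  ss <- setup$ss
  selected <- data.frame(
    snp_id = ss$snp_id[sel], chrom = ss$chrom[sel], pos = ss$pos[sel],
    a1 = ss$a1[sel], a2 = ss$a2[sel], freq_a1 = ss$freq_a1[sel],
    beta = ss$beta[sel], se = ss$se[sel], p = ss$p[sel],
    bJ = fit$bJ, bJ_se = fit$bJ_se, pJ = fit$pJ,
    log10_pJ = fit$log10_pJ, stringsAsFactors = FALSE
  )
  conditioned <- lapply(seq_along(sel), function(i) {
    others <- sel[-i]
    rest <- setdiff(seq_len(m), others)
    cond <- cojo_conditional(setup, others, rest)
    data.frame(snp_id = ss$snp_id[cond$idx], chrom = ss$chrom[cond$idx],
               pos = ss$pos[cond$idx], beta_c = cond$beta_c,
               se_c = cond$se_c, p_c = cond$p_c,
               log10_p_c = cond$log10_p_c, stringsAsFactors = FALSE)
  })
  names(conditioned) <- selected$snp_id
  structure(list(selected = selected,
                 settings = list(p_cut = p_cut, collinearity = collinearity,
                                 window_bp = window_bp),
                 conditioned_marginals = conditioned),
            class = "cojo_model")
}

#' @export
print.cojo_model <- function(x, ...) {
  cat("COJO model:", nrow(x$selected), "index SNP(s)\n")
  if (nrow(x$selected)) print(x$selected[, c("snp_id", "pos", "beta", "bJ",
                                             "bJ_se", "pJ")])
  invisible(x)
}

#' Conditional marginal statistics given a set of index SNPs
#'
#' For every SNP outside the conditioning set, returns its effect, SE and
#' p-value conditioned on the given index SNPs under the same
#' normal-equations approximation as [cojo_select()]. An empty conditioning
#' set returns the marginal statistics unchanged.
#'
#' @param sumstats locus summary-statistics table.
#' @param ld_ref `ld_reference` covering the SNPs.
#' @param condition_on character vector of index SNP ids (must be present
#'   in the reference).
#' @param window_bp LD window (default 10 Mb).
#' @param n effective sample size override.
#' @return data.frame with snp_id, chrom, pos, beta_c, se_c, p_c.
#' @export
cojo_cond <- function(sumstats, ld_ref, condition_on = character(),
                      window_bp = 10e6, n = NULL) {
  if (length(condition_on) == 0L) {
    out <- data.frame(snp_id = sumstats$snp_id, chrom = sumstats$chrom,
                      pos = sumstats$pos, beta_c = sumstats$beta,
                      se_c = sumstats$se, p_c = sumstats$p,
                      log10_p_c = sumstats$log10_p, stringsAsFactors = FALSE)
    return(out)
  }
  setup <- cojo_setup(sumstats, ld_ref, n = n, window_bp = window_bp)
  sel <- match(condition_on, setup$ss$snp_id)
  if (anyNA(sel)) stop("conditioning SNP(s) absent: ",
                       paste(condition_on[is.na(sel)], collapse = ", "))
  rest <- setdiff(seq_len(nrow(setup$ss)), sel)
  cond <- cojo_conditional(setup, sel, rest)
  data.frame(snp_id = setup$ss$snp_id[cond$idx],
             chrom = setup$ss$chrom[cond$idx],
             pos = setup$ss$pos[cond$idx],
             beta_c = cond$beta_c, se_c = cond$se_c, p_c = cond$p_c,
             log10_p_c = cond$log10_p_c, stringsAsFactors = FALSE)
}
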