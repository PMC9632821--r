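# Approximate-Bayes-factor colocalization under the single-causal-variant
# assumption, with the composite two-prior decision rule and per-signal
# colocalization of conditioned (fine-mapped) association signals.

#' Colocalization prior configuration
#'
#' @param p1,p2 per-SNP prior probability of association with trait 1 / 2
#'   only (defaults 1e-4).
#' @param p12 per-SNP prior probability of association with both traits
#'   (default 1e-5; the composite decision rule also evaluates 5e-5).
#' @param W1,W2 prior variance of the true effect for each trait; 0.2^2 on
#'   the log-odds scale is the canonical case-control choice, 0.15^2 the
#'   quantitative-trait one.
#' @return a named list of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         W1 = 0.04, W2 = 0.04) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p12 <= min(p1, p2),
            p1 + p2 + p12 < 1, W1 >= 0, W2 >= 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, W1 = W1, W2 = W2),
            class = "coloc_config")
}

#' Wakefield log approximate Bayes factor
#'
#' With V = se^2, r = W/(W+V) and z = beta/se:
#' lABF = (log(1 - r) + r z^2) / 2.
#'
#' @param beta,se effect and standard error (vectorized).
#' @param W prior variance of the true effect.
#' @return vector of log ABFs.
#' @export
labf <- function(beta, se, W) {
  stopifnot(all(se > 0))
  V <- se^2
  r <- W / (W + V)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization posteriors from per-SNP log ABFs
#'
#' Under one causal variant per trait, sums the prior-weighted likelihoods
#' of the five sharing hypotheses in log space (log-sum-exp throughout):
#' H0 no association, H1/H2 one trait only, H3 two distinct causal
#' variants, H4 one shared causal variant.
#'
#' @param labf_1,labf_2 aligned per-SNP log ABF vectors.
#' @param config a [coloc_config()].
#' @return object of class `coloc_posterior`: list with `pp` (named
#'   posterior vector PP.H0..PP.H4), the inputs and the config.
#' @export
coloc_abf <- function(labf_1, labf_2, config = coloc_config()) {
  if (length(labf_1) != length(labf_2))
    stop("log ABF vectors differ in length")
  l1 <- logsumexp(labf_1)
  l2 <- logsumexp(labf_2)
  l12 <- logsumexp(labf_1 + labf_2)
  lh <- c(
    H0 = 0,
    H1 = log(config$p1) + l1,
    H2 = log(config$p2) + l2,
    H3 = log(config$p1) + log(config$p2) + logdiffexp(l1 + l2, l12),
    H4 = log(config$p12) + l12
  )
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP.", names(lh))
  structure(list(pp = pp, labf_1 = labf_1, labf_2 = labf_2,
                 config = config, n_snps = length(labf_1)),
            class = "coloc_posterior")
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat("Colocalization over", x$n_snps, "SNPs (p12 =", x$config$p12, "):\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Colocalization of two summary-statistics tables at a locus
#'
#' Convenience wrapper: computes per-trait log ABFs with [labf()] on the
#' shared SNPs (assumed already harmonized) and calls [coloc_abf()].
#'
#' @param ss1,ss2 summary-statistics tables on identical SNPs.
#' @param config a [coloc_config()].
#' @return a `coloc_posterior`.
#' @export
coloc_sumstats <- function(ss1, ss2, config = coloc_config()) {
  stopifnot(nrow(ss1) == nrow(ss2))
  coloc_abf(labf(ss1$beta, ss1$se, config$W1),
            labf(ss2$beta, ss2$se, config$W2), config)
}

#' Composite two-prior sharing decision
#'
#' A signal pair is deemed to colocalize iff PP_H4 > 0.5 under the liberal
#' shared prior (p12 = 5e-5) AND PP_H3 < 0.5 under the default prior
#' (p12 = 1e-5). Both inequalities are strict.
#'
#' @param pp_at_p12_5e5 posterior computed with p12 = 5e-5.
#' @param pp_at_p12_1e5 posterior computed with p12 = 1e-5.
#' @return logical.
#' @export
shared_decision <- function(pp_at_p12_5e5, pp_at_p12_1e5) {
  unname(pp_at_p12_5e5$pp["PP.H4"] > 0.5 & pp_at_p12_1e5$pp["PP.H3"] < 0.5)
}

#' Strict sharing decision for published-locus checks
#'
#' @param pp a `coloc_posterior`.
#' @param bound strict lower bound on PP_H4 (default 0.9).
#' @return logical: PP_H4 strictly greater than `bound`.
#' @export
strict_shared_decision <- function(pp, bound = 0.9) {
  unname(pp$pp["PP.H4"] > bound)
}

#' Per-signal colocalization of fine-mapped loci
#'
#' When a locus carries multiple independent signals per trait, each
#' trait-1 signal's conditioned marginal statistics (conditioning on the
#' other index SNPs of that trait) are colocalized against each trait-2
#' signal's. With at most one selected signal (or an empty model) on a
#' side, that side falls back to its unconditioned statistics.
#'
#' @param ss1,ss2 locus summary-statistics tables on identical SNPs.
#' @param model1,model2 `cojo_model` objects for the two traits (NULL for
#'   unconditioned).
#' @param ld_ref locus `ld_reference` used for conditioning.
#' @param config a [coloc_config()].
#' @return list with `pp_matrix` (signals1 x signals2 PP_H4 matrix),
#'   `max_pp_h4`, `best` (indices of the best pair) and the per-pair
#'   `posteriors`.
#' @export
coloc_per_signal <- function(ss1, ss2, model1 = NULL, model2 = NULL,
                             ld_ref = NULL, config = coloc_config()) {
  signal_tables <- function(ss, model) {
    sel <- if (is.null(model)) character() else model$selected$snp_id
    if (length(sel) <= 1L) return(list(ss))
    lapply(seq_along(sel), function(i) {
      cond <- cojo_cond(ss, ld_ref, condition_on = sel[-i])
      data.frame(snp_id = cond$snp_id, beta = cond$beta_c, se = cond$se_c,
                 stringsAsFactors = FALSE)
    })
  }
  tabs1 <- signal_tables(ss1, model1)
  tabs2 <- signal_tables(ss2, model2)
  pp <- matrix(NA_real_, length(tabs1), length(tabs2))
  posts <- vector("list", length(tabs1) * length(tabs2))
  for (i in seq_along(tabs1)) for (j in seq_along(tabs2)) {
    t1 <- tabs1[[i]]; t2 <- tabs2[[j]]
    shared <- intersect(t1$snp_id, t2$snp_id)
    t1 <- t1[match(shared, t1$snp_id), ]
    t2 <- t2[match(shared, t2$snp_id), ]
    post <- coloc_abf(labf(t1$beta, t1$se, config$W1),
                      labf(t2$beta, t2$se, config$W2), config)
    pp[i, j] <- post$pp["PP.H4"]
    posts[[(i - 1L) * length(tabs2) + j]] <- post
  }
  best <- which(pp == max(pp), arr.ind = TRUE)[1, ]
  list(pp_matrix = pp, max_pp_h4 = max(pp),
       best = c(signal_1 = unname(best[1]), signal_2 = unname(best[2])),
       posteriors = posts)
}
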