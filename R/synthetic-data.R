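# Two-trait GWAS simulator with LD-blocked correlation structure and a
# planted pleiotropic architecture. Two routes are provided:
#   * simulate_sumstats(): draws marginal z-scores directly from their
#     sampling distribution z_t ~ MVN(sqrt(N_t) R b_t, R), with a
#     cross-trait noise covariance (Ns * rho / sqrt(N1 N2)) R when samples
#     overlap -- fast enough for genome-scale calibration runs;
#   * simulate_individual(): draws genotypes from a Gaussian-copula
#     discretization of MVN(0, R) and regresses simulated quantitative
#     liabilities SNP by SNP -- the slow route used as an oracle for the
#     fast one and for fine-mapping checks.
# Effects are on the standardized-genotype / unit-variance-phenotype scale
# throughout; betas and SEs are back-computed per SNP as
#   se = 1 / sqrt(2 f (1-f) N),  beta = z * se.

CAUSAL_LABELS <- c("none", "shared_aligned", "shared_opposing",
                   "trait1_only", "trait2_only")

#' Specify a synthetic two-trait GWAS architecture
#'
#' @param blocks data.frame with columns `size` and `rho`: LD blocks with
#'   AR(1) within-block correlation rho^|i-j|.
#' @param causal named or unnamed character vector (length = total SNPs) of
#'   labels in `none`, `shared_aligned`, `shared_opposing`, `trait1_only`,
#'   `trait2_only`; or a data.frame with columns `index` and `label`
#'   (all other SNPs `none`).
#' @param effect_scale length-2 standardized effect-size s.d. for causal
#'   SNPs, one per trait. Shared labels use one draw for trait 1 and scale
#'   it (with sign flip for `shared_opposing`) for trait 2.
#' @param n1,n2 effective sample sizes per trait.
#' @param n_overlap number of samples shared between the two studies.
#' @param pheno_corr phenotypic correlation among overlapping samples.
#' @param maf_range range from which reference allele frequencies are drawn.
#' @param chrom chromosome label for the simulated region.
#' @param pos_start,pos_step base-pair coordinates: SNP i sits at
#'   pos_start + (i-1) * pos_step.
#' @param seed integer seed; all downstream draws are deterministic in it.
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(blocks, causal = NULL,
                              effect_scale = c(0.1, 0.1),
                              n1 = 10000, n2 = 10000,
                              n_overlap = 0, pheno_corr = 0,
                              maf_range = c(0.05, 0.5),
                              chrom = "1", pos_start = 1000000L,
                              pos_step = 1000L, seed = 1L) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("size", "rho") %in% names(blocks)),
            all(blocks$size >= 1), all(abs(blocks$rho) < 1))
  m <- sum(blocks$size)
  lab <- rep("none", m)
  if (!is.null(causal)) {
    if (is.data.frame(causal)) {
      lab[causal$index] <- as.character(causal$label)
    } else {
      stopifnot(length(causal) == m)
      lab <- as.character(causal)
    }
  }
  if (!all(lab %in% CAUSAL_LABELS))
    stop("unknown causal label(s): ",
         paste(setdiff(lab, CAUSAL_LABELS), collapse = ", "))
  if (n_overlap > min(n1, n2)) stop("n_overlap exceeds min(n1, n2)")
  structure(list(blocks = blocks, causal = lab,
                 effect_scale = rep_len(effect_scale, 2),
                 n1 = n1, n2 = n2, n_overlap = n_overlap,
                 pheno_corr = pheno_corr, maf_range = maf_range,
                 chrom = chrom, pos_start = as.integer(pos_start),
                 pos_step = as.integer(pos_step), seed = as.integer(seed)),
            class = "architecture_spec")
}

#' Read an architecture specification from YAML
#' @param path YAML file with the fields of [architecture_spec()].
#' @return an `architecture_spec`.
#' @export
read_architecture_spec <- function(path) {
  y <- yaml::read_yaml(path)
  y$blocks <- do.call(rbind, lapply(y$blocks, as.data.frame))
  if (!is.null(y$causal)) y$causal <- do.call(rbind, lapply(y$causal, as.data.frame))
  do.call(architecture_spec, y)
}

#' Build the block-diagonal AR(1) LD reference of an architecture
#'
#' Within block b, r(i, j) = rho_b^|i-j|; cross-block correlation is zero.
#' Frequencies are Uniform(maf_range) per SNP, deterministic in the seed.
#'
#' @param spec an `architecture_spec`.
#' @return an `ld_reference` with one AR(1) block per spec block and
#'   `n_ref = Inf` (a population, not sampled, panel).
#' @export
make_ld_blocks <- function(spec) {
  m <- sum(spec$blocks$size)
  rng <- local({
    set.seed(substream_seed(spec$seed, 1L))
    stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  })
  R_blocks <- lapply(seq_len(nrow(spec$blocks)), function(b) {
    mb <- spec$blocks$size[b]
    rho <- spec$blocks$rho[b]
    rho^abs(outer(seq_len(mb), seq_len(mb), "-"))
  })
  ld_reference(
    snp_ids = sprintf("rs%06d", seq_len(m)),
    chrom = spec$chrom,
    pos = spec$pos_start + (seq_len(m) - 1L) * spec$pos_step,
    freqs = rng, R_blocks = R_blocks, n_ref = Inf
  )
}

#' True standardized effect vectors of an architecture
#'
#' Causal SNPs get effects drawn N(0, s_t^2); shared labels reuse the trait-1
#' draw, rescaled by s_2/s_1 and negated for `shared_opposing`.
#' @keywords internal
true_effects <- function(spec) {
  m <- length(spec$causal)
  set.seed(substream_seed(spec$seed, 2L))
  s <- spec$effect_scale
  b1 <- numeric(m); b2 <- numeric(m)
  draw <- stats::rnorm(m)
  shared <- spec$causal %in% c("shared_aligned", "shared_opposing")
  b1[shared | spec$causal == "trait1_only"] <-
    s[1] * draw[shared | spec$causal == "trait1_only"]
  b2[shared] <- (s[2] / s[1]) * b1[shared] *
    ifelse(spec$causal[shared] == "shared_opposing", -1, 1)
  t2only <- spec$causal == "trait2_only"
  b2[t2only] <- s[2] * stats::rnorm(sum(t2only))
  list(b1 = b1, b2 = b2)
}

#' @keywords internal
sumstats_from_z <- function(z, freqs, n, ld_ref, n_cases = NULL,
                            n_controls = NULL) {
  se <- 1 / sqrt(2 * freqs * (1 - freqs) * n)
  data.frame(
    snp_id = ld_ref$snp_ids, chrom = ld_ref$chrom, pos = ld_ref$pos,
    a1 = "A", a2 = "G", freq_a1 = freqs,
    beta = z * se, se = se, p = z_to_p(z),
    n_cases = n_cases %||% (n / 2), n_controls = n_controls %||% (n / 2),
    info = 1, log10_p = z_to_log10p(z),
    stringsAsFactors = FALSE
  )
}

#' Simulate two-trait marginal summary statistics
#'
#' Per trait t the z-score vector is drawn block-wise from
#' MVN(sqrt(N_t) R b_t, R); overlapping samples add the cross-trait noise
#' covariance c R with c = n_overlap * pheno_corr / sqrt(n1 n2). The same
#' standard-normal increments are reused blockwise via
#' z2 = mean2 + c e1 + sqrt(1 - c^2) e2 so the joint draw is exact.
#'
#' @param spec an `architecture_spec`.
#' @param ld_ref the matching `ld_reference` (built if omitted).
#' @param truth optional list(b1, b2) of standardized effects overriding the
#'   architecture's own draw.
#' @return object of class `synthetic_cohort`: list with `ld_ref`, `truth`,
#'   `sumstats_1`, `sumstats_2`.
#' @export
simulate_sumstats <- function(spec, ld_ref = NULL, truth = NULL) {
  if (is.null(ld_ref)) ld_ref <- make_ld_blocks(spec)
  m <- length(ld_ref$snp_ids)
  stopifnot(length(spec$causal) == m)
  if (is.null(truth)) truth <- true_effects(spec)
  cc <- spec$n_overlap * spec$pheno_corr / sqrt(spec$n1 * spec$n2)
  if (abs(cc) >= 1)
    stop("overlap setting gives non-positive-definite joint covariance: ",
         "n_overlap=", spec$n_overlap, ", pheno_corr=", spec$pheno_corr)
  set.seed(substream_seed(spec$seed, 3L))
  z1 <- numeric(m); z2 <- numeric(m)
  off <- 0L
  for (R in ld_ref$R_blocks) {
    mb <- nrow(R); idx <- off + seq_len(mb)
    L <- chol(R)  # upper triangular, R = t(L) %*% L
    mu1 <- sqrt(spec$n1) * drop(R %*% truth$b1[idx])
    mu2 <- sqrt(spec$n2) * drop(R %*% truth$b2[idx])
    e1 <- drop(t(L) %*% stats::rnorm(mb))
    e2 <- drop(t(L) %*% stats::rnorm(mb))
    z1[idx] <- mu1 + e1
    z2[idx] <- mu2 + cc * e1 + sqrt(1 - cc^2) * e2
    off <- off + mb
  }
  structure(list(
    ld_ref = ld_ref, truth = truth,
    sumstats_1 = sumstats_from_z(z1, ld_ref$freqs, spec$n1, ld_ref),
    sumstats_2 = sumstats_from_z(z2, ld_ref$freqs, spec$n2, ld_ref)
  ), class = "synthetic_cohort")
}

#' Gaussian-copula dosage draw for one LD block
#'
#' Thresholding the latent Gaussian attenuates pairwise correlation by the
#' factor a_i a_j, where a_j = (phi(t0) + phi(t1)) / sqrt(2 f (1-f)) is the
#' dosage-latent correlation; the latent correlation is pre-inflated by
#' 1/(a_i a_j) (to first order) so the realized dosage LD matches the
#' target R. If inflation breaks positive-definiteness it is shrunk back
#' toward the target until the Cholesky factor exists.
#' @keywords internal
draw_dosages <- function(n, R, freqs) {
  t0 <- stats::qnorm((1 - freqs)^2)
  t1 <- stats::qnorm(1 - freqs^2)
  a <- (stats::dnorm(t0) + stats::dnorm(t1)) /
    sqrt(2 * freqs * (1 - freqs))
  infl <- pmin(pmax(R / outer(a, a), -0.99), 0.99)
  diag(infl) <- 1
  L <- NULL
  for (w in seq(1, 0, by = -0.1)) {
    Rl <- w * infl + (1 - w) * R
    diag(Rl) <- 1
    L <- tryCatch(chol(Rl), error = function(e) NULL)
    if (!is.null(L)) break
  }
  Z <- matrix(stats::rnorm(n * nrow(R)), n) %*% L
  G <- matrix(0L, n, nrow(R))
  for (j in seq_len(nrow(R))) {
    f <- freqs[j]
    # HWE genotype probabilities; thresholds on the latent standard normal
    t0 <- stats::qnorm((1 - f)^2)
    t1 <- stats::qnorm((1 - f)^2 + 2 * f * (1 - f))
    G[, j] <- (Z[, j] > t0) + (Z[, j] > t1)
  }
  G
}

#' Fast per-SNP marginal regression of a phenotype on dosage columns
#' @keywords internal
marginal_gwas <- function(G, y) {
  n <- length(y)
  gm <- colMeans(G)
  gv <- colMeans(G^2) - gm^2          # MLE variance, n denominator
  gv[gv <= 0] <- NA
  cov_gy <- drop(crossprod(G, y - mean(y))) / n
  beta <- cov_gy / gv
  vy <- stats::var(y) * (n - 1) / n
  resid_var <- pmax(vy - beta * cov_gy, 1e-12)
  se <- sqrt(resid_var / (gv * (n - 2)))
  list(beta = beta, se = se)
}

#' Simulate individual-level genotypes and phenotypes, then run the GWAS
#'
#' Dosages come from a Gaussian-copula discretization of MVN(0, R) into
#' \{0,1,2\} at the reference frequencies; quantitative liability phenotypes
#' are y = X_std b + e with Var(e) chosen so the phenotype has unit variance;
#' per-SNP least-squares on the raw dosage then yields summary statistics.
#' The first `n_overlap` samples (and their noise, correlated at
#' `pheno_corr`) are shared between the two studies.
#'
#' @param spec an `architecture_spec` with n1, n2 <= 5000.
#' @param ld_ref matching `ld_reference` (built if omitted).
#' @param truth optional list(b1, b2) of standardized effects.
#' @return a `synthetic_cohort` with extra elements `genotypes_1`,
#'   `genotypes_2`, `pheno_1`, `pheno_2`.
#' @export
simulate_individual <- function(spec, ld_ref = NULL, truth = NULL) {
  if (spec$n1 > 5000 || spec$n2 > 5000)
    stop("individual-level simulation is bounded at n <= 5000 per trait")
  if (is.null(ld_ref)) ld_ref <- make_ld_blocks(spec)
  m <- length(ld_ref$snp_ids)
  if (is.null(truth)) truth <- true_effects(spec)
  set.seed(substream_seed(spec$seed, 4L))
  ns <- spec$n_overlap
  n_tot <- spec$n1 + spec$n2 - ns  # shared samples drawn once
  G <- matrix(0L, n_tot, m, dimnames = list(NULL, ld_ref$snp_ids))
  off <- 0L
  for (b in seq_along(ld_ref$R_blocks)) {
    R <- ld_ref$R_blocks[[b]]
    idx <- off + seq_len(nrow(R))
    G[, idx] <- draw_dosages(n_tot, R, ld_ref$freqs[idx])
    off <- off + nrow(R)
  }
  i1 <- seq_len(spec$n1)
  i2 <- c(seq_len(ns), spec$n1 + seq_len(spec$n2 - ns))
  make_pheno <- function(rows, b, eps) {
    X <- G[rows, , drop = FALSE]
    Xs <- scale(X)               # standardized genotypes
    Xs[is.na(Xs)] <- 0           # monomorphic draws carry no effect
    g <- drop(Xs %*% b)
    ve <- max(1 - sum(b^2), 0.05)
    g + sqrt(ve) * eps
  }
  eps_sh <- stats::rnorm(ns)
  eps1 <- c(eps_sh, stats::rnorm(spec$n1 - ns))
  rho <- spec$pheno_corr
  eps2_sh <- rho * eps_sh + sqrt(1 - rho^2) * stats::rnorm(ns)
  eps2 <- c(eps2_sh, stats::rnorm(spec$n2 - ns))
  y1 <- make_pheno(i1, truth$b1, eps1)
  y2 <- make_pheno(i2, truth$b2, eps2)
  g1 <- marginal_gwas(G[i1, , drop = FALSE], y1)
  g2 <- marginal_gwas(G[i2, , drop = FALSE], y2)
  ss <- function(gw, n) {
    z <- gw$beta / gw$se
    out <- sumstats_from_z(z, ld_ref$freqs, n, ld_ref)
    out$beta <- gw$beta; out$se <- gw$se   # keep the raw per-allele scale
    out
  }
  structure(list(
    ld_ref = ld_ref, truth = truth,
    sumstats_1 = ss(g1, spec$n1), sumstats_2 = ss(g2, spec$n2),
    genotypes_1 = G[i1, , drop = FALSE], genotypes_2 = G[i2, , drop = FALSE],
    pheno_1 = y1, pheno_2 = y2
  ), class = "synthetic_cohort")
}

#' Simulate an infinitesimal (polygenic) two-trait architecture
#'
#' Every SNP is causal with per-SNP standardized effects drawn bivariate
#' normal with variances h2_t / M and cross-trait correlation rg -- the
#' generative model under which LD score regression is calibrated. Returns
#' marginal summary statistics via [simulate_sumstats()].
#'
#' @param ld_ref an `ld_reference`.
#' @param h2_1,h2_2 genome(-segment)-wide SNP heritabilities.
#' @param rg true genetic correlation.
#' @param n1,n2 effective sample sizes.
#' @param n_overlap,pheno_corr sample-overlap structure as in
#'   [architecture_spec()].
#' @param seed integer seed.
#' @return a `synthetic_cohort`.
#' @export
simulate_polygenic_pair <- function(ld_ref, h2_1, h2_2, rg, n1, n2,
                                    n_overlap = 0, pheno_corr = 0, seed = 1L) {
  m <- length(ld_ref$snp_ids)
  set.seed(substream_seed(seed, 5L))
  s1 <- sqrt(h2_1 / m); s2 <- sqrt(h2_2 / m)
  u <- stats::rnorm(m); v <- stats::rnorm(m)
  b1 <- s1 * u
  b2 <- s2 * (rg * u + sqrt(1 - rg^2) * v)
  spec <- architecture_spec(
    blocks = data.frame(size = m, rho = 0),  # placeholder; ld_ref rules
    n1 = n1, n2 = n2, n_overlap = n_overlap, pheno_corr = pheno_corr,
    seed = substream_seed(seed, 6L)
  )
  spec$causal <- rep("none", m)
  simulate_sumstats(spec, ld_ref, truth = list(b1 = b1, b2 = b2))
}

#' Write a synthetic cohort's summary statistics to disk
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return paths of the two written tables.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "trait1.sumstats.tsv")
  p2 <- file.path(dir, "trait2.sumstats.tsv")
  write_sumstats(cohort$sumstats_1, p1)
  write_sumstats(cohort$sumstats_2, p2)
  c(p1, p2)
}
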