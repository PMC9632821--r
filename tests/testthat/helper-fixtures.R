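# Shared fixtures and independent oracles, built in code at test time.

# A small valid summary-statistics table with reproducible random content.
toy_sumstats <- function(n = 10, seed = 1, chrom = "1", pos0 = 1e6) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, n, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1), character(1))
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.01, 0.05)
  df <- data.frame(
    snp_id = sprintf("rs%04d", seq_len(n)), chrom = chrom,
    pos = pos0 + seq_len(n) * 1000L, a1 = a1, a2 = unname(a2),
    freq_a1 = runif(n, 0.05, 0.95), beta = beta, se = se,
    p = 2 * pnorm(-abs(beta / se)), n_cases = 1000, n_controls = 2000,
    info = 1, stringsAsFactors = FALSE
  )
  validate_sumstats(df)
}

# Brute-force colocalization oracle: enumerate every causal configuration
# (none/none, i/none, none/j, i/j distinct, i/i shared) with its prior
# weight and Bayes factor product, then normalize. Independent of the
# log-sum-exp implementation: plain arithmetic on exp(lABF).
coloc_enum_oracle <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(labf1)
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  s <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(m)) s["H1"] <- s["H1"] + p1 * bf1[i]
  for (j in seq_len(m)) s["H2"] <- s["H2"] + p2 * bf2[j]
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) s["H4"] <- s["H4"] + p12 * bf1[i] * bf2[j]
    else s["H3"] <- s["H3"] + p1 * p2 * bf1[i] * bf2[j]
  }
  s / sum(s)
}

# Two-signal fine-mapping architecture: one AR(1) block in which the two
# causal SNPs sit two steps apart so their LD is rho^2 (r^2 = rho^4).
two_signal_spec <- function(seed, n = 2000, m = 50, rho = 0.55,
                            b = 0.15, opposing = FALSE) {
  ca <- c(10L, 12L)
  spec <- architecture_spec(
    blocks = data.frame(size = m, rho = rho),
    causal = data.frame(index = ca,
                        label = if (opposing) "shared_opposing" else "shared_aligned"),
    n1 = n, n2 = n, seed = seed
  )
  # fixed-size effects (the architecture's own draw is Gaussian)
  truth <- list(b1 = numeric(m), b2 = numeric(m))
  truth$b1[ca] <- b
  truth$b2[ca] <- if (opposing) -b else b
  list(spec = spec, truth = truth, causal = ca)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
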