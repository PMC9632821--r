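# Reading, validation, harmonization and genomic inflation.

test_that("odds-ratio dialect converts to log scale with CI-derived SE", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = "rs7960611", chr = "12", bp = 10230416,
                   ea = "G", oa = "A", eaf = 0.12,
                   OR = 1.14, L95 = 1.09, U95 = 1.19, pval = 8.02e-9)
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- sumstats_dialect(snp_id = "rsid", chrom = "chr", pos = "bp",
                        a1 = "ea", a2 = "oa", freq_a1 = "eaf",
                        beta = "OR", p = "pval", effect = "or",
                        ci_lower = "L95", ci_upper = "U95")
  ss <- read_sumstats(tf, d)
  expect_equal(ss$beta, log(1.14))
  expect_equal(ss$se, (log(1.19) - log(1.09)) / (2 * 1.959964))
})

test_that("write/read round trip is the identity on canonical columns", {
  ss <- toy_sumstats(10, seed = 7)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, tf)
  back <- read_sumstats(tf)
  for (col in c("snp_id", "chrom", "a1", "a2")) {
    expect_identical(back[[col]], ss[[col]])
  }
  for (col in c("pos", "freq_a1", "beta", "se", "n_cases", "n_controls")) {
    expect_equal(back[[col]], ss[[col]], tolerance = 1e-12)
  }
})

test_that("invalid rows are dropped and counted", {
  ss <- toy_sumstats(6, seed = 3)
  ss$se[2] <- 0
  ss$freq_a1[4] <- 1.2
  ss$a2[5] <- ss$a1[5]
  out <- validate_sumstats(ss)
  expect_equal(nrow(out), 3)
  expect_equal(unname(attr(out, "report")["n_dropped"]), 3)
})

test_that("missing mandatory columns give a hard error naming the column", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(snp_id = "rs1", chrom = "1"), tf, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(tf), "pos")
})

test_that("harmonization aligns swapped alleles by negating beta", {
  t1 <- toy_sumstats(1, seed = 1)
  t1$a1 <- "G"; t1$a2 <- "A"; t1$beta <- 0.10; t1$freq_a1 <- 0.3
  t2 <- t1
  t2$a1 <- "A"; t2$a2 <- "G"; t2$beta <- -0.10; t2$freq_a1 <- 0.7
  pair <- harmonize_pair(validate_sumstats(t1), validate_sumstats(t2))
  expect_equal(pair$records_2$beta, 0.10)
  expect_equal(pair$records_2$a1, "G")
  expect_equal(pair$records_2$freq_a1, 0.3)
  expect_equal(unname(pair$report["n_flipped_allele"]), 1)
})

test_that("harmonization complements strand-flipped alleles, sign kept", {
  t1 <- toy_sumstats(1, seed = 1)
  t1$a1 <- "C"; t1$a2 <- "T"; t1$beta <- 0.05; t1$freq_a1 <- 0.2
  t2 <- t1
  t2$a1 <- "G"; t2$a2 <- "A"  # reverse complement of (C, T)
  pair <- harmonize_pair(validate_sumstats(t1), validate_sumstats(t2))
  expect_equal(pair$records_2$a1, "C")
  expect_equal(pair$records_2$a2, "T")
  expect_equal(pair$records_2$beta, 0.05)
  expect_equal(unname(pair$report["n_strand_flipped"]), 1)
})

test_that("near-0.5 palindromic SNPs are dropped as strand-ambiguous", {
  t1 <- toy_sumstats(2, seed = 2)
  t1$a1 <- c("A", "C"); t1$a2 <- c("T", "G")
  t1$freq_a1 <- c(0.49, 0.10)
  t2 <- t1
  pair <- harmonize_pair(validate_sumstats(t1), validate_sumstats(t2),
                         ambiguity_maf_bound = 0.40)
  expect_equal(nrow(pair$records_1), 1)
  expect_equal(pair$records_1$a1, "C")
  expect_equal(unname(pair$report["n_dropped_ambiguous"]), 1)
})

test_that("harmonize_pair is idempotent and sign-equivariant", {
  t1 <- toy_sumstats(30, seed = 11)
  t2 <- toy_sumstats(30, seed = 11)
  set.seed(5)
  flip <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  tmp <- t2$a1[flip]; t2$a1[flip] <- t2$a2[flip]; t2$a2[flip] <- tmp
  t2$beta[flip] <- -t2$beta[flip]
  t2$freq_a1[flip] <- 1 - t2$freq_a1[flip]
  p1 <- harmonize_pair(t1, t2)
  p2 <- harmonize_pair(p1$records_1, p1$records_2)
  expect_equal(p2$records_2$beta, p1$records_2$beta)
  expect_equal(p2$records_2$a1, p1$records_2$a1)
  expect_equal(nrow(p2$records_1), nrow(p1$records_1))
  # negating t2's betas before harmonizing equals negating after
  t2n <- t2; t2n$beta <- -t2n$beta
  pn <- harmonize_pair(t1, t2n)
  expect_equal(pn$records_2$beta, -p1$records_2$beta)
})

test_that("genomic lambda is 1 at the null median and under uniform p", {
  expect_equal(genomic_lambda(rep(0.5, 5)), 1)
  set.seed(101)
  expect_lt(abs(genomic_lambda(runif(1e6)) - 1), 0.01)
  expect_error(genomic_lambda(numeric(0)))
})

test_that("genomic lambda tracks uniform inflation of z^2 scores", {
  set.seed(7)
  z <- rnorm(2e5)
  p_inflated <- 2 * pnorm(-abs(z * sqrt(1.1)))
  expect_lt(abs(genomic_lambda(p_inflated) - 1.1), 0.02)
  # permutation invariance and monotonicity
  p <- 2 * pnorm(-abs(z))
  expect_equal(genomic_lambda(p), genomic_lambda(rev(p)))
  expect_gt(genomic_lambda(p_inflated), genomic_lambda(p))
})

test_that("lambda_1000 rescaling matches its closed form", {
  expect_equal(lambda_1000(1, 123, 4567), 1)
  expect_equal(lambda_1000(1.1, 1000, 1000), 1.1)
  expect_equal(lambda_1000(1.2, 2000, 2000), 1.1)
})

test_that("ld_matrix equals brute-force pairwise Pearson correlation", {
  set.seed(21)
  n <- 40; m <- 8
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  G[sample(length(G), 12)] <- NA
  ref <- ld_matrix(G)
  # brute force: mean-impute, then pairwise cor
  Gi <- apply(G, 2, function(g) { g[is.na(g)] <- mean(g, na.rm = TRUE); g })
  R_oracle <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) R_oracle[i, j] <- cor(Gi[, i], Gi[, j])
  expect_close(as.matrix(ref), R_oracle, 1e-12)
  expect_equal(ref$freqs, colMeans(Gi) / 2)
})

test_that("ld_matrix handles perfect LD, monomorphic and independent SNPs", {
  set.seed(8)
  g <- rbinom(500, 2, 0.4)
  G <- cbind(a = g, b = g, c = rbinom(500, 2, 0.4), d = rep(1L, 500))
  ref <- ld_matrix(G)
  R <- as.matrix(ref)
  expect_equal(R["a", "b"], 1)
  expect_lt(abs(R["a", "c"]), 0.15)  # independent draws, n = 500
  expect_equal(R["d", "a"], 0)       # monomorphic: zeroed off-diagonal
  expect_true(ref$monomorphic[4])
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  # duplicating samples leaves the correlation unchanged
  ref2 <- ld_matrix(rbind(G, G))
  expect_close(as.matrix(ref2), R, 1e-12)
})

test_that("PLINK bed/bim/fam round trip preserves dosages", {
  set.seed(31)
  G <- matrix(rbinom(60, 2, 0.35), 12, 5,
              dimnames = list(NULL, sprintf("snp%d", 1:5)))
  G[2, 3] <- NA
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_plink(G, prefix, pos = 101:105)
  back <- read_plink(prefix)
  expect_equal(unname(back$genotypes), unname(G))
  expect_equal(back$bim$pos, 101:105)
})
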