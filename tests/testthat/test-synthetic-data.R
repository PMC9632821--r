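# Calibration and determinism of the two-trait GWAS simulator.

test_that("AR(1) LD blocks have the closed-form structure", {
  spec <- architecture_spec(blocks = data.frame(size = c(3, 4),
                                                rho = c(0.5, 0)), seed = 1)
  R <- as.matrix(make_ld_blocks(spec))
  expect_equal(unname(R[1, 1:3]), c(1, 0.5, 0.25))
  expect_equal(unname(R[4:7, 4:7]), diag(4))       # rho = 0: identity
  expect_equal(unname(R[1:3, 4:7]), matrix(0, 3, 4))  # cross-block zero
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- architecture_spec(blocks = data.frame(size = 10, rho = 0.4),
                            causal = data.frame(index = 3, label = "shared_opposing"),
                            n1 = 1000, n2 = 1000, seed = 99)
  a <- simulate_sumstats(spec)
  b <- simulate_sumstats(spec)
  expect_identical(a$sumstats_1, b$sumstats_1)
  expect_identical(a$sumstats_2, b$sumstats_2)
  ia <- simulate_individual(spec)
  ib <- simulate_individual(spec)
  expect_identical(ia$genotypes_1, ib$genotypes_1)
  expect_identical(ia$sumstats_2, ib$sumstats_2)
})

test_that("null z-scores are calibrated: mean 0, variance 1, no cross-trait corr", {
  spec0 <- architecture_spec(blocks = data.frame(size = c(10, 10),
                                                 rho = c(0.5, 0.2)),
                             n1 = 5000, n2 = 5000, seed = 1)
  z1 <- z2 <- matrix(NA_real_, 500, 20)
  for (r in 1:500) {
    spec0$seed <- r
    co <- simulate_sumstats(spec0)
    z1[r, ] <- co$sumstats_1$beta / co$sumstats_1$se
    z2[r, ] <- co$sumstats_2$beta / co$sumstats_2$se
  }
  expect_lt(max(abs(colMeans(z1))), 0.2)
  expect_lt(abs(mean(z1)), 0.05)
  expect_lt(abs(mean(apply(z1, 2, var)) - 1), 0.1)
  expect_lt(abs(cor(as.vector(z1), as.vector(z2))), 0.05)
})

test_that("planted causal SNP gives E[z] = sqrt(n) R b, averaged over replicates", {
  base <- architecture_spec(blocks = data.frame(size = 5, rho = 0.6),
                            n1 = 1000, n2 = 1000, seed = 1)
  b <- numeric(5); b[3] <- 0.08
  R <- as.matrix(make_ld_blocks(base))
  target <- sqrt(1000) * drop(R %*% b)
  zbar <- numeric(5)
  for (r in 1:1000) {
    base$seed <- r
    co <- simulate_sumstats(base, truth = list(b1 = b, b2 = numeric(5)))
    zbar <- zbar + co$sumstats_1$beta / co$sumstats_1$se
  }
  zbar <- zbar / 1000
  expect_close(zbar, target, 0.15)  # MC error of a mean of 1000 N(.,1) draws
})

test_that("sample overlap induces the stated cross-trait noise covariance", {
  spec <- architecture_spec(blocks = data.frame(size = 10, rho = 0),
                            n1 = 4000, n2 = 4000, n_overlap = 2000,
                            pheno_corr = 0.8, seed = 1)
  cc <- 2000 * 0.8 / 4000  # Ns * rho / sqrt(n1 n2) = 0.4
  z1 <- z2 <- matrix(NA_real_, 400, 10)
  for (r in 1:400) {
    spec$seed <- r
    co <- simulate_sumstats(spec)
    z1[r, ] <- co$sumstats_1$beta / co$sumstats_1$se
    z2[r, ] <- co$sumstats_2$beta / co$sumstats_2$se
  }
  expect_lt(abs(cor(as.vector(z1), as.vector(z2)) - cc), 0.05)
  # an impossible overlap setting is rejected with a clear error
  bad <- architecture_spec(blocks = data.frame(size = 2, rho = 0),
                           n1 = 100, n2 = 100, n_overlap = 100,
                           pheno_corr = 1.2, seed = 1)
  expect_error(simulate_sumstats(bad), "overlap")
})

test_that("copula dosages reproduce the target LD within sampling error", {
  spec <- architecture_spec(blocks = data.frame(size = 20, rho = 0.5),
                            n1 = 2000, n2 = 2000, seed = 5)
  co <- simulate_individual(spec)
  R_emp <- cor(co$genotypes_1)
  R_tgt <- as.matrix(co$ld_ref)
  expect_lt(max(abs(R_emp - R_tgt)), 0.1)
  f_emp <- colMeans(co$genotypes_1) / 2
  expect_close(f_emp, co$ld_ref$freqs, 0.05)
})

test_that("null individual-level p-values are uniform", {
  ks <- replicate(10, {
    seed <- sample.int(1e6, 1)
    spec <- architecture_spec(blocks = data.frame(size = 200, rho = 0),
                              n1 = 500, n2 = 500, seed = seed)
    co <- simulate_individual(spec)
    suppressWarnings(ks.test(co$sumstats_1$p, "punif")$p.value)
  })
  set.seed(404)
  expect_gte(sum(ks > 0.01), 8)
})

test_that("marginal-summary and individual-level routes agree in moments", {
  # same architecture through both routes: compare mean and covariance of z
  m <- 10; n <- 1000; reps <- 300
  b <- numeric(m); b[4] <- 0.1
  spec <- architecture_spec(blocks = data.frame(size = m, rho = 0.5),
                            n1 = n, n2 = n, seed = 2)
  ref <- make_ld_blocks(spec)
  zi <- zs <- matrix(NA_real_, reps, m)
  for (r in seq_len(reps)) {
    spec$seed <- r + 1000
    ind <- simulate_individual(spec, ref, truth = list(b1 = b, b2 = numeric(m)))
    zi[r, ] <- ind$sumstats_1$beta / ind$sumstats_1$se
    sum_ <- simulate_sumstats(spec, ref, truth = list(b1 = b, b2 = numeric(m)))
    zs[r, ] <- sum_$sumstats_1$beta / sum_$sumstats_1$se
  }
  # discretizing the latent Gaussian attenuates LD slightly, so compare
  # against moments computed from the realized dosage correlation
  expect_lt(max(abs(colMeans(zi) - colMeans(zs))), 0.35)
  expect_lt(abs(mean(apply(zi, 2, var)) - 1), 0.15)
  expect_lt(max(abs(cor(zi) - cor(zs))), 0.25)
})

test_that("downstream per-SNP type-I error is nominal on null architecture", {
  spec <- architecture_spec(blocks = data.frame(size = rep(100, 100), rho = 0),
                            n1 = 2000, n2 = 2000, seed = 17)
  co <- simulate_sumstats(spec)
  rate <- mean(co$sumstats_1$p < 0.05)
  expect_gte(rate, 0.04); expect_lte(rate, 0.06)
})

test_that("polygenic pair plants the requested cross-trait effect correlation", {
  spec <- architecture_spec(blocks = data.frame(size = 2000, rho = 0), seed = 3)
  ref <- make_ld_blocks(spec)
  co <- simulate_polygenic_pair(ref, h2_1 = 0.4, h2_2 = 0.4, rg = 0.56,
                                n1 = 5e4, n2 = 5e4, seed = 12)
  expect_lt(abs(cor(co$truth$b1, co$truth$b2) - 0.56), 0.05)
  expect_lt(abs(sum(co$truth$b1^2) - 0.4), 0.05)
})

test_that("architecture specs survive a YAML round trip", {
  spec <- architecture_spec(blocks = data.frame(size = c(5, 5), rho = c(0.3, 0)),
                            causal = data.frame(index = 2L, label = "trait1_only"),
                            n1 = 1234, n2 = 4321, seed = 77)
  tf <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    blocks = lapply(seq_len(2), function(i) as.list(spec$blocks[i, ])),
    causal = list(list(index = 2L, label = "trait1_only")),
    n1 = 1234, n2 = 4321, seed = 77L), tf)
  back <- read_architecture_spec(tf)
  expect_equal(back$blocks$rho, spec$blocks$rho)
  expect_equal(back$causal, spec$causal)
  expect_identical(simulate_sumstats(back)$sumstats_1,
                   simulate_sumstats(spec)$sumstats_1)
})
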