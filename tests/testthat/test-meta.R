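# Fixed-effect pooling, the opposing-effect mode, concordance filtering
# and candidate-locus discovery.

test_that("pooling two identical inputs gives (beta, se/sqrt(2))", {
  out <- ivw_meta(c(0.2, 0.2), c(0.05, 0.05))
  expect_equal(out$beta_meta, 0.2)
  expect_equal(out$se_meta, 0.05 / sqrt(2))
})

test_that("ivw_meta matches an independent fixed-effect meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(9)
  for (rep in 1:5) {
    b <- rnorm(5, 0.1, 0.2)
    s <- runif(5, 0.02, 0.3)
    ours <- ivw_meta(matrix(b, 1), matrix(s, 1))
    oracle <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(ours$beta_meta, as.numeric(oracle$beta), tolerance = 1e-10)
    expect_equal(ours$se_meta, oracle$se, tolerance = 1e-10)
  }
})

test_that("ivw_meta is permutation-invariant, sign-equivariant, and tightens with inputs", {
  b <- c(0.1, -0.05, 0.2); s <- c(0.04, 0.08, 0.1)
  expect_equal(ivw_meta(b, s), ivw_meta(b[c(3, 1, 2)], s[c(3, 1, 2)]))
  expect_equal(ivw_meta(-b, s)$beta_meta, -ivw_meta(b, s)$beta_meta)
  expect_lt(ivw_meta(b, s)$se_meta, ivw_meta(b[1:2], s[1:2])$se_meta)
  expect_lt(ivw_meta(b, s)$se_meta, min(s))
  expect_error(ivw_meta(b, c(0.04, 0, 0.1)), "> 0")
})

# reconstruct (beta, se) from a printed "OR (low-high)" pair
printed <- function(s) parse_or_ci(s)

test_that("aligned pooling of printed per-trait ORs reproduces the printed meta OR", {
  sle <- printed("1.11 (1.05-1.17)")
  covid <- printed("1.17 (1.10-1.25)")
  pooled <- ivw_meta(c(sle$beta, covid$beta), c(sle$se, covid$se))
  expect_lt(abs(exp(pooled$beta_meta) - 1.14), 0.02)
})

test_that("opposing pooling of printed per-trait ORs reproduces the printed meta OR", {
  sle <- printed("0.80 (0.77-0.84)")
  covid <- printed("1.19 (1.14-1.23)")
  pooled <- ivw_meta(c(-sle$beta, covid$beta), c(sle$se, covid$se))
  expect_lt(abs(exp(pooled$beta_meta) - 1.21), 0.02)
})

test_that("opposing_meta equals ivw_meta with trait-2 betas negated", {
  t1 <- toy_sumstats(12, seed = 4)
  t2 <- toy_sumstats(12, seed = 5)
  t2[, c("snp_id", "chrom", "pos", "a1", "a2")] <-
    t1[, c("snp_id", "chrom", "pos", "a1", "a2")]
  pair <- harmonize_pair(t1, t2)
  opp <- opposing_meta(pair)
  direct <- ivw_meta(cbind(pair$records_1$beta, -pair$records_2$beta),
                     cbind(pair$records_1$se, pair$records_2$se))
  expect_equal(opp$beta_meta, direct$beta_meta)
  expect_equal(opp$p_meta, direct$p_meta)
  # beta2 = -beta1 with equal se pools to beta1 under the flip
  flip <- ivw_meta(c(0.3, -(-0.3)), c(0.1, 0.1))
  expect_equal(flip$beta_meta, 0.3)
})

test_that("concordance filter enforces the p-bound and direction rule", {
  rec <- data.frame(
    beta_1 = c(0.2, 0.2, 0.2, 0.2), p_1 = c(0.005, 0.005, 0.005, 0.02),
    beta_2 = c(0.1, 0.1, -0.1, 0.1), p_2 = c(0.009, 0.02, 0.009, 0.009),
    mode = "aligned"
  )
  out <- cross_trait_filter(rec, p_bound = 0.01)
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE))
  # same-direction pairs are dropped in opposing mode
  out_opp <- cross_trait_filter(rec, p_bound = 0.01, mode = "opposing")
  expect_equal(out_opp$retained, c(FALSE, FALSE, TRUE, FALSE))
})

make_retained <- function(chrom, pos, p) {
  data.frame(snp_id = sprintf("s%d", seq_along(pos)), chrom = chrom,
             pos = pos, p_meta = p, log10_p_meta = log10(p),
             p_1 = 1e-3, p_2 = 1e-3, mode = "aligned", retained = TRUE,
             stringsAsFactors = FALSE)
}

test_that("candidate loci: greedy 1 Mb clustering with MHC masking", {
  rec <- make_retained(c("2", "6", "3", "3"),
                       c(5e6, 30e6, 7e6, 7.5e6),
                       c(1e-9, 1e-20, 1e-8, 1e-9))
  loci <- find_candidates(rec)
  # chr6:30Mb sits inside the masked MHC despite the strongest p
  expect_false("6" %in% loci$chrom)
  # the two chr3 SNPs 500 kb apart merge into one locus led by smaller p
  chr3 <- loci[loci$chrom == "3", ]
  expect_equal(nrow(chr3), 1)
  expect_equal(chr3$pos, 7.5e6)
  expect_equal(nrow(loci), 2)
  # without the mask the MHC SNP leads its own locus
  expect_equal(nrow(find_candidates(rec, mhc = NULL)), 3)
  # sub-threshold SNPs produce no loci
  expect_equal(nrow(find_candidates(make_retained("1", 1e6, 1e-7))), 0)
})

test_that("published-locus check uses a half-open 1 Mb window", {
  other <- data.frame(chrom = "5", pos = c(2e6, 3e6 - 1, 3e6),
                      p = c(1e-4, 3e-6, 1e-12))
  pub <- data.frame(snp_id = c("lead1", "lead2"), chrom = "5",
                    pos = c(2e6, 9e6))
  out <- check_published_loci(pub, other, p_bound = 1e-5)
  # window [1e6, 3e6): the 3e-6 SNP at 3e6-1 is in, the 1e-12 at 3e6 is out
  expect_true(out$candidate[1])
  expect_equal(out$min_p_other[1], 3e-6)
  expect_false(out$candidate[2])
})

test_that("retention is enriched at planted SNPs in the matching mode", {
  hits_al <- hits_op <- 0L; null_al <- 0L; n_null <- 0L
  for (r in 1:40) {
    spec <- architecture_spec(
      blocks = data.frame(size = rep(10, 6), rho = 0.3),
      causal = data.frame(index = c(5, 35), label = c("shared_aligned",
                                                      "shared_opposing")),
      effect_scale = c(0.12, 0.12), n1 = 8000, n2 = 8000, seed = 2000 + r)
    co <- simulate_sumstats(spec)
    pair <- harmonize_pair(co$sumstats_1, co$sumstats_2)
    al <- cross_trait_filter(aligned_meta(pair))
    op <- cross_trait_filter(opposing_meta(pair))
    hits_al <- hits_al + al$retained[5]
    hits_op <- hits_op + op$retained[35]
    null_al <- null_al + sum(al$retained[41:60])
    n_null <- n_null + 20L
  }
  # power at planted SNPs far exceeds the null retention rate
  expect_gt(hits_al / 40, 0.5)
  expect_gt(hits_op / 40, 0.5)
  expect_lt(null_al / n_null, 0.05)
})
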