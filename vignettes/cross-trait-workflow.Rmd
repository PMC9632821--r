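---
title: "Cross-trait GWAS analysis from summary statistics: models, assumptions and design choices"
author: "crosstraitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait GWAS analysis from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstraitr)
```

# The problem

Two complex diseases can share genetic architecture in ways a single GWAS
cannot reveal: risk alleles for one may be risk for the other (aligned
effects) or protective (opposing effects), and apparent sharing at a locus
may be two distinct causal variants in linkage disequilibrium rather than
one shared variant. `crosstraitr` implements the full summary-statistics
workflow for this question — the motivating use case is contrasting an
autoimmune disease with a severe infectious outcome, where opposing
effects are biologically expected (alleles that heighten innate immune
responses can predispose to autoimmunity while protecting against
pathogens). Every stage consumes only per-SNP effects, standard errors and
allele frequencies plus a reference LD panel, so nothing requires
individual-level genotypes.

# Models and procedures

## Harmonization

Two summary-statistics tables are intersected (by chromosome and position
by default; positions are 1-based GRCh37, intervals half-open) and table 2
is rewritten onto table 1's effect allele: where the alleles are listed in
the opposite order the beta is negated and the frequency complemented;
where they match only as reverse complements the labels are strand-flipped
first. Palindromic A/T and C/G variants are unresolvable from labels
alone; they are oriented by allele frequency when the minor-allele
frequency is informative and dropped as ambiguous when
min(f, 1−f) exceeds 0.40 in either table (a frequency near 0.5 makes
frequency-based orientation a coin flip; the bound is this package's
declared default, not an inference about any published pipeline).
P-values are carried in log10 space alongside the raw column because
pooled signals reach p ≈ 1e−31, beyond any safe margin for repeated
exponentiation round trips.

## Cross-trait fixed-effect meta-analysis, aligned and opposing

Per SNP, effects are pooled with inverse-variance weights
(w = 1/se²; β̂ = Σwβ/Σw; se = (Σw)^(−1/2)). The *opposing* mode negates
trait 2's betas first, which is the powered test where the traits' risk
alleles are reciprocal; the pooled effect is then reported on trait 1's
allele orientation (published tables sometimes print the reciprocal
orientation — the magnitude is identical). Both modes then apply a
concordance filter — per-trait p < 0.01 in **both** traits and a direction
of effect consistent with the mode — before candidate loci are called at
p < 5e−8, greedily clustered into ±1 Mb windows around successive
minimum-p leads (ties broken by position). The MHC extended region
(chr6:24–36 Mb, endpoints inclusive since the boundary is quoted only to
Mb precision) is masked for its extreme long-range LD.

## Genetic correlation by LD score regression

Under a polygenic model, E[χ²_j] = 1 + a + N h² ℓ_j / M where
ℓ_j = Σ_k r²_jk is SNP j's LD score, and for two traits
E[z_1j z_2j] = ρ_Ns/√(N₁N₂) + √(N₁N₂) ρ_g ℓ_j / M. Slopes estimate
heritability and genetic covariance; the free intercepts absorb
confounding and sample overlap, so overlap need not be known. Weighting is
the canonical two-step heteroskedasticity scheme (1/ℓ, then inverse
squared fitted mean); χ² values above max(80, 0.001 N) are winsorized
(the cross-product is winsorized at the same cap so a trait regressed on
itself returns r_g = 1 exactly); standard errors come from a delete-one
block jackknife over 200 contiguous genomic blocks (scaled down when
fewer than 20,000 SNPs), and r_g = ρ̂_g/√(ĥ²₁ĥ²₂) is jackknifed as the
full ratio. LD scores use the unbiased small-sample adjustment
r² − (1−r²)/(n_ref−2) for finite panels; SNPs with MAF ≤ 0.01 are
excluded before fitting.

## Local heritability and genetic covariance

Within a locus, with R = UΛU′ and standardized effects b = z/√N, the
quadratic form over the top-k eigencomponents gives
ĥ²_loc = (N q_k − k)/(N − k), an unbiased estimator that is legitimately
negative at null loci, and
ĝcov = b₁′U_kΛ_k⁻¹U_k′b₂ − k ρ N_s/(N₁N₂), whose second term removes the
noise covariance induced by overlapping samples (zero by default: the
motivating cohorts are disjoint). k defaults to the smallest number of
eigencomponents explaining 99.5% of the positive trace, capped at 50 —
the usual bias/variance truncation for this estimator family. The cap
matters: on loci much wider than 50 effective components the truncation
discards genetic signal and biases ĥ²_loc downward (we measured ≈ −20%
on a 100-SNP AR(1) ρ = 0.5 locus), so loci should be analyzed at a scale
where the retained trace stays near 99.5%. The local correlation
ĝcov/√(ĥ²₁ĥ²₂) is reported only when both heritabilities are positive,
and is numerically unstable when they are near zero — read it together
with `p_gencov`, a Wald test from the asymptotic variance of the bilinear
form.

## Colocalization

Per SNP, Wakefield's log approximate Bayes factor is
lABF = ½[log(1−r) + r z²] with r = W/(W + se²). Under the
one-causal-variant-per-trait assumption the five hypothesis likelihoods
(H0 none, H1/H2 one trait only, H3 two distinct variants, H4 one shared
variant) are prior-weighted sums over configurations, computed with
log-sum-exp throughout and verified against exhaustive enumeration. Prior
effect variance defaults to W = 0.2² on the log-odds scale (0.15² is the
quantitative-trait convention); per-SNP priors p1 = p2 = 1e−4,
p12 = 1e−5. The composite decision rule declares sharing iff
PP_H4 > 0.5 at the liberal prior p12 = 5e−5 **and** PP_H3 < 0.5 at
p12 = 1e−5 (both strict); the stricter published-locus rule requires
PP_H4 > 0.9. Multi-signal loci are handled per signal: each trait's
conditioned marginal statistics (conditioning on its other index SNPs)
are colocalized pairwise and the maximum PP_H4 reported.

## Conditional and joint fine-mapping

Stepwise selection from marginal effects uses the summary-statistics
normal-equations approximation: D_j = 2f_j(1−f_j)N_j stands in for
x_j′x_j, off-diagonals are r_jk√(D_jD_k) from reference LD (zero beyond
10 Mb), joint effects solve B b_J = D b_marginal, and the residual
variance comes from a median-aggregated reconstruction of y′y — the
median, rather than a mean, guards against SNPs whose printed (β, se, f,
N) quadruple is internally inconsistent. Defaults: entry/exit p < 1e−5,
collinearity cutoff r² > 0.9 (candidates in stronger LD with a selected
SNP are skipped), backward elimination after each addition,
ill-conditioned systems (reciprocal condition number < 1e−8) skipped with
a message, ties on conditional p broken by position, and SNPs whose
summary frequency differs from the reference panel by more than 0.2
dropped as panel mismatches. Joint effects are on the same per-allele,
unit-phenotype-variance scale as the inputs; published log-odds tables
using other variance conventions are contract references, not numeric
targets.

# The synthetic cohort generator

`simulate_sumstats()` draws marginal z-scores directly from their
sampling distribution, z_t ~ MVN(√N_t R β_t, R) blockwise, with
cross-trait noise covariance (N_s ρ/√(N₁N₂)) R when samples overlap —
this is exactly the generative model under which LDSC, coloc and COJO are
derived, which is what makes calibrated recovery tests meaningful.
`simulate_individual()` is the slower oracle route: genotypes from a
Gaussian-copula discretization of MVN(0, R) into {0,1,2} at
Hardy-Weinberg proportions (the latent correlation is pre-inflated by the
analytic attenuation factor so realized dosage LD matches the target R),
quantitative liability phenotypes y = X_std β + ε with unit variance, and
per-SNP least squares. Case-control traits are treated as quantitative on
the liability/log-odds scale — all downstream algebra consumes (β, se)
pairs and is scale-agnostic — and the effective sample size of a
case-control study is 4/(1/n_cases + 1/n_controls) wherever an N is
needed. One integer seed drives everything through fixed per-stage
substreams; reruns are byte-identical.

What the generator does *not* emulate: coalescent genealogies,
recombination-map LD (blocks are AR(1)), allele-frequency/effect-size
coupling, imputation error (INFO is carried but simulated as 1), and
case-control ascertainment. Passing recovery tests therefore demonstrate
correctness of the estimators under their own assumptions, not robustness
to real-data violations of them.

# Study conditions used by the calibration suite

Chosen once, as realistic desk-scale analogues of the motivating study,
and used unchanged by the tests and the acceptance script:

* **Meta-analysis worked examples**: per-trait ORs and 95% CIs read off
  the published lead-SNP association table (shipped as a plain-text
  input), reconstructed as β = ln OR, se = (ln U − ln L)/(2·1.959964),
  pooled and compared to the printed meta ORs within ±0.02 (the inputs
  are rounded to two decimals).
* **LDSC**: 20,000 SNPs in 50-SNP AR(1) blocks with ρ cycling over
  {0, 0.3, 0.5, 0.7, 0.9} (real genomes have widely varying LD; a
  constant ρ makes the LD-score regressor nearly constant and the slope
  unidentifiable), h² = 0.4 per trait, N = 50,000, planted r_g = 0.56 and
  0; 50 replicates; coverage of the truth by ±2 jackknife SEs.
* **Fine-mapping**: 50 two-signal loci, n = 2,000 individuals, m = 50
  SNPs, standardized effects 0.15 at two causal SNPs two steps apart in
  an AR(1) ρ = 0.55 block (realized r² ≈ 0.08 between them); the
  generating genotypes provide the LD panel and the multivariate OLS
  oracle.
* **Local covariance**: 50-SNP ρ = 0.5 locus, five causal SNPs of local
  h² = 0.002 total, N = 50,000, 200 replicates per direction of sharing.
* **End-to-end pipeline**: 3,000-SNP genome, one aligned and one opposing
  shared locus plus trait-specific decoys, n = 20,000 per trait.

These sizes keep the default test run to well under a minute of compute
while leaving the statistical criteria (coverage, sign rates, selection
rates) comfortably away from their thresholds.

# Numerical choices and degenerate inputs

* All hypothesis sums, p-values and Bayes-factor aggregations run in log
  space; H3's difference term uses a guarded log-difference that returns
  −∞ on single-SNP loci (where distinct causal variants are impossible).
* LD references are stored blockwise (cross-block correlation exactly
  zero) so genome-scale panels stay linear in SNP count; blocks are
  symmetrized, unit-diagonal and eigenvalue-checked at construction.
* Monomorphic reference SNPs get zero off-diagonal LD and a flag;
  missing dosages are mean-imputed per SNP.
* Zero-variance / non-positive-definite joint covariances in the
  simulator, empty SNP intersections, negative heritabilities (r_g left
  undefined but covariance reported), and conditioning sets that absorb a
  candidate (d* ≤ 0) all produce explicit errors, flags or NAs rather
  than silent numbers.

# Known limitations

Single-causal-variant colocalization cannot represent allelic
heterogeneity within one signal (the per-signal conditioning only
separates *distinct* signals); LDSC intercepts absorb but do not estimate
confounding separately from overlap; the local estimator's truncation
bias grows with locus width; and the workflow deliberately performs no
liftover, imputation or external-resource retrieval — inputs must already
be on a common build.
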