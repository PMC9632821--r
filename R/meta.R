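# Fixed-effect inverse-variance meta-analysis, the sign-reversed
# ("opposing effect") cross-trait mode, the per-trait concordance filter,
# and candidate-locus discovery with MHC masking.

#' Fixed-effect inverse-variance pooling
#'
#' Pools per-study effects with weights w_i = 1/se_i^2:
#' beta = sum(w b) / sum(w), se = 1/sqrt(sum(w)); the two-sided normal
#' p-value is computed in log space.
#'
#' @param betas,ses numeric matrices (SNPs x studies) or vectors for a
#'   single SNP; at least two study columns.
#' @return data.frame with `beta_meta`, `se_meta`, `z`, `p_meta`,
#'   `log10_p_meta`.
#' @export
ivw_meta <- function(betas, ses) {
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
  if (is.null(dim(ses))) ses <- matrix(ses, nrow = 1)
  stopifnot(identical(dim(betas), dim(ses)), ncol(betas) >= 2)
  if (any(ses <= 0, na.rm = TRUE)) stop("all standard errors must be > 0")
  w <- 1 / ses^2
  sw <- rowSums(w)
  beta <- rowSums(w * betas) / sw
  se <- 1 / sqrt(sw)
  z <- beta / se
  data.frame(beta_meta = beta, se_meta = se, z = z,
             p_meta = z_to_p(z), log10_p_meta = z_to_log10p(z))
}

#' @keywords internal
meta_table <- function(pair, mode) {
  r1 <- pair$records_1; r2 <- pair$records_2
  b2 <- if (mode == "opposing") -r2$beta else r2$beta
  pooled <- ivw_meta(cbind(r1$beta, b2), cbind(r1$se, r2$se))
  out <- data.frame(
    snp_id = r1$snp_id, chrom = r1$chrom, pos = r1$pos,
    a1 = r1$a1, a2 = r1$a2,
    beta_meta = pooled$beta_meta, se_meta = pooled$se_meta,
    p_meta = pooled$p_meta, log10_p_meta = pooled$log10_p_meta,
    beta_1 = r1$beta, se_1 = r1$se, p_1 = r1$p, log10_p_1 = r1$log10_p,
    beta_2 = r2$beta, se_2 = r2$se, p_2 = r2$p, log10_p_2 = r2$log10_p,
    mode = mode, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Aligned-mode cross-trait meta-analysis of a harmonized pair
#'
#' @param pair a `harmonized_pair`.
#' @return per-SNP meta-analysis table carrying the pooled and the
#'   per-trait statistics (trait betas on the harmonized, unflipped scale).
#' @export
aligned_meta <- function(pair) meta_table(pair, "aligned")

#' Opposing-mode (sign-reversed) cross-trait meta-analysis
#'
#' Negates trait 2's betas before inverse-variance pooling, which is the
#' powered test for loci where the two traits' risk alleles are reciprocal.
#' The pooled effect is reported on trait 1's allele orientation; the
#' per-trait columns keep the original harmonized signs.
#'
#' @param pair a `harmonized_pair`.
#' @return per-SNP meta-analysis table, as [aligned_meta()].
#' @export
opposing_meta <- function(pair) meta_table(pair, "opposing")

#' Concordance filter on a cross-trait meta-analysis table
#'
#' Retains SNPs with per-trait p below `p_bound` in both traits and a
#' direction of effect consistent with the meta-analysis mode: same sign
#' for aligned mode, opposite signs for opposing mode.
#'
#' @param records table from [aligned_meta()]/[opposing_meta()].
#' @param p_bound per-trait p-value bound (default 0.01).
#' @param mode `"aligned"` or `"opposing"`; defaults to the table's own mode.
#' @return the table with a logical `retained` column.
#' @export
cross_trait_filter <- function(records, p_bound = 0.01, mode = NULL) {
  mode <- mode %||% records$mode[1]
  s <- sign(records$beta_1) * sign(records$beta_2)
  concordant <- if (mode == "aligned") s > 0 else s < 0
  records$retained <- records$p_1 < p_bound & records$p_2 < p_bound & concordant
  records
}

MHC_EXTENDED <- list(chrom = "6", start = 24e6, end = 36e6)

#' @keywords internal
in_mhc <- function(chrom, pos, mhc = MHC_EXTENDED) {
  # boundaries inclusive: "extended region" is quoted only to Mb precision
  chrom == mhc$chrom & pos >= mhc$start & pos <= mhc$end
}

#' Greedy candidate-locus discovery from retained meta-analysis SNPs
#'
#' Removes the MHC extended region, keeps retained SNPs below the
#' genome-wide threshold and clusters them greedily into +/- `window`
#' half-open windows around successive minimum-p leads (ties broken by
#' smaller position).
#'
#' @param records filtered table from [cross_trait_filter()].
#' @param threshold genome-wide significance threshold (default 5e-8).
#' @param mhc list(chrom, start, end) to mask, or NULL to keep everything.
#' @param window half-width of a locus in bp (default 1 Mb).
#' @return data.frame of candidate loci: lead SNP, window, mode and the
#'   lead's meta and per-trait p-values.
#' @export
find_candidates <- function(records, threshold = 5e-8, mhc = MHC_EXTENDED,
                            window = 1e6) {
  stopifnot("retained" %in% names(records))
  hits <- records[records$retained & records$p_meta < threshold, , drop = FALSE]
  if (!is.null(mhc)) hits <- hits[!in_mhc(hits$chrom, hits$pos, mhc), , drop = FALSE]
  loci <- list()
  hits <- hits[order(hits$p_meta, hits$pos), , drop = FALSE]
  while (nrow(hits) > 0L) {
    lead <- hits[1L, ]
    loci[[length(loci) + 1L]] <- data.frame(
      lead_snp = lead$snp_id, chrom = lead$chrom, pos = lead$pos,
      start = lead$pos - window, end = lead$pos + window,
      mode = lead$mode, lead_p_meta = lead$p_meta,
      lead_log10_p_meta = lead$log10_p_meta,
      lead_p_trait1 = lead$p_1, lead_p_trait2 = lead$p_2,
      stringsAsFactors = FALSE
    )
    inside <- hits$chrom == lead$chrom &
      hits$pos >= lead$pos - window & hits$pos < lead$pos + window
    hits <- hits[!inside, , drop = FALSE]
  }
  if (length(loci) == 0L)
    return(data.frame(lead_snp = character(), chrom = character(),
                      pos = integer(), start = numeric(), end = numeric(),
                      mode = character(), lead_p_meta = numeric(),
                      lead_log10_p_meta = numeric(),
                      lead_p_trait1 = numeric(), lead_p_trait2 = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Check published trait loci for locus-wide association in the other trait
#'
#' For each published lead SNP, scans the half-open +/- `window` interval in
#' the other trait's summary statistics and flags the locus for
#' colocalization follow-up when any SNP there has p below `p_bound`.
#'
#' @param published data.frame with `snp_id`, `chrom`, `pos` of published
#'   leads (leads whose coordinates are missing are skipped with a message).
#' @param other_trait summary-statistics table for the other trait.
#' @param p_bound locus-wide association bound (default 1e-5).
#' @param window half-width in bp (default 1 Mb).
#' @return data.frame of published loci with the other-trait minimum p and
#'   a `candidate` flag.
#' @export
check_published_loci <- function(published, other_trait, p_bound = 1e-5,
                                 window = 1e6) {
  rows <- lapply(seq_len(nrow(published)), function(i) {
    lead <- published[i, ]
    if (is.na(lead$pos) || is.na(lead$chrom)) {
      message("skipping unresolvable published lead: ", lead$snp_id)
      return(NULL)
    }
    inside <- other_trait$chrom == as.character(lead$chrom) &
      other_trait$pos >= lead$pos - window & other_trait$pos < lead$pos + window
    minp <- if (any(inside)) min(other_trait$p[inside]) else NA_real_
    data.frame(snp_id = lead$snp_id, chrom = as.character(lead$chrom),
               pos = lead$pos, n_snps_window = sum(inside),
               min_p_other = minp,
               candidate = !is.na(minp) && minp < p_bound,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
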