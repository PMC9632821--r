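# Reading, validating, harmonizing and writing GWAS summary statistics.
#
# The canonical in-memory representation is a plain data.frame with columns
#   snp_id, chrom, pos, a1, a2, freq_a1, beta, se, p, n_cases, n_controls, info
# (1-based GRCh37 positions; a1 is the effect allele; beta is the log-odds
# effect of a1). A log10_p column is carried alongside so that p-values far
# below double precision survive downstream arithmetic.

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "a1", "a2", "freq_a1",
                   "beta", "se", "p", "n_cases", "n_controls", "info")

#' Default column-name dialect for summary-statistics files
#'
#' A dialect maps the canonical column names onto the names used in a file,
#' and declares the effect scale. `effect = "or"` declares that the effect
#' column holds odds ratios to be converted to log-odds on read; when
#' `ci_lower`/`ci_upper` are mapped the standard error is reconstructed from
#' the 95% confidence bounds as (log(U) - log(L)) / (2 * 1.959964).
#'
#' @param ... named overrides of the default mapping, e.g. `beta = "OR",
#'   effect = "or"`.
#' @return a named list usable as the `dialect` argument of [read_sumstats()].
#' @export
sumstats_dialect <- function(...) {
  d <- list(snp_id = "snp_id", chrom = "chrom", pos = "pos",
            a1 = "a1", a2 = "a2", freq_a1 = "freq_a1",
            beta = "beta", se = "se", p = "p",
            n_cases = "n_cases", n_controls = "n_controls", info = "info",
            ci_lower = NULL, ci_upper = NULL, effect = "beta")
  ov <- list(...)
  d[names(ov)] <- ov
  d
}

#' Read a tab-delimited GWAS summary-statistics file
#'
#' Reads, renames columns through a dialect, converts odds ratios to
#' log-odds where declared, validates every row and drops (with counts)
#' rows violating the record invariants.
#'
#' @param path file path to a tab-delimited table with a header line.
#' @param dialect column mapping from [sumstats_dialect()]; may also be a
#'   path to a YAML file holding the same named list.
#' @return validated summary-statistics data.frame; attribute `"report"`
#'   holds the per-reason drop counts.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  if (is.character(dialect) && length(dialect) == 1L) {
    dialect <- do.call(sumstats_dialect, yaml::read_yaml(dialect))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("snp_id", "chrom", "pos", "a1", "a2", "freq_a1", "beta", "se")
  ci_se <- identical(dialect$effect, "or") &&
    !is.null(dialect$ci_lower) && !is.null(dialect$ci_upper)
  if (ci_se) mandatory <- setdiff(mandatory, "se")
  for (col in mandatory) {
    src <- dialect[[col]]
    if (is.null(src) || !(src %in% names(raw)))
      stop("mandatory column missing from ", path, ": ", col,
           " (mapped to '", src %||% "<unmapped>", "')")
  }
  df <- data.frame(
    snp_id = as.character(raw[[dialect$snp_id]]),
    chrom = as.character(raw[[dialect$chrom]]),
    pos = as.integer(raw[[dialect$pos]]),
    a1 = toupper(as.character(raw[[dialect$a1]])),
    a2 = toupper(as.character(raw[[dialect$a2]])),
    freq_a1 = as.numeric(raw[[dialect$freq_a1]]),
    beta = suppressWarnings(as.numeric(raw[[dialect$beta]])),
    stringsAsFactors = FALSE
  )
  grab <- function(col, default) {
    src <- dialect[[col]]
    if (!is.null(src) && src %in% names(raw))
      suppressWarnings(as.numeric(raw[[src]])) else rep(default, nrow(raw))
  }
  df$se <- grab("se", NA_real_)
  df$p <- grab("p", NA_real_)
  df$n_cases <- grab("n_cases", NA_real_)
  df$n_controls <- grab("n_controls", NA_real_)
  df$info <- grab("info", 1)
  df$info[is.na(df$info)] <- 1

  if (identical(dialect$effect, "or")) {
    or <- df$beta
    df$beta <- log(or)
    if (!is.null(dialect$ci_lower) && !is.null(dialect$ci_upper)) {
      lo <- suppressWarnings(as.numeric(raw[[dialect$ci_lower]]))
      hi <- suppressWarnings(as.numeric(raw[[dialect$ci_upper]]))
      df$se <- (log(hi) - log(lo)) / (2 * Z_95)
    }
  }
  validate_sumstats(df)
}

#' Validate a summary-statistics table
#'
#' Enforces the record invariants (distinct A/C/G/T alleles, se > 0,
#' frequency strictly inside (0,1), p in (0,1], INFO in \[0,1\]); failing
#' rows are dropped and counted. Missing p-values are filled from beta/se
#' under a two-sided normal test; the `log10_p` column is always recomputed
#' from beta/se so extreme signals keep full precision.
#'
#' @param df data.frame with the canonical columns.
#' @return the cleaned data.frame with a `"report"` attribute of drop counts.
#' @export
validate_sumstats <- function(df) {
  n0 <- nrow(df)
  bad_allele <- !(df$a1 %in% c("A", "C", "G", "T")) |
    !(df$a2 %in% c("A", "C", "G", "T")) | df$a1 == df$a2
  bad_se <- !is.finite(df$se) | df$se <= 0
  bad_beta <- !is.finite(df$beta)
  bad_freq <- !is.finite(df$freq_a1) | df$freq_a1 <= 0 | df$freq_a1 >= 1
  bad_p <- !is.na(df$p) & (df$p < 0 | df$p > 1)
  bad_info <- !is.na(df$info) & (df$info < 0 | df$info > 1)
  bad_pos <- !is.finite(df$pos) | df$pos < 1
  drop <- bad_allele | bad_se | bad_beta | bad_freq | bad_p | bad_info | bad_pos
  report <- c(n_in = n0,
              dropped_allele = sum(bad_allele, na.rm = TRUE),
              dropped_se = sum(bad_se & !bad_allele, na.rm = TRUE),
              dropped_other = sum(drop, na.rm = TRUE) -
                sum(bad_allele | (bad_se & !bad_allele), na.rm = TRUE),
              n_dropped = sum(drop, na.rm = TRUE))
  df <- df[!drop, , drop = FALSE]
  z <- df$beta / df$se
  df$log10_p <- z_to_log10p(z)
  fill <- is.na(df$p) | df$p == 0
  df$p[fill] <- z_to_p(z[fill])
  rownames(df) <- NULL
  attr(df, "report") <- report
  df
}

#' Write summary statistics in the canonical tab-delimited layout
#'
#' @param df summary-statistics data.frame.
#' @param path output file path.
#' @export
write_sumstats <- function(df, path) {
  out <- df[, SUMSTATS_COLS]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' @keywords internal
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize two summary-statistics tables to a common effect allele
#'
#' Intersects the tables (by chromosome/position with the allele set, or by
#' SNP id), aligns table 2 to table 1's effect allele -- negating beta and
#' complementing the frequency where the alleles are swapped, complementing
#' the allele labels where they match only on the opposite strand -- and
#' drops palindromic (A/T or C/G) variants whose minor-allele frequency is
#' too close to 0.5 for frequency-based orientation to be trusted, plus any
#' remaining allele mismatches.
#'
#' @param t1,t2 validated summary-statistics data.frames.
#' @param ambiguity_maf_bound palindromic SNPs with min(freq, 1-freq)
#'   above this bound in either table are dropped as strand-ambiguous
#'   (default 0.40).
#' @param match_by `"position"` (chromosome + position, the default) or
#'   `"snp_id"`.
#' @return object of class `harmonized_pair`: list with aligned
#'   `records_1`, `records_2` and a `report` of counts.
#' @export
harmonize_pair <- function(t1, t2, ambiguity_maf_bound = 0.40,
                           match_by = c("position", "snp_id")) {
  match_by <- match.arg(match_by)
  key <- function(df) {
    if (match_by == "position") paste(df$chrom, df$pos, sep = ":") else df$snp_id
  }
  k1 <- key(t1); k2 <- key(t2)
  t1 <- t1[!duplicated(k1), , drop = FALSE]
  t2 <- t2[!duplicated(k2), , drop = FALSE]
  k1 <- key(t1); k2 <- key(t2)
  shared <- intersect(k1, k2)
  if (length(shared) == 0L) stop("no shared SNPs between the two tables")
  t1 <- t1[match(shared, k1), , drop = FALSE]
  t2 <- t2[match(shared, k2), , drop = FALSE]

  n_flipped <- 0L; n_strand <- 0L
  exact <- t1$a1 == t2$a1 & t1$a2 == t2$a2
  swap <- t1$a1 == t2$a2 & t1$a2 == t2$a1
  c1 <- unname(COMPLEMENT[t2$a1]); c2 <- unname(COMPLEMENT[t2$a2])
  comp <- t1$a1 == c1 & t1$a2 == c2 & !exact & !swap
  comp_swap <- t1$a1 == c2 & t1$a2 == c1 & !exact & !swap & !comp

  # strand-flip table 2's labels where only the reverse complement matches
  flip_strand <- comp | comp_swap
  t2$a1[flip_strand] <- unname(COMPLEMENT[t2$a1[flip_strand]])
  t2$a2[flip_strand] <- unname(COMPLEMENT[t2$a2[flip_strand]])
  n_strand <- sum(flip_strand)

  # allele swap: t2's effect allele is t1's other allele
  do_swap <- swap | comp_swap
  if (any(do_swap)) {
    tmp <- t2$a1[do_swap]
    t2$a1[do_swap] <- t2$a2[do_swap]
    t2$a2[do_swap] <- tmp
    t2$beta[do_swap] <- -t2$beta[do_swap]
    t2$freq_a1[do_swap] <- 1 - t2$freq_a1[do_swap]
    n_flipped <- sum(do_swap)
  }

  matched <- exact | swap | comp | comp_swap
  pal <- is_palindromic(t1$a1, t1$a2) & matched
  maf1 <- pmin(t1$freq_a1, 1 - t1$freq_a1)
  maf2 <- pmin(t2$freq_a1, 1 - t2$freq_a1)
  ambiguous <- pal & (maf1 > ambiguity_maf_bound | maf2 > ambiguity_maf_bound)
  # palindromic but orientable: use frequency agreement to fix orientation
  orient <- pal & !ambiguous &
    (t1$freq_a1 - 0.5) * (t2$freq_a1 - 0.5) < 0
  if (any(orient)) {
    t2$beta[orient] <- -t2$beta[orient]
    t2$freq_a1[orient] <- 1 - t2$freq_a1[orient]
    n_flipped <- n_flipped + sum(orient)
  }

  keep <- matched & !ambiguous
  report <- c(n_shared = length(shared),
              n_kept = sum(keep),
              n_flipped_allele = n_flipped,
              n_strand_flipped = n_strand,
              n_dropped_ambiguous = sum(ambiguous),
              n_dropped_mismatch = sum(!matched))
  r1 <- t1[keep, , drop = FALSE]; rownames(r1) <- NULL
  r2 <- t2[keep, , drop = FALSE]; rownames(r2) <- NULL
  structure(list(records_1 = r1, records_2 = r2, report = report),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("Harmonized summary-statistics pair:", x$report[["n_kept"]],
      "shared SNPs\n")
  print(x$report)
  invisible(x)
}

#' Genomic inflation factor
#'
#' lambda = median of the chi-square(1) statistics implied by the p-values,
#' divided by the null median 0.4549364.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return scalar lambda.
#' @export
genomic_lambda <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / CHISQ1_MEDIAN
}

#' Rescale a genomic inflation factor to a 1,000-case/1,000-control study
#'
#' @param lambda observed inflation factor.
#' @param n_cases,n_controls sample counts of the study that produced it.
#' @return lambda_1000 = 1 + (lambda - 1) * (1/n_cases + 1/n_controls) / (2/1000).
#' @export
lambda_1000 <- function(lambda, n_cases, n_controls) {
  stopifnot(lambda >= 0, n_cases > 0, n_controls > 0)
  1 + (lambda - 1) * (1 / n_cases + 1 / n_controls) / (2 / 1000)
}
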