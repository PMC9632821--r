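# End-to-end cross-trait workflow: harmonize -> per-trait QC -> both
# meta-analysis modes -> concordance filter -> candidate loci -> per-trait
# stepwise fine-mapping -> per-signal colocalization -> sharing decisions
# -> shared-locus report. Driven by one config; deterministic given the
# config and seed; every stage's row counts go into a manifest.

#' Pipeline configuration
#'
#' All thresholds default to the workflow's canonical values: per-trait
#' MAF > 0.01, INFO > 0.9 (trait 1) / 0.6 (trait 2), concordance filter
#' p < 0.01, genome-wide threshold 5e-8, locus-wide bound 1e-5, composite
#' coloc decision at p12 = 5e-5 / 1e-5, COJO at p < 1e-5 with collinearity
#' 0.9 over 10 Mb, MHC mask chr6:24-36 Mb.
#'
#' @param trait1,trait2 either a summary-statistics data.frame or a list
#'   `list(path=, dialect=)` to read from disk.
#' @param ld_ref an `ld_reference` (or NULL to skip fine-mapping and use
#'   unconditioned colocalization).
#' @param maf_min,info_min_1,info_min_2 per-trait QC bounds.
#' @param p_filter,gw_threshold,locus_p workflow thresholds.
#' @param coloc a [coloc_config()]; its `p12` is the default prior, the
#'   composite rule also evaluates `p12_liberal`.
#' @param p12_liberal liberal shared prior for decision condition 1.
#' @param cojo list(p_cut, collinearity, window_bp).
#' @param mhc MHC interval to mask, or NULL.
#' @param ambiguity_maf_bound palindromic ambiguity bound for harmonization.
#' @param locus_window candidate-locus half-width (bp).
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory for artifacts, or NULL for none.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(trait1, trait2, ld_ref = NULL,
                            maf_min = 0.01, info_min_1 = 0.9,
                            info_min_2 = 0.6,
                            p_filter = 0.01, gw_threshold = 5e-8,
                            locus_p = 1e-5,
                            coloc = coloc_config(), p12_liberal = 5e-5,
                            cojo = list(p_cut = 1e-5, collinearity = 0.9,
                                        window_bp = 10e6),
                            mhc = MHC_EXTENDED,
                            ambiguity_maf_bound = 0.40,
                            locus_window = 1e6,
                            seed = 1L, out_dir = NULL) {
  stopifnot(p_filter > 0, p_filter < 1, gw_threshold > 0, gw_threshold < 1,
            locus_p > 0, locus_p < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file gives trait input paths/dialects and any threshold overrides;
#' unspecified fields keep the [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (tr in c("trait1", "trait2")) {
    if (!is.null(y[[tr]]$dialect)) y[[tr]]$dialect <-
        do.call(sumstats_dialect, y[[tr]]$dialect)
  }
  if (!is.null(y$coloc)) y$coloc <- do.call(coloc_config, y$coloc)
  do.call(pipeline_config, y)
}

#' Format an effect and SE as "OR (low-high)"
#'
#' OR = exp(beta); 95% bounds exp(beta +/- 1.959964 se); two decimals,
#' en-dash separator, as association tables print them.
#'
#' @param beta log-odds effect.
#' @param se standard error (> 0).
#' @return character vector.
#' @export
format_or_ci <- function(beta, se) {
  stopifnot(all(se > 0))
  sprintf("%.2f (%.2f–%.2f)", exp(beta), exp(beta - Z_95 * se),
          exp(beta + Z_95 * se))
}

#' Recover beta and se from an "OR (low-high)" string
#'
#' @param s strings as produced by [format_or_ci()] (any of "-", en-dash
#'   or em-dash separators are accepted).
#' @return data.frame with `beta` = log(OR) and
#'   `se` = (log(high) - log(low)) / (2 * 1.959964).
#' @export
parse_or_ci <- function(s) {
  nums <- lapply(regmatches(s, gregexpr("[0-9]*\\.?[0-9]+", s)), as.numeric)
  bad <- lengths(nums) != 3L
  if (any(bad)) stop("cannot parse OR (CI) string: ", s[bad][1])
  or <- vapply(nums, `[`, numeric(1), 1)
  lo <- vapply(nums, `[`, numeric(1), 2)
  hi <- vapply(nums, `[`, numeric(1), 3)
  data.frame(beta = log(or), se = (log(hi) - log(lo)) / (2 * Z_95))
}

#' @keywords internal
load_trait <- function(input) {
  if (is.data.frame(input)) return(validate_sumstats(input))
  read_sumstats(input$path, input$dialect %||% sumstats_dialect())
}

#' Run the full cross-trait workflow
#'
#' @param config a [pipeline_config()].
#' @return list with the shared-locus `report`, both per-SNP meta tables,
#'   `candidates`, per-trait inflation factors, and a `manifest` of
#'   per-stage row counts. Artifacts are written under `config$out_dir`
#'   when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed)
  t1 <- load_trait(config$trait1)
  t2 <- load_trait(config$trait2)
  manifest$n_input <- c(trait1 = nrow(t1), trait2 = nrow(t2))

  qc <- function(df, info_min) {
    maf <- pmin(df$freq_a1, 1 - df$freq_a1)
    df[maf > config$maf_min & df$info > info_min, , drop = FALSE]
  }
  t1 <- qc(t1, config$info_min_1)
  t2 <- qc(t2, config$info_min_2)
  manifest$n_after_qc <- c(trait1 = nrow(t1), trait2 = nrow(t2))

  lam <- function(df) {
    l <- genomic_lambda(df$p)
    nca <- stats::median(df$n_cases, na.rm = TRUE)
    nco <- stats::median(df$n_controls, na.rm = TRUE)
    c(lambda = l,
      lambda_1000 = if (is.finite(nca) && is.finite(nco))
        lambda_1000(l, nca, nco) else NA_real_)
  }
  inflation <- rbind(trait1 = lam(t1), trait2 = lam(t2))

  pair <- harmonize_pair(t1, t2, config$ambiguity_maf_bound)
  manifest$harmonization <- pair$report
  manifest$n_overlapped <- unname(pair$report["n_kept"])

  metas <- list(aligned = aligned_meta(pair), opposing = opposing_meta(pair))
  metas <- lapply(metas, cross_trait_filter, p_bound = config$p_filter)
  manifest$n_retained <- vapply(metas, function(m) sum(m$retained), numeric(1))

  cands <- lapply(names(metas), function(mode)
    find_candidates(metas[[mode]], threshold = config$gw_threshold,
                    mhc = config$mhc, window = config$locus_window))
  candidates <- do.call(rbind, cands)
  manifest$n_candidate_loci <- nrow(candidates)

  report_rows <- lapply(seq_len(nrow(candidates)), function(i) {
    locus <- candidates[i, ]
    win <- function(df) df[df$chrom == locus$chrom &
                             df$pos >= locus$start & df$pos < locus$end, ,
                           drop = FALSE]
    s1 <- win(pair$records_1); s2 <- win(pair$records_2)
    model1 <- model2 <- NULL
    if (!is.null(config$ld_ref)) {
      cj <- config$cojo
      model1 <- tryCatch(cojo_select(s1, config$ld_ref, p_cut = cj$p_cut,
                                     collinearity = cj$collinearity,
                                     window_bp = cj$window_bp),
                         error = function(e) NULL)
      model2 <- tryCatch(cojo_select(s2, config$ld_ref, p_cut = cj$p_cut,
                                     collinearity = cj$collinearity,
                                     window_bp = cj$window_bp),
                         error = function(e) NULL)
    }
    cfg_lib <- config$coloc; cfg_lib$p12 <- config$p12_liberal
    ps_main <- coloc_per_signal(s1, s2, model1, model2, config$ld_ref,
                                config$coloc)
    ps_lib <- coloc_per_signal(s1, s2, model1, model2, config$ld_ref, cfg_lib)
    bi <- ps_lib$best
    post_main <- ps_main$posteriors[[(bi[1] - 1L) * ncol(ps_main$pp_matrix) + bi[2]]]
    post_lib <- ps_lib$posteriors[[(bi[1] - 1L) * ncol(ps_lib$pp_matrix) + bi[2]]]
    lead1 <- s1[s1$snp_id == locus$lead_snp, ][1, ]
    lead2 <- s2[s2$snp_id == locus$lead_snp, ][1, ]
    meta_row <- metas[[locus$mode]]
    meta_row <- meta_row[meta_row$snp_id == locus$lead_snp, ][1, ]
    data.frame(
      lead_snp = locus$lead_snp, chrom = locus$chrom, pos = locus$pos,
      mode = locus$mode,
      meta_or_ci = format_or_ci(meta_row$beta_meta, meta_row$se_meta),
      meta_p = meta_row$p_meta,
      trait1_or_ci = format_or_ci(lead1$beta, lead1$se), trait1_p = lead1$p,
      trait2_or_ci = format_or_ci(lead2$beta, lead2$se), trait2_p = lead2$p,
      n_signals_1 = if (is.null(model1)) 1L else max(1L, nrow(model1$selected)),
      n_signals_2 = if (is.null(model2)) 1L else max(1L, nrow(model2$selected)),
      max_pp_h4 = ps_lib$max_pp_h4,
      shared = shared_decision(post_lib, post_main),
      shared_strict = strict_shared_decision(post_main),
      stringsAsFactors = FALSE
    )
  })
  report <- if (length(report_rows)) do.call(rbind, report_rows) else
    data.frame()

  out <- list(report = report, meta_aligned = metas$aligned,
              meta_opposing = metas$opposing, candidates = candidates,
              inflation = inflation, pair = pair, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) utils::write.table(
      df, file.path(config$out_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wr(report, "shared_locus_report.tsv")
    wr(metas$aligned, "meta_aligned.tsv")
    wr(metas$opposing, "meta_opposing.tsv")
    wr(candidates, "candidate_loci.tsv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
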