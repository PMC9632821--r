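# LD reference panels: per-region SNP correlation structure with allele
# frequencies. Stored block-wise (cross-block correlation is exactly zero)
# so genome-scale references stay linear in SNP count; a dense matrix is
# materialized on demand for small regions.

#' Construct an LD reference object
#'
#' @param snp_ids character vector of SNP identifiers, in genomic order.
#' @param chrom chromosome label(s), recycled.
#' @param pos 1-based positions.
#' @param freqs reference effect-allele frequencies.
#' @param R_blocks list of correlation matrices; their sizes must sum to
#'   the number of SNPs. A single dense matrix may be given.
#' @param n_ref reference panel sample count (`Inf` for a theoretical panel).
#' @param a1,a2 optional allele labels.
#' @return object of class `ld_reference`.
#' @export
ld_reference <- function(snp_ids, chrom, pos, freqs, R_blocks, n_ref = Inf,
                         a1 = NULL, a2 = NULL) {
  if (is.matrix(R_blocks)) R_blocks <- list(R_blocks)
  m <- length(snp_ids)
  sizes <- vapply(R_blocks, nrow, integer(1))
  if (sum(sizes) != m) stop("block sizes must sum to the number of SNPs")
  for (i in seq_along(R_blocks)) {
    R <- (R_blocks[[i]] + t(R_blocks[[i]])) / 2
    diag(R) <- 1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("block ", i, " is not positive semi-definite (min eigenvalue ",
           format(min(ev)), ")")
    R_blocks[[i]] <- R
  }
  structure(list(
    snp_ids = as.character(snp_ids),
    chrom = rep_len(as.character(chrom), m),
    pos = as.integer(pos),
    freqs = as.numeric(freqs),
    R_blocks = R_blocks,
    block_index = rep(seq_along(sizes), sizes),
    n_ref = n_ref,
    a1 = a1, a2 = a2
  ), class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat("LD reference:", length(x$snp_ids), "SNPs in", length(x$R_blocks),
      "block(s); n_ref =", x$n_ref, "\n")
  invisible(x)
}

#' Dense correlation matrix of an LD reference
#'
#' @param x an `ld_reference`.
#' @param ... unused.
#' @return symmetric correlation matrix with unit diagonal; zero between
#'   blocks.
#' @export
as.matrix.ld_reference <- function(x, ...) {
  m <- length(x$snp_ids)
  R <- matrix(0, m, m, dimnames = list(x$snp_ids, x$snp_ids))
  off <- 0L
  for (b in x$R_blocks) {
    idx <- off + seq_len(nrow(b))
    R[idx, idx] <- b
    off <- off + nrow(b)
  }
  R
}

#' Subset an LD reference to a set of SNPs (genomic order preserved)
#'
#' @param ref an `ld_reference`.
#' @param snp_ids SNPs to keep.
#' @return a dense-block `ld_reference` on the kept SNPs.
#' @export
ld_subset <- function(ref, snp_ids) {
  keep <- which(ref$snp_ids %in% snp_ids)
  if (length(keep) == 0L) stop("no requested SNPs present in the reference")
  blocks <- list()
  for (bi in unique(ref$block_index[keep])) {
    rows <- which(ref$block_index == bi)
    sel <- match(intersect(rows, keep), rows)
    blocks[[length(blocks) + 1L]] <- ref$R_blocks[[bi]][sel, sel, drop = FALSE]
  }
  ld_reference(ref$snp_ids[keep], ref$chrom[keep], ref$pos[keep],
               ref$freqs[keep], blocks, n_ref = ref$n_ref,
               a1 = ref$a1[keep], a2 = ref$a2[keep])
}

#' Pairwise LD correlation from a dosage matrix
#'
#' Pearson correlation of dosage columns; missing dosages are mean-imputed
#' per SNP; frequencies come from dosage means / 2. Zero-variance
#' (monomorphic) SNPs get zero off-diagonal correlation and are flagged.
#'
#' @param genotypes n_ref x m numeric matrix of dosages in \[0, 2\]
#'   (column names taken as SNP ids).
#' @param chrom,pos optional coordinates for the SNPs.
#' @return an `ld_reference` with a single dense block; element
#'   `monomorphic` flags zero-variance SNPs.
#' @export
ld_matrix <- function(genotypes, chrom = "1", pos = NULL) {
  X <- as.matrix(genotypes)
  if (nrow(X) < 2L) stop("need at least 2 reference samples")
  if (any(X < 0 | X > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  freqs <- colMeans(X) / 2
  sds <- apply(X, 2, stats::sd)
  mono <- sds == 0 | !is.finite(sds)
  R <- matrix(0, ncol(X), ncol(X))
  if (any(!mono)) R[!mono, !mono] <- stats::cor(X[, !mono, drop = FALSE])
  diag(R) <- 1
  ids <- colnames(X) %||% paste0("snp", seq_len(ncol(X)))
  if (is.null(pos)) pos <- seq_len(ncol(X))
  ref <- ld_reference(ids, chrom, pos, freqs, R, n_ref = nrow(X))
  ref$monomorphic <- mono
  ref
}

#' Read PLINK bed/bim/fam genotypes into a dosage matrix
#'
#' Minimal decoder for SNP-major PLINK 1 binary files: returns the dosage
#' of the bim A1 allele per sample, with missing genotypes as NA.
#'
#' @param prefix path prefix (without extension) of the .bed/.bim/.fam trio.
#' @return list with `genotypes` (n x m matrix, SNP ids as colnames),
#'   `bim` and `fam` data.frames.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(108L, 27L, 1L)))
    stop("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) < bytes_per_snp * m) stop("truncated .bed file")
  # 2-bit codes per sample: 00 hom A1 (dosage 2), 10 het (1), 11 hom A2 (0),
  # 01 missing
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  ints <- as.integer(raw)
  codes <- rbind(bitwAnd(ints, 3L),
                 bitwAnd(bitwShiftR(ints, 2L), 3L),
                 bitwAnd(bitwShiftR(ints, 4L), 3L),
                 bitwAnd(bitwShiftR(ints, 6L), 3L))
  dim(codes) <- c(4 * bytes_per_snp, m)
  G <- matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  colnames(G) <- bim$snp_id
  list(genotypes = G, bim = bim, fam = fam)
}

#' Write genotypes as a PLINK bed/bim/fam trio
#'
#' @param genotypes n x m dosage matrix in \{0,1,2,NA\}.
#' @param prefix output path prefix.
#' @param chrom,pos,a1,a2 per-SNP metadata (defaults: chrom 1, index
#'   positions, alleles A/G).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(genotypes, prefix, chrom = "1", pos = NULL,
                        a1 = NULL, a2 = NULL) {
  G <- as.matrix(genotypes)
  n <- nrow(G); m <- ncol(G)
  ids <- colnames(G) %||% paste0("snp", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m)
  bim <- data.frame(chrom = rep_len(chrom, m), snp_id = ids, cm = 0, pos = pos,
                    a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m))
  fam <- data.frame(fid = seq_len(n), iid = seq_len(n), pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code <- matrix(3L, 4 * ceiling(n / 4), m)  # pad with hom A2
  g <- G[seq_len(n), , drop = FALSE]
  code[seq_len(n), ] <- ifelse(is.na(g), 1L, c(3L, 2L, 0L)[g + 1L])
  idx <- seq(1, nrow(code), by = 4)
  packed <- code[idx, , drop = FALSE] +
    4L * code[idx + 1, , drop = FALSE] +
    16L * code[idx + 2, , drop = FALSE] +
    64L * code[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(108L, 27L, 1L)), con)
  writeBin(as.raw(packed), con)
  invisible(prefix)
}

#' Read ALT-allele dosages from a VCF file
#'
#' Thin wrapper over vcfR for reference panels distributed as VCF.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return n x m dosage matrix with SNP ids as colnames.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a != "0"), numeric(1)))
  }
  G <- apply(gt, c(1, 2), function(g) dose(g))
  t(G)
}
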