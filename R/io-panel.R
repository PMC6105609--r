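#' Construct a reference genotype panel
#'
#' A panel holds a samples-by-SNPs dosage matrix (values in [0, 2]) plus a
#' SNP coordinate index. Monomorphic SNPs (zero dosage variance) are
#' removed, SNPs are sorted by chromosome then position, and duplicate
#' chrom:pos records are dropped. All r-squared values used by the LD
#' module are Pearson correlations of these dosage columns.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns.
#' @param snps data frame with columns snp_id, chrom, pos (and optionally
#'   a1, a2), one row per dosage column.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages` and `snps`.
#' @export
genotype_panel <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  if (nrow(snps) != ncol(dosages))
    stop_format("panel: %d SNP records but %d dosage columns",
                nrow(snps), ncol(dosages))
  if (nrow(dosages) == 0) stop_format("panel has no samples")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(snps$a1)) snps$a1 <- "N"
  if (is.null(snps$a2)) snps$a2 <- "N"
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  dup <- duplicated(paste(snps$chrom, snps$pos))
  v <- apply(dosages, 2, stats::var)
  keep <- !dup & v > 0
  n_mono <- sum(v == 0)
  snps <- snps[keep, , drop = FALSE]
  rownames(snps) <- NULL
  dosages <- dosages[, keep, drop = FALSE]
  colnames(dosages) <- snps$snp_id
  structure(list(dosages = dosages, snps = snps),
            class = "genotype_panel", n_monomorphic = n_mono,
            n_duplicate = sum(dup))
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$snps$chrom))))
  invisible(x)
}

#' Number of SNPs in a panel
#' @param panel a [genotype_panel()].
#' @export
n_snps <- function(panel) nrow(panel$snps)

# column-standardized dosage matrix (cached on the panel environment-free
# object is not possible; callers that reuse it pass it along explicitly)
standardize_panel <- function(panel) {
  scale(panel$dosages)
}

#' Read a reference panel from VCF or a TSV dosage matrix
#'
#' VCF input must contain GT genotypes; multi-allelic records are skipped
#' with a warning and missing genotypes are handled per `missing`
#' (mean imputation by default, which keeps all pairwise correlations
#' defined). The dosage format is the TSV written by [write_panel()]:
#' columns snp_id, chrom, pos, a1, a2, then one column per sample.
#'
#' @param path input file.
#' @param format "auto" (by extension), "vcf" or "dosage".
#' @param missing missing-genotype policy: "mean" imputes the per-SNP mean
#'   dosage, "zero" sets 0.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path, format = c("auto", "vcf", "dosage"),
                       missing = c("mean", "zero")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_panel_vcf(path, missing) else read_panel_dosage(path)
}

read_panel_vcf <- function(path, missing) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) == 0) stop_format("VCF %s contains no samples", path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) != 1
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    vcf <- vcf[!multi]
    alt <- VariantAnnotation::alt(vcf)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop_format("VCF %s has no GT field", path)
  count_alt <- function(g) {
    alleles <- strsplit(g, "[/|]")
    vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  dos <- apply(gt, 1, count_alt)              # samples x SNPs
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  if (missing == "mean") {
    for (j in seq_len(ncol(dos))) {
      na <- is.na(dos[, j])
      if (any(na)) dos[na, j] <- mean(dos[!na, j])
    }
  } else {
    dos[is.na(dos)] <- 0
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.frame(
    snp_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    a1 = as.character(unlist(alt)),
    a2 = as.character(VariantAnnotation::ref(vcf)),
    stringsAsFactors = FALSE
  )
  genotype_panel(dos, snps)
}

read_panel_dosage <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  meta <- c("snp_id", "chrom", "pos", "a1", "a2")
  if (!all(meta %in% names(df)))
    stop_format("dosage matrix %s lacks columns: %s", path,
                paste(setdiff(meta, names(df)), collapse = ", "))
  samp <- setdiff(names(df), meta)
  if (length(samp) == 0) stop_format("dosage matrix %s has no sample columns", path)
  dos <- t(as.matrix(df[, samp, drop = FALSE]))
  genotype_panel(dos, df[, meta])
}

#' Write a panel as a TSV dosage matrix
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  df <- cbind(panel$snps[, c("snp_id", "chrom", "pos", "a1", "a2")],
              as.data.frame(t(panel$dosages)))
  names(df)[-(1:5)] <- sprintf("s%03d", seq_len(nrow(panel$dosages)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

AMBIGUOUS_PAIRS <- c(AT = "A/T", TA = "T/A", CG = "C/G", GC = "G/C")

#' Harmonize summary statistics to a reference panel
#'
#' Matches SNPs on chromosome + position, flips the z sign when the
#' effect/other alleles are swapped relative to the panel, and drops
#' strand-ambiguous (A/T, C/G) and allele-mismatched SNPs. The result is
#' row-aligned with the panel SNP index (SNPs absent from the summary
#' statistics are absent from the result).
#'
#' @param sumstats a `sumstats` table (see [read_sumstats()]).
#' @param panel a [genotype_panel()].
#' @return A `sumstats` table aligned to the panel, with a report attribute
#'   counting flips and drops, and an integer attribute `panel_index`
#'   giving, for each row, the matching panel SNP column.
#' @export
harmonize_sumstats <- function(sumstats, panel) {
  key_ss <- paste(norm_chrom(sumstats$chrom), sumstats$pos)
  key_pn <- paste(norm_chrom(panel$snps$chrom), panel$snps$pos)
  idx <- match(key_pn, key_ss)          # panel order
  hit <- which(!is.na(idx))
  ss <- as.data.frame(sumstats)[idx[hit], , drop = FALSE]
  pn <- panel$snps[hit, , drop = FALSE]

  ambiguous <- paste0(ss$a1, ss$a2) %in% names(AMBIGUOUS_PAIRS)
  same <- ss$a1 == pn$a1 & ss$a2 == pn$a2
  swapped <- ss$a1 == pn$a2 & ss$a2 == pn$a1
  no_alleles <- ss$a1 == "N" | pn$a1 == "N"   # allele-free sources: keep as-is
  keep <- !ambiguous & (same | swapped | no_alleles)

  ss$z[swapped & keep] <- -ss$z[swapped & keep]
  tmp <- ss$a1[swapped & keep]
  ss$a1[swapped & keep] <- ss$a2[swapped & keep]
  ss$a2[swapped & keep] <- tmp

  report <- list(
    n_input = nrow(sumstats), n_kept = sum(keep),
    n_dropped = nrow(sumstats) - sum(keep),
    reasons = c(unmatched = nrow(sumstats) - length(hit),
                ambiguous = sum(ambiguous),
                allele_mismatch = sum(!ambiguous & !(same | swapped | no_alleles)),
                flipped = sum(swapped & keep))
  )
  out <- new_sumstats(ss[keep, , drop = FALSE], report = report)
  attr(out, "panel_index") <- hit[keep]
  out
}
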