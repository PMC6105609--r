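#' Genomic-control inflation factor from intergenic SNPs
#'
#' Estimates lambda_GC as the median squared z-score of independent
#' (LD-pruned) sets of intergenic SNPs, aggregated over repeated pruning
#' iterations, divided by the chi-square(1) median (0.4549364). Intergenic
#' SNPs are used because their relative depletion of true associations
#' makes them a reliably null set, so their median chi-square reflects
#' confounding inflation (e.g. cryptic relatedness) rather than polygenic
#' signal.
#'
#' @param sumstats a `sumstats` table; SNPs are matched to the panel by
#'   snp_id.
#' @param intergenic logical vector over panel SNPs (see
#'   [classify_intergenic()]).
#' @param panel a [genotype_panel()].
#' @param iterations number of seeded LD-pruning draws (100).
#' @param r2_threshold pruning threshold defining "independent" (0.2).
#' @param window_bp LD window half-width.
#' @param seed integer; iteration i prunes with seed `seed + i`.
#' @param aggregate how to combine the per-iteration medians: "median"
#'   (default) or "mean".
#' @return lambda_GC as a single number, with attribute `n_pruned` (median
#'   kept-set size).
#' @export
lambda_gc <- function(sumstats, intergenic, panel, iterations = 100,
                      r2_threshold = 0.2, window_bp = 1e6, seed = 1,
                      aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  candidates <- which(intergenic)
  if (length(candidates) == 0)
    stop_format("lambda_gc: empty intergenic set")
  idx <- match(panel$snps$snp_id[candidates], sumstats$snp_id)
  candidates <- candidates[!is.na(idx)]
  z_of <- numeric(n_snps(panel))
  z_of[candidates] <- sumstats$z[idx[!is.na(idx)]]
  if (length(candidates) < 100)
    warning("lambda_gc: fewer than 100 intergenic SNPs with summary statistics")
  pairs <- ld_pairs(panel, window_bp, r2_threshold, candidates)
  med <- vapply(seq_len(iterations), function(it) {
    kept <- ld_prune(panel, candidates, r2_threshold, window_bp,
                     seed = seed + it, pairs = pairs)
    median(z_of[kept]^2)
  }, numeric(1))
  agg <- if (aggregate == "median") median(med) else mean(med)
  structure(agg / CHISQ1_MEDIAN,
            n_pruned = length(ld_prune(panel, candidates, r2_threshold,
                                       window_bp, seed = seed, pairs = pairs)))
}

#' Apply genomic-control correction
#'
#' Divides z-scores by sqrt(lambda_GC) (equivalently chi-squares by
#' lambda) and recomputes p-values, when lambda_GC > 1; the identity
#' otherwise (deflation is never amplified).
#'
#' @param sumstats a `sumstats` table.
#' @param lambda lambda_GC estimate, must be > 0.
#' @return Corrected `sumstats` table with attribute `lambda_gc`.
#' @export
gc_correct <- function(sumstats, lambda) {
  if (!is.finite(lambda) || lambda <= 0)
    stop_format("gc_correct: lambda_GC must be positive")
  out <- as.data.frame(sumstats)
  if (lambda > 1) {
    out$z <- out$z / sqrt(lambda)
    out$p <- pmax(2 * pnorm(-abs(out$z)), .Machine$double.xmin)
  }
  out <- new_sumstats(out, report = validation_report(sumstats))
  attr(out, "lambda_gc") <- as.numeric(lambda)
  out
}

#' Conditional Q-Q curves by SNP stratum
#'
#' For each stratum, p-values are sorted ascending (ties broken by snp_id
#' for a stable order), the empirical p for rank r of n is r/(n + 1), and
#' points are emitted with nominal -log10(p) below 7.3 (p > 5e-8) so the
#' curves describe polygenic, sub-genome-wide-significant signal. An
#' enriched stratum deflects leftward: its empirical quantiles exceed the
#' nominal ones.
#'
#' @param sumstats a `sumstats` table.
#' @param strata named list of logical vectors over `sumstats` rows.
#' @return Named list of `qq_curve` data frames with columns
#'   `nominal_nlog10p` and `empirical_nlog10p`; empty strata are skipped
#'   with a warning.
#' @export
conditional_qq <- function(sumstats, strata) {
  stopifnot(length(names(strata)) == length(strata))
  out <- list()
  for (nm in names(strata)) {
    mask <- strata[[nm]]
    if (sum(mask) == 0) {
      warning(sprintf("conditional_qq: stratum '%s' has no SNPs, skipped", nm))
      next
    }
    p <- sumstats$p[mask]
    id <- sumstats$snp_id[mask]
    ord <- order(p, id)
    p <- p[ord]
    n <- length(p)
    emp <- seq_len(n) / (n + 1)
    keep <- -log10(p) < NLOG10P_CAP
    out[[nm]] <- structure(
      data.frame(nominal_nlog10p = -log10(p[keep]),
                 empirical_nlog10p = -log10(emp[keep])),
      class = c("qq_curve", "data.frame"), label = nm, n_stratum = n)
  }
  out
}

#' Fold-enrichment curve of a SNP stratum
#'
#' At each grid abscissa x (in -log10 p units), the complementary
#' empirical CDF of the stratum, `CDF_s(x) = #\{stratum SNPs with
#' -log10(p) >= x\} / #stratum`, is divided by the same quantity over all
#' SNPs. A value above 1 ("upward deflection") means the stratum holds a
#' higher proportion of small p-values than the genome as a whole;
#' `fold(0) = 1` by construction. Points where fewer than `min_count`
#' SNPs feed the denominator tail are flagged unreliable; points with an
#' empty denominator are NA and flagged undefined.
#'
#' @param sumstats a `sumstats` table.
#' @param stratum logical vector over `sumstats` rows (non-empty).
#' @param grid abscissae in [0, 7.3).
#' @param min_count reliability threshold on the denominator tail count.
#' @return A `fold_curve` data frame with columns x, fold, n_stratum,
#'   n_all (tail counts) and reliable.
#' @export
fold_enrichment <- function(sumstats, stratum,
                            grid = seq(0, 7.2, by = 0.1), min_count = 5) {
  if (sum(stratum) == 0) stop_format("fold_enrichment: empty stratum")
  if (any(grid < 0 | grid >= NLOG10P_CAP))
    stop_format("fold_enrichment: grid must lie in [0, 7.3)")
  nl <- -log10(sumstats$p)
  nl_s <- nl[stratum]
  n_s <- vapply(grid, function(x) sum(nl_s >= x), numeric(1))
  n_a <- vapply(grid, function(x) sum(nl >= x), numeric(1))
  cdf_s <- n_s / length(nl_s)
  cdf_a <- n_a / length(nl)
  fold <- ifelse(n_a > 0, cdf_s / cdf_a, NA_real_)
  structure(data.frame(x = grid, fold = fold, n_stratum = n_s, n_all = n_a,
                       reliable = n_a >= min_count),
            class = c("fold_curve", "data.frame"),
            label = attr(stratum, "label") %||% "stratum",
            w_stratum = sum(stratum) / length(stratum))
}

#' @export
print.fold_curve <- function(x, ...) {
  cat(sprintf("fold_curve '%s': %d grid points, fold range [%.2f, %.2f]\n",
              attr(x, "label"), nrow(x),
              min(x$fold, na.rm = TRUE), max(x$fold, na.rm = TRUE)))
  invisible(x)
}

#' Write curve data as TSV
#' @param x a `qq_curve` or `fold_curve` data frame.
#' @param path output path.
#' @export
write_curve <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  invisible(path)
}
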