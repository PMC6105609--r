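#' Column-name dialect for summary-statistics files
#'
#' GWAS summary statistics come with heterogeneous headers. A dialect maps
#' the canonical field names used throughout this package onto the column
#' names of a particular file. Fields whose columns are absent from the
#' file may be left in place; [read_sumstats()] only requires that the
#' mandatory fields (snp, chrom, pos, n, and z or p) resolve.
#'
#' @param snp,chrom,pos,a1,a2,z,p,n,beta column names in the file for the
#'   SNP identifier, chromosome, 1-based position, effect and other allele,
#'   z-score, two-sided p-value, sample size, and signed effect estimate.
#' @return A named list of class `sumstats_dialect`.
#' @export
#' @examples
#' sumstats_dialect(snp = "SNP", chrom = "CHR", pos = "BP", p = "P", n = "N")
sumstats_dialect <- function(snp = "snp_id", chrom = "chrom", pos = "pos",
                             a1 = "a1", a2 = "a2", z = "z", p = "p",
                             n = "n", beta = "beta") {
  structure(list(snp = snp, chrom = chrom, pos = pos, a1 = a1, a2 = a2,
                 z = z, p = p, n = n, beta = beta),
            class = "sumstats_dialect")
}

new_sumstats <- function(df, report = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"), report = report)
}

#' Read and validate GWAS summary statistics
#'
#' Reads a tab- or whitespace-delimited file with a header line, resolves
#' columns through a [sumstats_dialect()], and validates each row. Rows
#' failing validation (p outside (0, 1], non-positive position or sample
#' size, duplicated SNP id, or mutually inconsistent z and p) are dropped
#' and counted in the attached report. When only a p-value and an effect
#' direction are present, the z-score is reconstructed as
#' sign(beta) * qnorm(1 - p/2); when only z is present, p = 2 * pnorm(-|z|).
#'
#' @param path path to the summary-statistics file.
#' @param dialect a [sumstats_dialect()] mapping canonical fields to the
#'   file's column names.
#' @return A `sumstats` data frame with columns snp_id, chrom, pos, a1, a2,
#'   z, p, n and a `report` attribute (see [validation_report()]).
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("snp", "chrom", "pos", "n")
  missing_cols <- vapply(need, function(f) !(dialect[[f]] %in% names(raw)),
                         logical(1))
  if (any(missing_cols))
    stop_format("summary-statistics file %s lacks mandatory column(s): %s",
                path, paste(unlist(dialect[need[missing_cols]]), collapse = ", "))
  has_z <- dialect$z %in% names(raw)
  has_p <- dialect$p %in% names(raw)
  has_beta <- dialect$beta %in% names(raw)
  if (!has_z && !has_p)
    stop_format("summary-statistics file %s has neither a z nor a p column", path)

  grab <- function(f, default = NA) {
    if (dialect[[f]] %in% names(raw)) raw[[dialect[[f]]]] else rep(default, nrow(raw))
  }
  df <- data.frame(
    snp_id = as.character(grab("snp")),
    chrom  = as.character(grab("chrom")),
    pos    = as.integer(grab("pos")),
    a1     = toupper(as.character(grab("a1", "N"))),
    a2     = toupper(as.character(grab("a2", "N"))),
    z      = if (has_z) as.numeric(raw[[dialect$z]]) else NA_real_,
    p      = if (has_p) as.numeric(raw[[dialect$p]]) else NA_real_,
    n      = as.numeric(grab("n")),
    stringsAsFactors = FALSE
  )
  beta <- if (has_beta) as.numeric(raw[[dialect$beta]]) else NULL

  reasons <- c(bad_p = 0L, bad_pos = 0L, bad_n = 0L, missing = 0L,
               z_p_inconsistent = 0L, no_direction = 0L, duplicate_id = 0L)
  drop <- logical(nrow(df))

  mark <- function(bad, reason) {
    bad <- bad & !drop
    reasons[[reason]] <<- reasons[[reason]] + sum(bad)
    drop <<- drop | bad
  }
  mark(is.na(df$snp_id) | is.na(df$chrom) | is.na(df$pos) | is.na(df$n),
       "missing")
  if (has_p) mark(!is.na(df$p) & (df$p <= 0 | df$p > 1), "bad_p")
  mark(!is.na(df$pos) & df$pos < 1, "bad_pos")
  mark(!is.na(df$n) & df$n <= 0, "bad_n")

  if (has_z && has_p) {
    both <- !is.na(df$z) & !is.na(df$p)
    p_from_z <- 2 * pnorm(-abs(df$z))
    rel <- abs(df$p - p_from_z) / pmax(df$p, .Machine$double.xmin)
    mark(both & rel > 1e-6, "z_p_inconsistent")
  } else if (has_z) {
    df$p <- 2 * pnorm(-abs(df$z))
  } else {
    if (is.null(beta)) {
      stop_format("file %s has p-values but no z or effect column to sign them",
                  path)
    }
    mark(is.na(beta) | beta == 0, "no_direction")
    df$z <- sign(beta) * qnorm(1 - df$p / 2)
  }
  mark(is.na(df$z) | is.na(df$p), "missing")
  mark(duplicated(df$snp_id), "duplicate_id")

  report <- list(n_input = nrow(df), n_kept = sum(!drop),
                 n_dropped = sum(drop), reasons = reasons)
  new_sumstats(df[!drop, , drop = FALSE], report = report)
}

#' Validation report of a read operation
#'
#' @param x an object returned by [read_sumstats()] or [harmonize_sumstats()].
#' @return A list with `n_input`, `n_kept`, `n_dropped` and per-reason counts.
#' @export
validation_report <- function(x) attr(x, "report")

#' Write summary statistics as canonical TSV
#'
#' Writes the canonical columns (snp_id, chrom, pos, a1, a2, z, p, n); the
#' output reads back identically with the default [sumstats_dialect()].
#'
#' @param x a `sumstats` data frame.
#' @param path output path.
#' @export
write_sumstats <- function(x, path) {
  cols <- c("snp_id", "chrom", "pos", "a1", "a2", "z", "p", "n")
  data.table::fwrite(as.data.frame(x)[, cols], path, sep = "\t")
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  rep <- validation_report(x)
  cat(sprintf("GWAS summary statistics: %d SNPs", nrow(x)))
  if (!is.null(rep))
    cat(sprintf(" (%d read, %d dropped)", rep$n_input, rep$n_dropped))
  cat("\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
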