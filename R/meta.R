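#' Fisher's combined probability test
#'
#' Combines k independent p-values via `X2 = -2 * sum(log(p))`, which is
#' chi-square distributed with 2k degrees of freedom under the joint null.
#' Independence of the combined tests is assumed; traits sharing samples
#' violate it and make the combination anti-conservative (documented
#' limitation).
#'
#' @param pvalues numeric vector of p-values in (0, 1], k >= 1.
#' @param label optional group label carried into the result.
#' @return A `meta_result`: list with `label`, `k`, `chi2_stat`, `df` and
#'   `p_combined`.
#' @export
fisher_combine <- function(pvalues, label = "group") {
  if (length(pvalues) == 0)
    stop_format("fisher_combine: empty p-value list")
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop_format("fisher_combine: p-values must lie in (0, 1]")
  k <- length(pvalues)
  stat <- -2 * sum(log(pvalues))
  structure(list(label = label, k = k, chi2_stat = stat, df = 2L * k,
                 p_combined = pchisq(stat, df = 2 * k, lower.tail = FALSE)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fisher combination '%s': k = %d, X2(%d) = %.3f, p = %s\n",
              x$label, x$k, x$df, x$chi2_stat, format_pvalue(x$p_combined)))
  invisible(x)
}

#' Group-wise Fisher combination of a result table
#'
#' Convenience wrapper over [fisher_combine()] for a table of per-phenotype
#' enrichment p-values, e.g. read from the TSV written by an enrichment
#' run: one combined test per group.
#'
#' @param df data frame with columns `phenotype`, `group` and `p`.
#' @return Data frame with one row per group: group, k, chi2_stat, df,
#'   p_combined.
#' @export
meta_combine <- function(df) {
  stopifnot(all(c("phenotype", "group", "p") %in% names(df)))
  groups <- unique(df$group)
  rows <- lapply(groups, function(g) {
    r <- fisher_combine(df$p[df$group == g], label = g)
    data.frame(group = g, k = r$k, chi2_stat = r$chi2_stat, df = r$df,
               p_combined = r$p_combined)
  })
  do.call(rbind, rows)
}
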