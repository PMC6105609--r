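#' Stratified LD-score regression with block jackknife
#'
#' Fits the partitioned polygenic model `E[chisq_j] = 1 + N*a +
#' N * sum_c tau_c * ell(j, c)` by two-step weighted least squares with a
#' free intercept: step 1 uses weights `1/max(ell_total, 1)`; step 2
#' re-weights by `1/(max(ell_total, 1) * max(1, E-hat[chisq_j])^2)` using
#' the step-1 fitted values. A delete-a-block jackknife over `n_blocks`
#' contiguous SNP blocks (equal SNP counts in chromosome order) yields the
#' coefficient covariance and, for each category, the enrichment fold
#' `(h2_c / h2_total) / (M_c / M)` with a standard error obtained by
#' jackknifing the ratio directly. Per-category heritability is
#' `h2_c = sum_{j in c} sum_c' tau_c' a_jc'` over reference SNPs.
#'
#' `p_coefficient` is the two-sided normal test of `tau_c / se(tau_c)`
#' (the coefficient test, reported in the field as beta for the focal
#' annotation); `p_enrichment` is the two-sided normal test of
#' `(fold_c - 1) / se(fold_c)`.
#'
#' @param chisq per-SNP chi-square statistics (z squared), aligned with
#'   the rows of `ldscores`.
#' @param n per-SNP GWAS sample size (scalar or vector).
#' @param ldscores an `ldscore_table` from [partitioned_ld_scores()],
#'   containing the `base` all-SNPs category.
#' @param n_blocks number of jackknife blocks (200).
#' @return An `enrichment_result`: list with `tau`, `tau_se`, `intercept`,
#'   `coef_cov` (jackknife covariance of intercept + tau), `h2_total`,
#'   `h2_c`, `M_c`, `M`, `fold`, `fold_se`, `p_enrichment`,
#'   `p_coefficient`, `n_blocks`, `dropped` (constant categories removed).
#' @export
fit_stratified <- function(chisq, n, ldscores, n_blocks = 200) {
  stopifnot(inherits(ldscores, "ldscore_table"))
  ell <- ldscores$ell
  M_j <- nrow(ell)
  if (length(chisq) != M_j)
    stop_format("fit_stratified: chisq length %d != %d regression SNPs",
                length(chisq), M_j)
  if (length(n) == 1) n <- rep(n, M_j)
  if (!("base" %in% colnames(ell)))
    stop_format("fit_stratified: ldscores must include the 'base' category")

  # drop categories with a constant LD-score column (collinear with the
  # free intercept and unidentifiable)
  const <- apply(ell, 2, function(col) diff(range(col)) == 0)
  const["base"] <- FALSE
  dropped <- colnames(ell)[const]
  if (length(dropped) > 0) {
    warning(sprintf("dropping constant LD-score column(s): %s",
                    paste(dropped, collapse = ", ")))
    ell <- ell[, !const, drop = FALSE]
  }
  cats <- colnames(ell)
  C <- length(cats)
  if (C + 1 >= M_j)
    stop_format("fit_stratified: more coefficients than SNPs")

  ell_total <- ell[, "base"]
  X <- cbind(intercept = 1, ell * n)
  y <- chisq

  wls <- function(w) {
    xw <- X * sqrt(w)
    solve(crossprod(xw), crossprod(xw, y * sqrt(w)))
  }
  w1 <- 1 / pmax(ell_total, 1)
  beta1 <- wls(w1)
  yhat <- pmax(drop(X %*% beta1), 1)
  w2 <- 1 / (pmax(ell_total, 1) * yhat^2)

  # block-sum sufficient statistics for fast leave-one-out refits
  block <- make_blocks(M_j, n_blocks)
  B <- max(block)
  xw <- X * sqrt(w2)
  yw <- y * sqrt(w2)
  p <- ncol(X)
  Sxx_b <- array(0, c(p, p, B))
  Sxy_b <- matrix(0, p, B)
  for (b in seq_len(B)) {
    idx <- which(block == b)
    Sxx_b[, , b] <- crossprod(xw[idx, , drop = FALSE])
    Sxy_b[, b] <- crossprod(xw[idx, , drop = FALSE], yw[idx])
  }
  Sxx <- rowSums(Sxx_b, dims = 2)
  Sxy <- rowSums(Sxy_b)
  coef_full <- drop(solve(Sxx, Sxy))

  O <- ldscores$overlap[cats, cats, drop = FALSE]
  M_c <- ldscores$M_c[cats]
  M <- ldscores$M_c[["base"]]
  # heritability below this contributes < 1e-8 to the mean chi-square:
  # numerically zero, so enrichment folds are undefined rather than 0/0
  h2_tol <- 1e-8 * M / (mean(n) * mean(pmax(ell_total, 1)))
  fold_of <- function(tau) {
    h2_c <- drop(O %*% tau)
    h2 <- h2_c[["base"]]
    if (h2 <= h2_tol)
      return(list(fold = rep(NA_real_, C), h2_c = h2_c, h2 = h2))
    list(fold = (h2_c / h2) / (M_c / M), h2_c = h2_c, h2 = h2)
  }

  coef_jk <- matrix(0, B, p, dimnames = list(NULL, colnames(X)))
  fold_jk <- matrix(0, B, C, dimnames = list(NULL, cats))
  for (b in seq_len(B)) {
    cb <- drop(solve(Sxx - Sxx_b[, , b], Sxy - Sxy_b[, b]))
    coef_jk[b, ] <- cb
    fold_jk[b, ] <- fold_of(cb[-1])$fold
  }
  jack_cov <- function(est) {
    d <- sweep(est, 2, colMeans(est))
    crossprod(d) * (B - 1) / B
  }
  coef_cov <- jack_cov(coef_jk)
  tau <- coef_full[-1]
  names(tau) <- cats
  tau_se <- sqrt(diag(coef_cov))[-1]
  full <- fold_of(tau)
  fold_se <- if (anyNA(fold_jk)) rep(NA_real_, C) else
    sqrt(diag(jack_cov(fold_jk)))
  names(fold_se) <- cats
  fold_se["base"] <- 0                      # fold(base) = 1 identically

  p_coef <- 2 * pnorm(-abs(tau / tau_se))
  p_enr <- ifelse(is.na(full$fold) | fold_se == 0, NA_real_,
                  2 * pnorm(-abs((full$fold - 1) / fold_se)))
  names(p_enr) <- cats

  structure(list(tau = tau, tau_se = tau_se, intercept = coef_full[1],
                 coef_cov = coef_cov, h2_total = full$h2, h2_c = full$h2_c,
                 M_c = M_c, M = M, fold = full$fold, fold_se = fold_se,
                 p_enrichment = p_enr, p_coefficient = p_coef,
                 n_blocks = B, dropped = dropped),
            class = "enrichment_result")
}

make_blocks <- function(m, n_blocks) {
  n_blocks <- max(1L, min(n_blocks, m))
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("stratified LD-score regression: %d categories, intercept %.3f, h2 %.4f\n",
              length(x$tau), x$intercept, x$h2_total))
  df <- data.frame(category = names(x$tau),
                   tau = x$tau, fold = x$fold, fold_se = x$fold_se,
                   p_enrichment = x$p_enrichment,
                   p_coefficient = x$p_coefficient)
  rownames(df) <- NULL
  print(df, ...)
  invisible(x)
}

#' Render a p-value in table style
#'
#' `format_pvalue(0.0263)` gives `"2.63 × 10−2"` (three
#' significant digits, multiplication sign, unicode minus).
#'
#' @param p numeric vector of p-values.
#' @param digits significant digits for the mantissa.
#' @export
format_pvalue <- function(p, digits = 3) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) return(NA_character_)
    e <- floor(log10(pi))
    m <- signif(pi / 10^e, digits)
    exp_str <- if (e < 0) paste0("−", -e) else as.character(e)
    sprintf("%s × 10%s", format(m), exp_str)
  }, character(1))
}

#' Tabulate enrichment results across phenotypes
#'
#' Projects a list of [fit_stratified()] results into one row per
#' phenotype for a focal category: Fold +/- s.e.m., enrichment p-value and
#' coefficient p-value.
#'
#' @param results named list of `enrichment_result` objects (names are
#'   phenotype labels).
#' @param category focal category (default "hd").
#' @return Data frame with columns phenotype, fold, fold_se, p_enrichment,
#'   p_enrichment_fmt, p_coefficient, p_coefficient_fmt.
#' @export
enrichment_table <- function(results, category = "hd") {
  if (length(results) == 0)
    return(data.frame(phenotype = character(), fold = numeric(),
                      fold_se = numeric(), p_enrichment = numeric(),
                      p_enrichment_fmt = character(),
                      p_coefficient = numeric(),
                      p_coefficient_fmt = character()))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(phenotype = nm,
               fold = r$fold[[category]], fold_se = r$fold_se[[category]],
               p_enrichment = r$p_enrichment[[category]],
               p_enrichment_fmt = format_pvalue(r$p_enrichment[[category]]),
               p_coefficient = r$p_coefficient[[category]],
               p_coefficient_fmt = format_pvalue(r$p_coefficient[[category]]))
  })
  do.call(rbind, rows)
}
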