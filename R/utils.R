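#' @importFrom stats cor median pchisq pnorm qchisq qnorm rbinom rnorm runif
#'   sd weighted.mean ks.test
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed RNG seed when `seed` is non-NULL, otherwise use
# the current RNG stream. All stochastic operations in the package route
# through this so results are reproducible from a single integer.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# chi-square(1) median; denominator of the genomic-control factor
CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

# -log10(5e-8): curves and Q-Q statistics are truncated at genome-wide
# significance so they describe the polygenic (sub-threshold) signal only
NLOG10P_CAP <- -log10(5e-8)

# strip an optional "chr" prefix so "6" and "chr6" compare equal
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))
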