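# Fixture builders and independent brute-force oracles used across the
# suite. Everything is generated in code; nothing is read from disk except
# through tempfiles written here.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small panel with iid Binomial(2, maf) dosages, all SNPs mutually within
# one LD window unless spacing says otherwise
toy_panel <- function(M = 20, n = 60, seed = 1, spacing = 1000,
                      chrom = NULL, maf = NULL) {
  withr::with_seed(seed, {
    maf <- maf %||% runif(M, 0.2, 0.5)
    dos <- sapply(maf, function(p) rbinom(n, 2, p))
    # guard against monomorphic draws
    for (j in which(apply(dos, 2, sd) == 0)) dos[1, j] <- 2 - dos[1, j]
    genotype_panel(dos, data.frame(
      snp_id = sprintf("rs%03d", seq_len(M)),
      chrom = chrom %||% rep("chr1", M),
      pos = seq_len(M) * spacing, a1 = "A", a2 = "G"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense r2 with self = 1 exactly
oracle_r2 <- function(panel) {
  r2 <- cor(panel$dosages)^2
  diag(r2) <- 1
  r2
}

in_window <- function(panel, window_bp = 1e6) {
  pos <- panel$snps$pos
  same <- outer(panel$snps$chrom, panel$snps$chrom, "==")
  same & abs(outer(pos, pos, "-")) <= window_bp
}

# double-loop oracle for the LD-weighted region score
oracle_region_score <- function(panel, delta, window_bp = 1e6,
                                r2_threshold = 0.2) {
  r2 <- oracle_r2(panel)
  r2[r2 < r2_threshold] <- 0
  r2[!in_window(panel, window_bp)] <- 0
  as.vector(r2 %*% delta)
}

# double-loop oracle for partitioned LD scores with the bias adjustment
oracle_ld_scores <- function(panel, A, window_bp = 1e6) {
  n <- nrow(panel$dosages)
  r2 <- oracle_r2(panel)
  adj <- r2 - (1 - r2) / (n - 2)
  adj[!in_window(panel, window_bp)] <- 0
  adj %*% cbind(base = 1, A)
}

# standard sumstats table straight from vectors
toy_sumstats <- function(z, chrom = "chr1", pos = seq_along(z) * 1000,
                         n = 10000) {
  sweepenrich:::new_sumstats(data.frame(
    snp_id = sprintf("rs%03d", seq_along(z)), chrom = chrom, pos = pos,
    a1 = "A", a2 = "G", z = z, p = pmax(2 * pnorm(-abs(z)), 1e-300), n = n))
}
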