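#' Configuration for the synthetic GWAS world
#'
#' Describes the generative model the enrichment analysis presumes: a
#' block-LD reference panel (haplotypes from a Gaussian copula with
#' exchangeable within-block latent correlation, thresholded at the drawn
#' minor-allele frequency), annotation tracks covering stated genome
#' fractions, and summary z-scores whose expected chi-square follows the
#' partitioned polygenic model `E[chisq_j] = a + N * sum_c tau_c *
#' ell(j, c)` with annotation-specific per-SNP heritability tau_c and
#' confounding intercept `a = intercept_inflation`.
#'
#' Defaults describe a desk-scale genome: 20,000 SNPs in 800 LD blocks of
#' 25 SNPs, 10 kb SNP spacing on 2 chromosomes (so a +/- 1 Mb window spans
#' +/- 100 SNPs and several blocks), a 200-sample panel, GWAS N = 50,000,
#' sweep regions covering 5% of SNPs, genes 30% (with exon/UTR/intron
#' substructure), brain genes a quarter of genes, and total SNP
#' heritability 0.5 spread evenly (no enrichment) unless `tau` says
#' otherwise.
#'
#' @param M number of SNPs.
#' @param n_blocks_ld number of LD blocks (M must be divisible by it).
#' @param block_rho latent within-block correlation: a scalar in [0, 1),
#'   or a length-2 range from which each block draws its own correlation
#'   (LD strength varies along real genomes).
#' @param n_panel reference-panel samples (>= 10).
#' @param N_gwas GWAS sample size.
#' @param maf_range minor-allele frequency range (uniform draw).
#' @param spacing_bp basepairs between adjacent SNPs.
#' @param n_chrom number of synthetic chromosomes.
#' @param frac_hd,frac_gene fractions of SNPs inside sweep (HD) regions
#'   and gene bodies (block-aligned placement).
#' @param exon_share share of gene-interior SNPs that are exonic.
#' @param brain_share share of gene blocks that are brain genes.
#' @param frac_context fraction of non-genic SNPs in each of the ncRNA,
#'   TFBS and miRNA-site context tracks.
#' @param h2_total total SNP heritability on the z-score scale.
#' @param tau optional named per-SNP heritability increments for model
#'   categories (e.g. `c(hd = ...)`) added on top of the uniform base;
#'   see [tau_for_fold()] to target a given enrichment fold.
#' @param intercept_inflation multiplicative confounding inflation of the
#'   null chi-square (>= 1; 1 = none).
#' @param seed integer master seed; sub-steps use seed, seed+1, seed+2.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(M = 20000, n_blocks_ld = M / 25, block_rho = 0.7,
                       n_panel = 200, N_gwas = 50000,
                       maf_range = c(0.05, 0.5), spacing_bp = 10000,
                       n_chrom = 2, frac_hd = 0.05, frac_gene = 0.30,
                       exon_share = 0.10, brain_share = 0.25,
                       frac_context = 0.01, h2_total = 0.5,
                       tau = c(), intercept_inflation = 1, seed = 42) {
  if (M %% n_blocks_ld != 0)
    stop_format("sim_config: M must be divisible by n_blocks_ld")
  if (!length(block_rho) %in% 1:2 || any(block_rho < 0) || any(block_rho >= 1))
    stop_format("sim_config: block_rho must be a value or range in [0, 1)")
  if (n_panel < 10) stop_format("sim_config: n_panel must be >= 10")
  if (intercept_inflation < 1)
    stop_format("sim_config: intercept_inflation must be >= 1")
  if (frac_hd > 1 || frac_gene > 1 || frac_hd < 0 || frac_gene < 0)
    stop_format("sim_config: fractions must lie in [0, 1]")
  if (any(tau < 0)) stop_format("sim_config: tau entries must be >= 0")
  structure(list(M = as.integer(M), n_blocks_ld = as.integer(n_blocks_ld),
                 block_size = as.integer(M / n_blocks_ld),
                 block_rho = block_rho, n_panel = as.integer(n_panel),
                 N_gwas = N_gwas, maf_range = maf_range,
                 spacing_bp = as.integer(spacing_bp),
                 n_chrom = as.integer(n_chrom), frac_hd = frac_hd,
                 frac_gene = frac_gene, exon_share = exon_share,
                 brain_share = brain_share, frac_context = frac_context,
                 h2_total = h2_total, tau = tau,
                 intercept_inflation = intercept_inflation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic SNP layout implied by a config: blocks are contiguous,
# chromosomes carry equal numbers of whole blocks
sim_layout <- function(cfg) {
  blocks_per_chrom <- ceiling(cfg$n_blocks_ld / cfg$n_chrom)
  block <- rep(seq_len(cfg$n_blocks_ld), each = cfg$block_size)
  chrom_of_block <- rep(seq_len(cfg$n_chrom), each = blocks_per_chrom,
                        length.out = cfg$n_blocks_ld)
  chrom <- paste0("chr", chrom_of_block[block])
  idx_in_chrom <- stats::ave(seq_len(cfg$M), chrom, FUN = seq_along)
  pos <- as.integer(idx_in_chrom * cfg$spacing_bp)
  list(block = block, chrom = chrom, pos = pos,
       snp_id = sprintf("snp%06d", seq_len(cfg$M)))
}

#' Generate a synthetic reference panel
#'
#' Dosages are sums of two independent haplotypes; each haplotype allele
#' is an indicator that a latent Gaussian (exchangeable within-block
#' correlation `block_rho`) falls below the MAF quantile. Monomorphic
#' columns are resampled. A fixed seed yields a bitwise-identical panel.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_panel()] with extra attributes `maf`, `block` and
#'   `cfg` used by [generate_sumstats()].
#' @export
generate_panel <- function(cfg) {
  lay <- sim_layout(cfg)
  with_seed_opt(cfg$seed, {
    maf <- runif(cfg$M, cfg$maf_range[1], cfg$maf_range[2])
    q <- qnorm(maf)
    rho <- if (length(cfg$block_rho) == 2)
      runif(cfg$n_blocks_ld, cfg$block_rho[1], cfg$block_rho[2])
    else rep(cfg$block_rho, cfg$n_blocks_ld)
    nh <- 2L * cfg$n_panel
    # per-haplotype shared block factor + per-SNP noise, block by block to
    # keep memory flat
    dos <- matrix(0L, cfg$n_panel, cfg$M)
    u1 <- matrix(rnorm(nh * cfg$n_blocks_ld), nh)
    for (b in seq_len(cfg$n_blocks_ld)) {
      sr <- sqrt(rho[b]); se <- sqrt(1 - rho[b])
      cols <- which(lay$block == b)
      lat <- sr * u1[, b] + se * matrix(rnorm(nh * length(cols)), nh)
      al <- lat < matrix(q[cols], nh, length(cols), byrow = TRUE)
      dos[, cols] <- al[seq_len(cfg$n_panel), , drop = FALSE] +
        al[cfg$n_panel + seq_len(cfg$n_panel), , drop = FALSE]
      # resample monomorphic columns (rare; fresh noise, same shared factor)
      mono <- which(apply(dos[, cols, drop = FALSE], 2, stats::var) == 0)
      guard <- 0
      while (length(mono) > 0 && guard < 100) {
        for (m in mono) {
          lat_m <- sr * u1[, b] + se * rnorm(nh)
          al_m <- lat_m < q[cols[m]]
          dos[, cols[m]] <- al_m[seq_len(cfg$n_panel)] +
            al_m[cfg$n_panel + seq_len(cfg$n_panel)]
        }
        mono <- mono[apply(dos[, cols[mono], drop = FALSE], 2, stats::var) == 0]
        guard <- guard + 1
      }
    }
    panel <- genotype_panel(dos, data.frame(snp_id = lay$snp_id,
                                            chrom = lay$chrom, pos = lay$pos,
                                            a1 = "A", a2 = "G"))
    attr(panel, "maf") <- maf
    attr(panel, "block") <- lay$block
    attr(panel, "rho") <- rho
    attr(panel, "cfg") <- cfg
    panel
  })
}

#' Generate synthetic annotation tracks
#'
#' Places region tracks over the deterministic SNP layout of `cfg` so that
#' each covers its configured SNP fraction exactly. Sweep (HD) regions and
#' gene bodies are block-aligned (whole LD blocks), so LD-tagging of the
#' HD stratum is realistic; the two are drawn independently and may
#' overlap. Within each gene block the first SNP is 5'UTR, the last is
#' 3'UTR, a random `exon_share` of the interior is exonic and the rest
#' intronic. Brain genes are a random `brain_share` of gene blocks;
#' `hdbrain` is the HD/brain intersection. Small ncRNA/TFBS/miRNA tracks
#' sit on random non-genic SNPs and only matter to the intergenic
#' classification.
#'
#' @param cfg a [sim_config()].
#' @return Named list of [region_set()]s: hd, gene, exon, intron, utr3,
#'   utr5, brain, hdbrain, ncrna, tfbs, mirna.
#' @export
generate_tracks <- function(cfg) {
  lay <- sim_layout(cfg)
  nb <- cfg$n_blocks_ld
  with_seed_opt(cfg$seed + 1L, {
    hd_blocks <- sort(sample(nb, round(cfg$frac_hd * nb)))
    gene_blocks <- sort(sample(nb, round(cfg$frac_gene * nb)))
    brain_blocks <- sort(sample(gene_blocks,
                                round(cfg$brain_share * length(gene_blocks))))
    snps_of <- function(blocks) which(lay$block %in% blocks)
    gene_snps <- snps_of(gene_blocks)
    utr5 <- utr3 <- exon <- intron <- integer()
    for (b in gene_blocks) {
      s <- which(lay$block == b)
      utr5 <- c(utr5, s[1])
      utr3 <- c(utr3, s[length(s)])
      interior <- s[-c(1, length(s))]
      ex <- sort(sample(interior, round(cfg$exon_share * length(interior))))
      exon <- c(exon, ex)
      intron <- c(intron, setdiff(interior, ex))
    }
    nongenic <- setdiff(seq_len(cfg$M), gene_snps)
    ctx <- function() sort(sample(nongenic, round(cfg$frac_context * length(nongenic))))
    tracks <- list(hd = snps_of(hd_blocks), gene = gene_snps,
                   exon = exon, intron = intron, utr3 = utr3, utr5 = utr5,
                   brain = snps_of(brain_blocks),
                   hdbrain = snps_of(intersect(hd_blocks, brain_blocks)),
                   ncrna = ctx(), tfbs = ctx(), mirna = ctx())
    lapply(stats::setNames(names(tracks), names(tracks)), function(nm) {
      snp_runs_to_regions(tracks[[nm]], lay, label = nm)
    })
  })
}

#' Per-block standardized-genotype correlation of a synthetic panel
#'
#' Computes, for each LD block of a [generate_panel()] panel, the
#' empirical correlation matrix of standardized dosages and its Cholesky
#' factor. [generate_sumstats()] derives this itself when not supplied;
#' precompute it once when drawing many summary-statistic replicates from
#' the same panel.
#'
#' @param panel a panel from [generate_panel()].
#' @return List (one element per block) of lists with `idx`, `R`, `U`.
#' @export
panel_block_ld <- function(panel) {
  block <- attr(panel, "block")
  if (is.null(block))
    stop_format("panel_block_ld: panel must come from generate_panel()")
  X <- standardize_panel(panel)
  n <- nrow(X)
  lapply(split(seq_len(ncol(X)), block), function(s) {
    R <- crossprod(X[, s, drop = FALSE]) / (n - 1)
    # duplicated genotype columns can make R numerically singular
    U <- tryCatch(chol(R), error = function(e)
      chol(R + diag(1e-8, nrow(R))))
    list(idx = s, R = R, U = U)
  })
}

# convert a set of SNP indices into BED intervals covering exactly those
# SNPs: runs of consecutive indices on one chromosome become one interval
# (pos - 1, pos_last], which under the membership rule start < pos <= end
# contains exactly the run
snp_runs_to_regions <- function(idx, lay, label) {
  if (length(idx) == 0) return(region_set(label = label))
  idx <- sort(idx)
  new_run <- c(TRUE, diff(idx) != 1 | lay$chrom[idx[-1]] != lay$chrom[idx[-length(idx)]])
  run_id <- cumsum(new_run)
  first <- idx[new_run]
  last <- idx[!duplicated(run_id, fromLast = TRUE)]
  region_set(lay$chrom[first], lay$pos[first] - 1L, lay$pos[last],
             label = label)
}

#' Per-SNP heritability targeting a given enrichment fold
#'
#' Returns `c(base, extra)` per-SNP heritabilities such that a category
#' covering fraction `frac` of SNPs, whose members receive `base + extra`
#' while all others receive `base`, has enrichment fold
#' `(h2_c/h2)/(M_c/M) = fold` and the genome totals `h2_total`.
#'
#' @param fold target enrichment fold (> 0; 1 = none).
#' @param frac category SNP fraction in (0, 1).
#' @param h2_total total heritability.
#' @param M number of SNPs.
#' @return Named numeric: `base` and `extra`.
#' @export
tau_for_fold <- function(fold, frac, h2_total, M) {
  if (fold * frac >= 1)
    stop_format("tau_for_fold: fold * frac must be < 1")
  tau_b <- 1
  tau_x <- tau_b * (fold - 1) / (1 - fold * frac)
  scale <- h2_total / (M * (tau_b + frac * tau_x))
  c(base = tau_b * scale, extra = tau_x * scale)
}

#' Simulate GWAS summary statistics from the partitioned polygenic model
#'
#' Draws per-SNP standardized effects `beta_j ~ N(0, sigma2_j)` with
#' `sigma2_j = tau_base + sum_c a_jc tau_c`, then per LD block forms
#' `z = sqrt(N) R beta + eta`, `eta ~ MVN(0, inflation * R)`, where R is
#' the standardized-genotype correlation of the reference panel itself:
#' the GWAS population and the panel share the same LD by design (no
#' reference mismatch), so `E[chisq_j] = inflation + N * sum_c tau_c *
#' ell(j, c)` holds exactly for the LD scores the pipeline computes.
#' Summary statistics are simulated directly at the z level (not via
#' individual phenotypes) for speed.
#'
#' @param panel a panel from [generate_panel()] (carries MAF and block
#'   attributes).
#' @param annotations an `annotation_set` over the panel whose binary
#'   columns include every category named in `cfg$tau`.
#' @param cfg the [sim_config()] used to build the panel.
#' @param block_ld optional [panel_block_ld()] cache; supply it when
#'   drawing many summary-statistic replicates from one panel.
#' @return A list: `sumstats` (a `sumstats` table), and `truth` with the
#'   realized tau vector, per-SNP sigma2, h2 by category, true fold by
#'   category and `ell_true` (per-SNP true LD score totals per category).
#' @export
generate_sumstats <- function(panel, annotations, cfg, block_ld = NULL) {
  maf <- attr(panel, "maf")
  block <- attr(panel, "block")
  if (is.null(maf) || is.null(block))
    stop_format("generate_sumstats: panel must come from generate_panel()")
  M <- n_snps(panel)
  A <- annotations$binary
  extra <- cfg$tau
  incr <- numeric(M)
  if (!is.null(names(extra)) && length(extra) > 0) {
    missing_cat <- setdiff(names(extra), colnames(A))
    if (length(missing_cat) > 0)
      stop_format("generate_sumstats: tau names %s not in annotations",
                  paste(missing_cat, collapse = ", "))
    incr <- drop(A[, names(extra), drop = FALSE] %*% extra)
  }
  # base per-SNP heritability is the remainder once the category
  # increments are accounted for, so the genome totals exactly h2_total
  # and targets from tau_for_fold() are realized exactly
  tau_base <- (cfg$h2_total - sum(incr)) / M
  if (tau_base < 0)
    stop_format("generate_sumstats: category increments exceed h2_total")
  sigma2 <- tau_base + incr
  if (sum(sigma2) > 1)
    stop_format("generate_sumstats: total heritability exceeds 1")

  z <- numeric(M)
  ell_true <- matrix(0, M, ncol(A) + 1,
                     dimnames = list(NULL, c("base", colnames(A))))
  block_ld <- block_ld %||% panel_block_ld(panel)
  with_seed_opt(cfg$seed + 2L, {
    beta <- rnorm(M, 0, sqrt(sigma2))
    for (b in seq_along(block_ld)) {
      s <- block_ld[[b]]$idx
      R <- block_ld[[b]]$R
      mean_z <- sqrt(cfg$N_gwas) * drop(R %*% beta[s])
      eta <- sqrt(cfg$intercept_inflation) *
        drop(crossprod(block_ld[[b]]$U, rnorm(length(s))))
      z[s] <- mean_z + eta
      ell_true[s, ] <- (R * R) %*% cbind(base = 1, A[s, , drop = FALSE])
    }
  })
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  ss <- new_sumstats(data.frame(
    snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
    pos = panel$snps$pos, a1 = panel$snps$a1, a2 = panel$snps$a2,
    z = z, p = p, n = cfg$N_gwas, stringsAsFactors = FALSE))

  Ab <- cbind(base = 1, A)
  h2_c <- drop(crossprod(Ab, sigma2))
  M_c <- colSums(Ab)
  fold_true <- (h2_c / h2_c[["base"]]) / (M_c / M)
  list(sumstats = ss,
       truth = list(sigma2 = sigma2, h2_total = sum(sigma2), h2_c = h2_c,
                    M_c = M_c, fold = fold_true, ell_true = ell_true,
                    N = cfg$N_gwas, inflation = cfg$intercept_inflation))
}
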