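# Windowed LD engine ---------------------------------------------------------
#
# Every LD computation in the package walks the panel in chunks of SNPs and,
# for each chunk, forms the Pearson correlation between the chunk columns and
# all panel columns within +/- window_bp on the same chromosome (one dense
# chunk x window crossprod per step, which keeps memory flat and lets BLAS do
# the work). The callback receives squared correlations with the self term
# set to exactly 1.

ld_chunk_walk <- function(panel, window_bp = 1e6, rows = NULL,
                          chunk_size = 512L, callback, X = NULL) {
  X <- X %||% standardize_panel(panel)
  n <- nrow(X)
  snps <- panel$snps
  rows <- sort(rows %||% seq_len(nrow(snps)))
  for (ch in unique(snps$chrom)) {
    on_ch <- which(snps$chrom == ch)
    r_ch <- intersect(rows, on_ch)
    if (length(r_ch) == 0) next
    pos_ch <- snps$pos[on_ch]
    starts <- seq(1L, length(r_ch), by = chunk_size)
    for (s in starts) {
      ci <- r_ch[s:min(s + chunk_size - 1L, length(r_ch))]   # global indices
      lo <- findInterval(min(snps$pos[ci]) - window_bp - 1L, pos_ch) + 1L
      hi <- findInterval(max(snps$pos[ci]) + window_bp, pos_ch)
      wi <- on_ch[lo:hi]                                     # global indices
      r <- crossprod(X[, ci, drop = FALSE], X[, wi, drop = FALSE]) / (n - 1)
      r2 <- r * r
      self <- cbind(match(intersect(ci, wi), ci), match(intersect(ci, wi), wi))
      r2[self] <- 1
      # zero out pairs beyond the bp window (chunk spans shift the range)
      dist_ok <- abs(outer(snps$pos[ci], snps$pos[wi], "-")) <= window_bp
      r2[!dist_ok] <- 0
      callback(ci, wi, r2, dist_ok)
    }
  }
  invisible(NULL)
}

#' Pairwise r-squared of one SNP against its window
#'
#' Squared Pearson correlation of dosage columns between SNP `i` and every
#' panel SNP within `window_bp` on the same chromosome (including itself,
#' with r-squared exactly 1).
#'
#' @param panel a [genotype_panel()].
#' @param i SNP column index or snp_id.
#' @param window_bp window half-width in basepairs.
#' @return Named numeric vector of r-squared values (names are snp_ids).
#' @export
pairwise_r2 <- function(panel, i, window_bp = 1e6) {
  if (is.character(i)) i <- match(i, panel$snps$snp_id)
  if (is.na(i) || i < 1 || i > n_snps(panel))
    stop_format("pairwise_r2: invalid SNP index")
  snps <- panel$snps
  xi <- panel$dosages[, i]
  if (sd(xi) == 0) stop_format("pairwise_r2: SNP %d has zero variance", i)
  win <- which(snps$chrom == snps$chrom[i] &
               abs(snps$pos - snps$pos[i]) <= window_bp)
  r2 <- as.vector(cor(xi, panel$dosages[, win, drop = FALSE]))^2
  r2[win == i] <- 1
  stats::setNames(r2, snps$snp_id[win])
}

# Core of the LD-weighted region score, factored out so the scoring rule can
# be checked directly against a stated r2 matrix: threshold sub-0.2 values
# to zero (self term already 1) and sum r2 over region members.
region_score_from_r2 <- function(r2, delta, r2_threshold = 0.2) {
  r2[r2 < r2_threshold] <- 0
  as.vector(r2 %*% delta)
}

#' LD-weighted region annotation score
#'
#' For each panel SNP i, the score is `sum_j delta_j * r2_ij` over panel
#' SNPs j within the window, where `delta_j` is 1 iff SNP j lies inside
#' `regions`, r-squared values below `r2_threshold` are set to 0, and the
#' self r-squared is exactly 1. A SNP inside the region therefore always
#' scores at least 1; a SNP with no (thresholded) LD to any region SNP
#' scores 0.
#'
#' @param panel a [genotype_panel()].
#' @param regions a [region_set()] (or a logical membership vector over
#'   panel SNPs).
#' @param window_bp window half-width in basepairs.
#' @param r2_threshold r-squared values below this are zeroed (0.2).
#' @return Numeric vector of length `n_snps(panel)`.
#' @export
ld_weighted_region_score <- function(panel, regions, window_bp = 1e6,
                                     r2_threshold = 0.2) {
  delta <- if (is.logical(regions)) regions else
    snp_in_regions(panel, regions)
  score <- numeric(n_snps(panel))
  ld_chunk_walk(panel, window_bp, callback = function(ci, wi, r2, ok) {
    score[ci] <<- region_score_from_r2(r2, as.numeric(delta[wi]), r2_threshold)
  })
  score
}

#' Build binary and LD-weighted annotations from region tracks
#'
#' @param panel a [genotype_panel()].
#' @param tracks named list of [region_set()] objects, one per category.
#' @param weighted also compute LD-weighted scores (TRUE).
#' @param window_bp,r2_threshold passed to [ld_weighted_region_score()].
#' @return An `annotation_set`: list with `binary` and `weighted` M x C
#'   matrices (columns named by category) and `categories`.
#' @export
build_annotations <- function(panel, tracks, weighted = TRUE,
                              window_bp = 1e6, r2_threshold = 0.2) {
  stopifnot(length(names(tracks)) == length(tracks))
  M <- n_snps(panel)
  binary <- vapply(tracks, function(rs) as.numeric(snp_in_regions(panel, rs)),
                   numeric(M))
  wmat <- NULL
  if (weighted) {
    X <- standardize_panel(panel)
    wmat <- matrix(0, M, length(tracks), dimnames = list(NULL, names(tracks)))
    ld_chunk_walk(panel, window_bp, X = X, callback = function(ci, wi, r2, ok) {
      r2[r2 < r2_threshold] <- 0
      wmat[ci, ] <<- r2 %*% binary[wi, , drop = FALSE]
    })
  }
  structure(list(binary = binary, weighted = wmat, categories = names(tracks)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d SNPs x %d categories (%s)\n",
              nrow(x$binary), length(x$categories),
              paste(x$categories, collapse = ", ")))
  invisible(x)
}

#' Partitioned LD scores
#'
#' For each regression SNP j and category c, `ell(j, c) = sum_k a_kc *
#' r2adj_jk` over panel SNPs k within the window, where `r2adj = r2 -
#' (1 - r2)/(n - 2)` is the standard small-sample bias adjustment (n =
#' panel samples). No 0.2 threshold is applied here: this is a distinct
#' procedure from [ld_weighted_region_score()], and individual adjusted
#' values may be negative although the category sums stay near or above 0.
#' A `base` all-SNPs category is prepended automatically.
#'
#' @param panel a [genotype_panel()].
#' @param annotations an `annotation_set` from [build_annotations()] (its
#'   binary matrix defines the categories), or a binary matrix directly.
#' @param regression_snps character vector of snp_ids to compute scores
#'   for (default: all panel SNPs); unknown ids are dropped with a warning.
#' @param window_bp window half-width in basepairs.
#' @return An `ldscore_table`: list with `snps` (coordinates of regression
#'   SNPs), `ell` (matrix of LD scores, first column `base`), `M_c`
#'   (reference SNP counts per category), `overlap` (C x C category
#'   co-membership counts over reference SNPs) and `n_ref`.
#' @export
partitioned_ld_scores <- function(panel, annotations, regression_snps = NULL,
                                  window_bp = 1e6) {
  A <- if (inherits(annotations, "annotation_set")) annotations$binary
       else as.matrix(annotations)
  if (nrow(A) != n_snps(panel))
    stop_format("annotation matrix rows != panel SNPs")
  A <- cbind(base = 1, A)
  n <- nrow(panel$dosages)
  rows <- seq_len(n_snps(panel))
  if (!is.null(regression_snps)) {
    rows <- match(regression_snps, panel$snps$snp_id)
    if (anyNA(rows)) {
      warning(sprintf("dropping %d unknown regression SNP id(s)", sum(is.na(rows))))
      rows <- rows[!is.na(rows)]
    }
    rows <- sort(rows)
  }
  ell <- matrix(0, length(rows), ncol(A), dimnames = list(NULL, colnames(A)))
  row_of <- integer(n_snps(panel)); row_of[rows] <- seq_along(rows)
  ld_chunk_walk(panel, window_bp, rows = rows, callback = function(ci, wi, r2, ok) {
    adj <- r2 - (1 - r2) / (n - 2)
    adj[!ok] <- 0                       # beyond-window pairs contribute 0
    ell[row_of[ci], ] <<- adj %*% A[wi, , drop = FALSE]
  })
  structure(list(snps = panel$snps[rows, c("snp_id", "chrom", "pos")],
                 ell = ell, M_c = colSums(A), overlap = crossprod(A),
                 n_ref = n_snps(panel)),
            class = "ldscore_table")
}

#' @export
print.ldscore_table <- function(x, ...) {
  cat(sprintf("ldscore_table: %d regression SNPs x %d categories; mean total LD score %.2f\n",
              nrow(x$ell), ncol(x$ell), mean(x$ell[, "base"])))
  invisible(x)
}

#' Write partitioned LD scores as TSV
#'
#' Layout mirrors the conventional `.l2.ldscore` files: snp, chrom, pos,
#' then one column per category.
#' @param x an `ldscore_table`.
#' @param path output path.
#' @export
write_ldscores <- function(x, path) {
  data.table::fwrite(cbind(x$snps, as.data.frame(x$ell)), path, sep = "\t")
  invisible(path)
}

# sparse list of LD pairs (i < j, global indices) with r2 >= r2_min,
# optionally restricted to a candidate subset on both sides
ld_pairs <- function(panel, window_bp = 1e6, r2_min = 0.2, candidates = NULL,
                     X = NULL) {
  keep <- rep(TRUE, n_snps(panel))
  if (!is.null(candidates)) {
    keep[] <- FALSE
    keep[candidates] <- TRUE
  }
  acc <- list(); k <- 0L
  ld_chunk_walk(panel, window_bp, rows = which(keep), X = X,
                callback = function(ci, wi, r2, ok) {
    sel <- which(r2 >= r2_min, arr.ind = TRUE)
    gi <- ci[sel[, 1]]; gj <- wi[sel[, 2]]
    f <- gi < gj & keep[gj]
    if (any(f)) {
      k <<- k + 1L
      acc[[k]] <<- data.frame(i = gi[f], j = gj[f], r2 = r2[sel][f])
    }
  })
  if (k == 0) data.frame(i = integer(), j = integer(), r2 = numeric())
  else do.call(rbind, acc)
}

#' Greedy random-order LD pruning
#'
#' Repeatedly picks a remaining candidate uniformly at random, keeps it,
#' and removes all remaining candidates with r-squared >= `r2_threshold`
#' to it (within `window_bp`). The kept set has maximal pairwise
#' r-squared below the threshold, and is reproducible given `seed`.
#'
#' @param panel a [genotype_panel()].
#' @param candidates integer indices or snp_ids of candidate SNPs.
#' @param r2_threshold pruning threshold (0.2).
#' @param window_bp window half-width in basepairs.
#' @param seed optional integer seed for the random order.
#' @param pairs optional precomputed pair list (internal reuse).
#' @return Integer vector of kept panel SNP indices (sorted).
#' @export
ld_prune <- function(panel, candidates, r2_threshold = 0.2, window_bp = 1e6,
                     seed = NULL, pairs = NULL) {
  if (is.character(candidates))
    candidates <- match(candidates, panel$snps$snp_id)
  candidates <- candidates[!is.na(candidates)]
  if (length(candidates) == 0) return(integer())
  if (is.null(pairs))
    pairs <- ld_pairs(panel, window_bp, r2_threshold, candidates)
  adj <- make_adjacency(pairs, n_snps(panel))
  ord <- with_seed_opt(seed, sample(candidates))
  alive <- rep(TRUE, n_snps(panel))
  alive[-candidates] <- FALSE
  kept <- logical(n_snps(panel))
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    nb <- adj[[i]]
    if (!is.null(nb)) alive[nb] <- FALSE
  }
  which(kept)
}

# position-indexed adjacency list (O(1) lookup during the greedy pass)
make_adjacency <- function(pairs, M) {
  adj <- vector("list", M)
  if (nrow(pairs) > 0) {
    by_i <- split(c(pairs$j, pairs$i), c(pairs$i, pairs$j))
    adj[as.integer(names(by_i))] <- by_i
  }
  adj
}

#' MHC exclusion mask
#'
#' Excludes SNPs inside the extended MHC region (chr6:25119106-33854733,
#' genome build 19) and any SNP with r-squared > `r2_tag` (within the
#' window) to such a SNP, to avoid inflation from the region's complex
#' long-range LD.
#'
#' @param panel a [genotype_panel()].
#' @param mhc_range 1-based inclusive bounds of the excluded interval.
#' @param chrom chromosome carrying the region ("6"; "chr6" also matches).
#' @param r2_tag LD-tagging threshold (0.1).
#' @param window_bp window half-width in basepairs.
#' @return Logical keep-mask over panel SNPs (TRUE = retained).
#' @export
mhc_exclusion_mask <- function(panel, mhc_range = c(25119106L, 33854733L),
                               chrom = "6", r2_tag = 0.1, window_bp = 1e6) {
  snps <- panel$snps
  inside <- norm_chrom(snps$chrom) == norm_chrom(chrom) &
    snps$pos >= mhc_range[1] & snps$pos <= mhc_range[2]
  excluded <- inside
  if (any(inside)) {
    ld_chunk_walk(panel, window_bp, rows = which(inside),
                  callback = function(ci, wi, r2, ok) {
      tagged <- wi[colSums(r2 > r2_tag) > 0]
      excluded[tagged] <<- TRUE
    })
  }
  !excluded
}

#' Classify intergenic SNPs
#'
#' A SNP is intergenic iff its LD-weighted scores for exon, intron, 3'UTR
#' and 5'UTR are all zero AND it is in LD (r-squared >= `r2_threshold`
#' within the window, self included) with no panel SNP inside the genic
#' context: protein-coding genes +/- `gene_pad_bp`, non-coding RNAs,
#' transcription-factor binding sites, or miRNA binding sites. Intergenic
#' SNPs serve as a reliably null set for genomic-control estimation.
#'
#' @param annotations an `annotation_set` whose weighted matrix contains
#'   columns exon, intron, utr3, utr5.
#' @param panel a [genotype_panel()].
#' @param gene_context named list of [region_set()]s with elements `genes`
#'   (gene bodies; padded internally), and optionally `ncrna`, `tfbs`,
#'   `mirna`.
#' @param gene_pad_bp padding added around gene bodies (100 kb).
#' @param window_bp,r2_threshold LD tagging parameters.
#' @return Logical vector: TRUE for intergenic SNPs.
#' @export
classify_intergenic <- function(annotations, panel, gene_context,
                                gene_pad_bp = 1e5, window_bp = 1e6,
                                r2_threshold = 0.2) {
  genic_cols <- c("exon", "intron", "utr3", "utr5")
  W <- annotations$weighted
  if (is.null(W) || !all(genic_cols %in% colnames(W)))
    stop_format("classify_intergenic: weighted scores for %s are required",
                paste(genic_cols, collapse = "/"))
  if (is.null(gene_context$genes))
    stop_format("classify_intergenic: gene_context$genes is required")
  context <- snp_in_regions(panel, dilate_regions(gene_context$genes, gene_pad_bp))
  for (nm in c("ncrna", "tfbs", "mirna")) {
    if (!is.null(gene_context[[nm]]))
      context <- context | snp_in_regions(panel, gene_context[[nm]])
  }
  context_score <- ld_weighted_region_score(panel, context, window_bp,
                                            r2_threshold)
  rowSums(W[, genic_cols, drop = FALSE]) == 0 & context_score == 0
}
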