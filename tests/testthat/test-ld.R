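test_that("pairwise_r2 matches a hand Pearson oracle and is exactly 1 on self", {
  dos <- cbind(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 1, 2), c(0, 0, 1, 1, 2, 2))
  panel <- genotype_panel(dos, data.frame(snp_id = c("s1", "s2", "s3"),
                                          chrom = "chr1",
                                          pos = c(1000L, 2000L, 3000L)))
  r2 <- pairwise_r2(panel, 1)
  expect_identical(unname(r2["s1"]), 1)                  # self, exact
  expect_equal(unname(r2["s2"]), cor(dos[, 1], dos[, 2])^2)
  expect_identical(unname(r2["s3"]), 1)                  # duplicated column
  # window restriction: SNP 2 Mb away is absent from the map
  panel2 <- genotype_panel(dos, data.frame(snp_id = c("s1", "s2", "s3"),
                                           chrom = "chr1",
                                           pos = c(1000L, 2000L, 2500000L)))
  expect_false("s3" %in% names(pairwise_r2(panel2, 1)))
})

test_that("region-score rule reproduces the stated 3-SNP example", {
  r2 <- rbind(c(1, .5, .1), c(.5, 1, .3), c(.1, .3, 1))
  delta <- c(1, 0, 0)    # region = {SNP1}
  expect_equal(sweepenrich:::region_score_from_r2(r2, delta), c(1.0, 0.5, 0.0))
})

test_that("LD-weighted region scores equal the dense brute-force oracle", {
  for (seed in 1:3) {
    panel <- toy_panel(M = 40, n = 50, seed = seed)
    delta <- withr::with_seed(seed, runif(40) < 0.3)
    rs <- sweepenrich:::snp_runs_to_regions(which(delta),
      list(block = rep(1, 40), chrom = panel$snps$chrom,
           pos = panel$snps$pos, snp_id = panel$snps$snp_id), "toy")
    got <- ld_weighted_region_score(panel, rs)
    expect_equal(got, oracle_region_score(panel, as.numeric(delta)),
                 tolerance = 1e-10)
    # member SNPs always score >= 1 (self term)
    expect_true(all(got[delta] >= 1))
  }
  # empty region set: all-zero scores
  expect_equal(ld_weighted_region_score(toy_panel(M = 5), region_set()),
               rep(0, 5))
})

test_that("partitioned LD scores equal the brute-force oracle and are additive", {
  panel <- toy_panel(M = 50, n = 40, seed = 11)
  A <- withr::with_seed(2, matrix(as.numeric(runif(150) < 0.4), 50, 3,
                                  dimnames = list(NULL, c("c1", "c2", "c3"))))
  ld <- partitioned_ld_scores(panel, A)
  expect_equal(unname(ld$ell), unname(oracle_ld_scores(panel, A)),
               tolerance = 1e-12)
  # additivity: a disjoint partition sums to the union category
  part <- cbind(p1 = as.numeric(seq_len(50) <= 20),
                p2 = as.numeric(seq_len(50) > 20))
  ld2 <- partitioned_ld_scores(panel, part)
  expect_equal(ld2$ell[, "p1"] + ld2$ell[, "p2"], ld2$ell[, "base"],
               tolerance = 1e-10)
  # bookkeeping for the heritability partition
  expect_equal(unname(ld$M_c[["base"]]), 50)
  expect_equal(ld$overlap["c1", "c2"], sum(A[, 1] * A[, 2]))
})

test_that("LD scores: self term for isolated SNPs, ~2 for a duplicated pair", {
  # isolated SNPs: ell(base) = 1 exactly (self r2 = 1, zero bias term)
  panel <- toy_panel(M = 4, n = 30, seed = 5, spacing = 5e6)
  ld <- partitioned_ld_scores(panel, matrix(1, 4, 1, dimnames = list(NULL, "all")))
  expect_equal(unname(ld$ell[, "base"]), rep(1, 4))
  # perfectly correlated pair in one category scores ~2
  dos <- toy_panel(M = 1, n = 40, seed = 8)$dosages
  panel2 <- genotype_panel(cbind(dos, dos),
                           data.frame(snp_id = c("a", "b"), chrom = "chr1",
                                      pos = c(100L, 200L)))
  ld2 <- partitioned_ld_scores(panel2, matrix(1, 2, 1, dimnames = list(NULL, "c")))
  expect_equal(unname(ld2$ell[, "c"]), c(2, 2), tolerance = 1e-10)
})

test_that("regression-SNP subsets are honored, unknown ids dropped", {
  panel <- toy_panel(M = 20, n = 30, seed = 4)
  ids <- panel$snps$snp_id[c(3, 7, 15)]
  expect_warning(
    ld <- partitioned_ld_scores(panel, matrix(1, 20, 1,
                                              dimnames = list(NULL, "x")),
                                regression_snps = c(ids, "nope")),
    "unknown")
  expect_equal(ld$snps$snp_id, ids)
  full <- partitioned_ld_scores(panel, matrix(1, 20, 1,
                                              dimnames = list(NULL, "x")))
  expect_equal(ld$ell, full$ell[c(3, 7, 15), , drop = FALSE])
})

test_that("LD computations are invariant under sample permutation", {
  panel <- toy_panel(M = 25, n = 40, seed = 21)
  perm <- withr::with_seed(1, sample(40))
  panel_p <- genotype_panel(panel$dosages[perm, ], panel$snps)
  A <- matrix(as.numeric(seq_len(25) %% 2 == 0), 25, 1,
              dimnames = list(NULL, "even"))
  expect_equal(partitioned_ld_scores(panel, A)$ell,
               partitioned_ld_scores(panel_p, A)$ell, tolerance = 1e-12)
  expect_equal(ld_weighted_region_score(panel, seq_len(25) <= 5),
               ld_weighted_region_score(panel_p, seq_len(25) <= 5),
               tolerance = 1e-12)
})

test_that("MHC exclusion removes the interval and its LD partners", {
  dup <- toy_panel(M = 1, n = 50, seed = 13)$dosages[, 1]
  other <- toy_panel(M = 3, n = 50, seed = 14)$dosages
  dos <- cbind(dup, other[, 1], dup, other[, 2:3])
  panel <- genotype_panel(dos, data.frame(
    snp_id = sprintf("m%d", 1:5),
    chrom = c("chr6", "chr6", "chr6", "chr6", "chr1"),
    pos = c(24500000L, 24600000L, 25200000L, 33900000L, 30000000L)))
  kp <- setNames(mhc_exclusion_mask(panel), panel$snps$snp_id)
  # m3 inside [25119106, 33854733]; m1 duplicates m3 (r2 = 1 > 0.1) -> out;
  # m2 independent and outside; m4 outside interval; m5 on chr1 kept
  expect_false(kp[["m3"]])
  expect_false(kp[["m1"]])
  expect_true(kp[["m2"]] || cor(dup, other[, 1])^2 > 0.1)
  expect_true(kp[["m5"]])
  # no chr6 SNPs: mask is all TRUE
  expect_true(all(mhc_exclusion_mask(toy_panel(M = 6))))
})

test_that("ld_prune yields an independent set, deterministically per seed", {
  dup <- toy_panel(M = 1, n = 50, seed = 17)$dosages[, 1]
  panel <- genotype_panel(cbind(dup, dup),
                          data.frame(snp_id = c("a", "b"), chrom = "chr1",
                                     pos = c(100L, 200L)))
  expect_length(ld_prune(panel, 1:2, seed = 3), 1)   # one of a perfect pair
  panel2 <- toy_panel(M = 10, n = 400, seed = 19)    # iid: all below 0.2
  expect_equal(ld_prune(panel2, 1:10, seed = 1), 1:10)
  panel3 <- toy_panel(M = 10, n = 25, seed = 23)
  k1 <- ld_prune(panel3, 1:10, seed = 42)
  k2 <- ld_prune(panel3, 1:10, seed = 42)
  expect_identical(k1, k2)
  r2 <- oracle_r2(panel3)[k1, k1]
  expect_true(max(r2[upper.tri(r2)]) < 0.2)
  expect_equal(ld_prune(panel3, integer()), integer())
})

test_that("intergenic classification applies both the score and context rules", {
  cfg <- sim_config(M = 1000, n_blocks_ld = 40, n_panel = 60, seed = 31)
  panel <- generate_panel(cfg)
  tracks <- generate_tracks(cfg)
  ann <- build_annotations(panel, tracks[c("exon", "intron", "utr3", "utr5")])
  ig <- classify_intergenic(ann, panel, list(genes = tracks$gene,
                                             ncrna = tracks$ncrna,
                                             tfbs = tracks$tfbs,
                                             mirna = tracks$mirna))
  # SNPs in exons are never intergenic
  expect_true(all(!ig[ann$binary[, "exon"] == 1]))
  # intergenic SNPs have zero genic scores
  expect_true(all(rowSums(ann$weighted[ig, ]) == 0))
  # SNPs inside the (dilated) gene context are excluded even with zero scores
  ctx <- snp_in_regions(panel, dilate_regions(tracks$gene, 1e5))
  expect_true(all(!ig[ctx]))
  expect_gt(sum(ig), 0)
  # missing genic score columns -> error
  ann2 <- build_annotations(panel, tracks["exon"])
  expect_error(classify_intergenic(ann2, panel, list(genes = tracks$gene)),
               "required")
})
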