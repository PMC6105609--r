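test_that("lambda_gc matches its definition on degenerate inputs", {
  panel <- toy_panel(M = 200, n = 100, seed = 41, spacing = 20000)
  ig <- rep(TRUE, 200)
  ss0 <- toy_sumstats(z = rep(0, 200), pos = panel$snps$pos)
  expect_equal(as.numeric(lambda_gc(ss0, ig, panel, iterations = 5)), 0)
  # median z^2 exactly at the chi-square(1) median -> lambda = 1
  zmed <- sqrt(qchisq(0.5, 1))
  ss1 <- toy_sumstats(z = rep(c(-zmed, zmed), 100), pos = panel$snps$pos)
  expect_equal(as.numeric(lambda_gc(ss1, ig, panel, iterations = 5)), 1,
               tolerance = 1e-12)
  expect_error(lambda_gc(ss0, rep(FALSE, 200), panel), "empty")
})

test_that("lambda_gc recovers inflation on independent null SNPs", {
  # Monte-Carlo oracle: 50,000 independent SNPs, z ~ N(0, sqrt(1.2))
  cfg <- sim_config(M = 50000, n_blocks_ld = 2000, block_rho = 0,
                    n_panel = 100, seed = 43)
  panel <- generate_panel(cfg)
  z <- withr::with_seed(44, rnorm(n_snps(panel), 0, sqrt(1.2)))
  ss <- toy_sumstats(z, chrom = panel$snps$chrom, pos = panel$snps$pos)
  ss$snp_id <- panel$snps$snp_id
  lam <- lambda_gc(ss, rep(TRUE, n_snps(panel)), panel, iterations = 20,
                   seed = 45)
  expect_equal(as.numeric(lam), 1.2, tolerance = 0.02)
  # and ~1 under the exact null
  z0 <- withr::with_seed(46, rnorm(n_snps(panel)))
  ss0 <- toy_sumstats(z0, chrom = panel$snps$chrom, pos = panel$snps$pos)
  ss0$snp_id <- panel$snps$snp_id
  lam0 <- lambda_gc(ss0, rep(TRUE, n_snps(panel)), panel, iterations = 20,
                    seed = 47)
  expect_gt(as.numeric(lam0), 0.97)
  expect_lt(as.numeric(lam0), 1.03)
})

test_that("gc_correct rescales chi-squares only when lambda > 1", {
  ss <- toy_sumstats(z = c(2, -1, 0.5))
  expect_equal(as.data.frame(gc_correct(ss, 1)), as.data.frame(ss),
               ignore_attr = TRUE)
  out <- gc_correct(ss, 4)
  expect_equal(out$z, c(1, -0.5, 0.25))
  expect_equal(out$p, 2 * pnorm(-abs(out$z)))
  # lambda = 1.21: all chi-squares scaled by 1/1.21
  out2 <- gc_correct(ss, 1.21)
  expect_equal(out2$z^2, ss$z^2 / 1.21, tolerance = 1e-12)
  # deflation is not amplified
  expect_equal(gc_correct(ss, 0.8)$z, ss$z)
  expect_error(gc_correct(ss, 0), "positive")
  expect_error(gc_correct(ss, -1), "positive")
})

test_that("conditional_qq: null identity, truncation, empty strata", {
  n <- 100
  p <- (1:n) / (n + 1)
  ss <- toy_sumstats(z = -qnorm(p / 2))
  ss$p <- p
  curves <- suppressWarnings(
    conditional_qq(ss, list(all = rep(TRUE, n), none = rep(FALSE, n))))
  expect_named(curves, "all")
  # p exactly rank/(n+1): the curve lies on the diagonal
  expect_equal(curves$all$nominal_nlog10p, curves$all$empirical_nlog10p,
               tolerance = 1e-12)
  # a genome-wide significant point is excluded
  ss2 <- toy_sumstats(z = c(rep(1, 5), 7))   # p(z=7) < 5e-8
  cc <- conditional_qq(ss2, list(all = rep(TRUE, 6)))
  expect_equal(nrow(cc$all), 5)
  expect_warning(conditional_qq(ss, list(none = rep(FALSE, n))), "no SNPs")
})

test_that("conditional_qq of uniform p stays within the 99% Kolmogorov band", {
  n <- 10000
  p <- withr::with_seed(48, runif(n))
  ss <- toy_sumstats(z = rep(1, n))
  ss$p <- p
  curve <- conditional_qq(ss, list(all = rep(TRUE, n)))$all
  d <- max(abs(10^(-curve$nominal_nlog10p) - 10^(-curve$empirical_nlog10p)))
  expect_lt(d, 1.628 / sqrt(n))
})

test_that("fold_enrichment matches the enumeration oracle", {
  # 10 SNPs, 2 with -log10 p >= 1, both inside a 5-SNP stratum
  p <- c(0.05, 0.08, 0.5, 0.6, 0.7, 0.3, 0.4, 0.5, 0.6, 0.9)
  ss <- toy_sumstats(z = rep(1, 10))
  ss$p <- p
  stratum <- c(rep(TRUE, 5), rep(FALSE, 5))
  fc <- fold_enrichment(ss, stratum, grid = c(0, 1))
  expect_equal(fc$fold, c(1, (2 / 5) / (2 / 10)))   # fold(1) = 2
  expect_equal(fc$n_all, c(10, 2))
  # all-SNPs stratum: fold identically 1 wherever defined (NA only when
  # the denominator tail is empty)
  fc_all <- fold_enrichment(ss, rep(TRUE, 10))
  expect_true(all(fc_all$fold == 1, na.rm = TRUE))
  expect_true(all(is.na(fc_all$fold) == (fc_all$n_all == 0)))
  expect_error(fold_enrichment(ss, rep(FALSE, 10)), "empty")
  expect_error(fold_enrichment(ss, stratum, grid = c(0, 8)), "7.3")
  # empty denominator tail -> undefined, flagged
  fc2 <- fold_enrichment(ss, stratum, grid = c(0, 3), min_count = 5)
  expect_true(is.na(fc2$fold[2]))
  expect_false(fc2$reliable[2])
})

test_that("complementary strata satisfy the CDF conservation identity", {
  z <- withr::with_seed(49, rnorm(2000, 0, 1.1))
  ss <- toy_sumstats(z = z)
  s <- withr::with_seed(50, runif(2000) < 0.3)
  grid <- seq(0, 5, by = 0.5)
  f1 <- fold_enrichment(ss, s, grid = grid)
  f2 <- fold_enrichment(ss, !s, grid = grid)
  w1 <- mean(s); w2 <- 1 - w1
  cdf_all <- f1$n_all / 2000
  ok <- f1$n_all > 0
  expect_equal(w1 * (f1$n_stratum / sum(s)) + w2 * (f2$n_stratum / sum(!s)),
               cdf_all, tolerance = 1e-12)
  # leftward Q-Q deflection of the stratum from the all-SNPs curve at
  # nominal level x (smaller empirical -log10, i.e. a larger tail rank
  # fraction) <=> fold > 1 at the same abscissa
  qq <- conditional_qq(ss, list(s = s, all = rep(TRUE, 2000)))
  emp_at <- function(curve, x) {
    tail_pts <- curve$empirical_nlog10p[curve$nominal_nlog10p >= x]
    if (length(tail_pts) == 0) NA_real_ else min(tail_pts)
  }
  for (x in grid[grid > 0]) {
    fold_x <- f1$fold[f1$x == x]
    es <- emp_at(qq$s, x); ea <- emp_at(qq$all, x)
    if (is.na(fold_x) || is.na(es) || is.na(ea)) next
    if (abs(fold_x - 1) < 0.1) next   # rank-correction flips near fold = 1
    expect_equal(unname(es < ea), unname(fold_x > 1))
  }
})
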