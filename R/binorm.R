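# Bivariate normal CDF and the implied genotype correlation of the
# threshold (Gaussian copula) haplotype model.
#
# The generator draws each haplotype allele as 1{latent < qnorm(maf)} with
# latent correlation rho inside an LD block. The induced correlation of
# 0/1 alleles (and hence of 0/1/2 genotypes, as sums of two independent
# haplotypes) is
#   rho_g = (Phi2(q_i, q_j; rho) - p_i p_j) / sqrt(p_i(1-p_i) p_j(1-p_j))
# which is what the panel estimates and what the z-score simulator must
# use so that simulated chi-squares match the LD scores computed from the
# panel.

gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

GL48 <- gauss_legendre(48)

# P(X < h, Y < k) for standard bivariate normal with correlation rho,
# vectorized over h and k (scalar rho). Uses Phi2 = Phi(h)Phi(k) +
# integral_0^rho phi2(h, k; r) dr with fixed Gauss-Legendre nodes.
pbinorm <- function(h, k, rho) {
  base <- pnorm(h) * pnorm(k)
  if (rho == 0) return(base)
  r <- (GL48$nodes + 1) / 2 * rho          # map [-1,1] -> [0, rho]
  w <- GL48$weights / 2 * rho
  acc <- numeric(length(h))
  for (m in seq_along(r)) {
    om <- 1 - r[m]^2
    dens <- exp(-(h^2 - 2 * r[m] * h * k + k^2) / (2 * om)) / (2 * pi * sqrt(om))
    acc <- acc + w[m] * dens
  }
  base + acc
}

# correlation matrix of 0/1/2 genotypes for one LD block with mafs `p`
# and latent exchangeable correlation rho
genotype_block_cor <- function(p, rho) {
  m <- length(p)
  q <- qnorm(p)
  R <- diag(m)
  if (m == 1) return(R)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  pij <- pbinorm(q[idx[, 1]], q[idx[, 2]], rho)
  cov_hap <- pij - p[idx[, 1]] * p[idx[, 2]]
  rr <- cov_hap / sqrt(p[idx[, 1]] * (1 - p[idx[, 1]]) *
                       p[idx[, 2]] * (1 - p[idx[, 2]]))
  R[idx] <- rr
  R[idx[, c(2, 1), drop = FALSE]] <- rr
  R
}
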