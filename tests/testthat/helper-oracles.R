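# Shared fixtures and independent oracles used across the suite.

# gl_set with perfectly certain genotype likelihoods from a 0/1/2 matrix
make_certain_gl <- function(geno, chrom = NULL, pos = NULL) {
  n <- nrow(geno)
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("chr01", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  lik <- array(0, dim = c(n, m, 3))
  for (g in 0:2) lik[, , g + 1][geno == g] <- 1
  gl_set(
    sites = data.frame(
      id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
      ref = "A", alt = "C", stringsAsFactors = FALSE
    ),
    lik = lik,
    individuals = sprintf("ind%03d", seq_len(n))
  )
}

# noisy likelihoods for one genotype vector via the read model
make_noisy_lik <- function(geno, depth = 30, eps = 0.01) {
  n <- length(geno)
  reads <- stats::rpois(n, depth)
  e_g <- function(g) g / 2 * (1 - eps) + (1 - g / 2) * eps
  alt <- stats::rbinom(n, reads, e_g(geno))
  lik <- sapply(0:2, function(g) stats::dbinom(alt, reads, e_g(g)))
  lik[reads == 0, ] <- 1 / 3
  lik
}

# least-squares score-statistic oracle via explicit projection matrices
score_oracle <- function(d, y, X) {
  n <- length(y)
  M <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
  sigma2 <- as.numeric(t(y) %*% M %*% y) / n
  as.numeric(t(d) %*% M %*% y)^2 / (sigma2 * as.numeric(t(d) %*% M %*% d))
}

# pruning oracle: repeatedly take the globally most significant remaining
# hit and discard same-chromosome hits within the window
prune_oracle <- function(hits, window = 500) {
  remaining <- hits[order(hits$p, hits$chrom, hits$pos), , drop = FALSE]
  kept <- remaining[0, , drop = FALSE]
  while (nrow(remaining) > 0) {
    top <- remaining[1, , drop = FALSE]
    kept <- rbind(kept, top)
    close_by <- remaining$chrom == top$chrom &
      abs(remaining$pos - top$pos) <= window
    remaining <- remaining[!close_by, , drop = FALSE]
  }
  kept[order(kept$chrom, kept$pos), , drop = FALSE]
}

# direct haplotype-count r2 from phased haplotypes (1 = alt allele)
hap_count_r2 <- function(hap_a, hap_b) {
  f_ab <- mean(hap_a == 1 & hap_b == 1)
  p_a <- mean(hap_a)
  p_b <- mean(hap_b)
  d <- f_ab - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

# phased two-site sample with no double heterozygote (so genotype data
# determine the haplotype counts uniquely)
sample_phased_no_double_het <- function(n, f) {
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  repeat {
    h1 <- sample(1:4, n, replace = TRUE, prob = f)
    h2 <- sample(1:4, n, replace = TRUE, prob = f)
    ga <- haps[h1, 1] + haps[h2, 1]
    gb <- haps[h1, 2] + haps[h2, 2]
    if (!any(ga == 1 & gb == 1)) {
      return(list(
        hap_a = c(haps[h1, 1], haps[h2, 1]),
        hap_b = c(haps[h1, 2], haps[h2, 2]),
        ga = ga, gb = gb
      ))
    }
  }
}
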