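test_that("perfect LD between identical certain sites gives r2 = 1", {
  set.seed(41)
  g <- rbinom(40, 2, 0.4)
  gl <- make_certain_gl(cbind(g, g))
  res <- ld_pair(gl, 1, 2)
  expect_equal(res$r2, 1, tolerance = 1e-6)
  expect_equal(sum(res$hap_freq), 1, tolerance = 1e-9)
  expect_true(all(res$hap_freq >= -1e-12))
})

test_that("haplotype EM matches the direct-count oracle on phased fixtures", {
  # 10 AB/AB + 10 ab/ab individuals: complete association
  geno_a <- c(rep(2, 10), rep(0, 10))
  res <- pairwise_r2_em(
    make_certain_gl(matrix(geno_a, ncol = 1))$lik[, 1, ],
    make_certain_gl(matrix(geno_a, ncol = 1))$lik[, 1, ]
  )
  expect_equal(res$r2, 1, tolerance = 1e-6)

  # random phased samples without double heterozygotes: genotype data
  # determine the haplotype counts, EM must agree with counting to 1e-6
  set.seed(42)
  for (rep in 1:5) {
    f <- c(0.4, 0.2, 0.1, 0.3)
    ph <- sample_phased_no_double_het(30, f)
    if (length(unique(ph$ga)) == 1 || length(unique(ph$gb)) == 1) next
    la <- make_certain_gl(matrix(ph$ga, ncol = 1))$lik[, 1, ]
    lb <- make_certain_gl(matrix(ph$gb, ncol = 1))$lik[, 1, ]
    res <- pairwise_r2_em(la, lb, tol = 1e-10, max_iter = 2000)
    expect_equal(res$r2, hap_count_r2(ph$hap_a, ph$hap_b), tolerance = 1e-6)
    expect_equal(unname(res$hap_freq["AB"]), mean(ph$hap_a == 1 & ph$hap_b == 1),
      tolerance = 1e-6
    )
  }
})

test_that("independent loci give near-zero r2 at high depth", {
  set.seed(43)
  hit <- 0L
  n_rep <- 40
  for (k in seq_len(n_rep)) {
    ga <- rbinom(200, 2, 0.3)
    gb <- rbinom(200, 2, 0.3)
    gl <- make_certain_gl(cbind(ga, gb))
    r2 <- ld_pair(gl, 1, 2)$r2
    if (r2 < 0.05) hit <- hit + 1L
  }
  expect_gte(hit / n_rep, 0.95)
})

test_that("r2 is invariant to an allele-label swap at either site", {
  set.seed(44)
  ga <- rbinom(50, 2, 0.3)
  gb <- rbinom(50, 2, 0.6)
  la <- make_certain_gl(matrix(ga, ncol = 1))$lik[, 1, ]
  lb <- make_certain_gl(matrix(gb, ncol = 1))$lik[, 1, ]
  base <- pairwise_r2_em(la, lb)$r2
  expect_equal(pairwise_r2_em(la[, 3:1], lb)$r2, base, tolerance = 1e-6)
  expect_equal(pairwise_r2_em(la, lb[, 3:1])$r2, base, tolerance = 1e-6)
  expect_equal(pairwise_r2_em(la[, 3:1], lb[, 3:1])$r2, base, tolerance = 1e-6)
})

test_that("monomorphic sites raise an undefined-r2 error", {
  mono <- make_certain_gl(matrix(0L, 20, 1))$lik[, 1, ]
  poly <- make_certain_gl(matrix(rbinom(20, 2, 0.5), ncol = 1))$lik[, 1, ]
  expect_error(pairwise_r2_em(mono, poly), "monomorphic")
})

test_that("LD decay separates within-block from cross-block pairs", {
  set.seed(45)
  # two recombination-free blocks on one chromosome: identical genotypes
  # inside a block, independent across blocks
  g1 <- rbinom(60, 2, 0.4)
  g2 <- rbinom(60, 2, 0.4)
  geno <- cbind(g1, g1, g2, g2)
  gl <- make_certain_gl(geno, pos = c(10L, 50L, 460L, 500L))
  dec <- ld_decay(gl, max_dist = 500, bin_width = 100)

  within <- dec$pairs$distance <= 100
  expect_true(all(dec$pairs$r2[within] > 0.99))
  expect_true(all(dec$pairs$r2[!within] < 0.2))
  expect_equal(dec$bins$n_pairs[1], 2L) # the two within-block pairs
  expect_gt(dec$bins$mean_r2[1], 0.99)
  # empty bins are reported empty, not zero
  expect_true(any(dec$bins$n_pairs == 0 & is.na(dec$bins$mean_r2)))
})

test_that("LD decay edge cases: single site and one-bin layout", {
  g <- matrix(rbinom(20, 2, 0.5), ncol = 1)
  dec <- ld_decay(make_certain_gl(g), max_dist = 1000, bin_width = 100)
  expect_equal(nrow(dec$pairs), 0L)
  expect_true(all(dec$bins$n_pairs == 0L))

  set.seed(46)
  geno <- matrix(rbinom(30 * 3, 2, 0.5), 30, 3)
  gl <- make_certain_gl(geno, pos = c(100L, 300L, 600L))
  dec <- ld_decay(gl, max_dist = 600, bin_width = 600)
  expect_equal(nrow(dec$bins), 1L)
  expect_equal(dec$bins$n_pairs, 3L)
})
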