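test_that("score test agrees with the projection-matrix oracle on certain genotypes", {
  set.seed(51)
  for (k in 1:20) {
    n <- sample(30:80, 1)
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    d <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- rnorm(n) + 0.3 * X[, 2] + 0.2 * d
    got <- score_test(d, y, X)
    expect_equal(got$statistic, score_oracle(d, y, X), tolerance = 1e-10)
    expect_equal(got$n, n)
    expect_equal(got$status, "tested")
  }
})

test_that("a phenotype equal to the dosage is overwhelmingly significant", {
  set.seed(52)
  d <- rbinom(50, 2, 0.4)
  res <- score_test(d, y = d)
  expect_lt(res$p, 1e-10)
})

test_that("degenerate dosages are untestable, tiny samples are refused", {
  res <- score_test(rep(1, 30), rnorm(30))
  expect_equal(res$status, "untestable")
  expect_true(is.na(res$p))

  res <- score_test(c(0, 1), c(0.2, 0.5))
  expect_equal(res$status, "n_too_small")
})

test_that("missing phenotype values drop individuals from the test", {
  set.seed(53)
  d <- rbinom(40, 2, 0.4)
  y <- rnorm(40)
  y[1:10] <- NA
  res <- score_test(d, y)
  expect_equal(res$n, 30)
  expect_equal(res$statistic, score_oracle(d[11:40], y[11:40], matrix(1, 30)),
    tolerance = 1e-10
  )
})

test_that("ANGSD-style testability filters follow the minCount/minHigh rules", {
  # 25 certain hom-ref: expected minor count 0
  post <- matrix(0, 25, 3)
  post[, 1] <- 1
  expect_equal(apply_site_filters(post, rep(0, 25)), "minCount_fail")

  # 12 certain hom-ref + 12 certain het + 1 flat: both classes credible
  post <- rbind(
    matrix(rep(c(1, 0, 0), 12), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 1, 0), 12), ncol = 3, byrow = TRUE),
    c(1 / 3, 1 / 3, 1 / 3)
  )
  d <- c(rep(0, 12), rep(1, 12), 1)
  expect_equal(apply_site_filters(post, d), "tested")

  # only 9 high-credibility hets (plus uncertain carriers keeping the
  # expected minor count above 10): minHigh fails
  post <- rbind(
    matrix(rep(c(1, 0, 0), 25), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 1, 0), 9), ncol = 3, byrow = TRUE),
    matrix(rep(c(0.5, 0.5, 0), 6), ncol = 3, byrow = TRUE)
  )
  d <- c(rep(0, 25), rep(1, 9), rep(0.5, 6))
  expect_equal(apply_site_filters(post, d), "minHigh_fail")
})

test_that("BH adjustment is the closed-form step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(54)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("pruning keeps the most significant SNP per 500-bp neighborhood", {
  h <- data.frame(
    chrom = "chr01", pos = c(100L, 400L), p = c(1e-8, 1e-5),
    stringsAsFactors = FALSE
  )
  out <- prune_hits(h)
  expect_equal(out$pos, 100L)
  expect_equal(out$pruned_n, 1L)

  h$pos <- c(100L, 700L) # 600 bp apart: both kept
  expect_equal(prune_hits(h)$pos, c(100L, 700L))

  chain <- data.frame(
    chrom = "chr01", pos = c(0L, 400L, 800L), p = c(1e-3, 1e-6, 1e-2),
    stringsAsFactors = FALSE
  )
  out <- prune_hits(chain)
  expect_equal(out$pos, 400L)
  expect_equal(out$pruned_n, 2L)
})

test_that("pruning equals the significance-greedy oracle and ignores input order", {
  set.seed(55)
  for (k in 1:60) {
    n <- sample(1:8, 1)
    h <- data.frame(
      chrom = sample(c("chr01", "chr02"), n, replace = TRUE),
      pos = sample.int(2500, n),
      p = round(runif(n), 6),
      stringsAsFactors = FALSE
    )
    got <- prune_hits(h)
    got <- got[order(got$chrom, got$pos), c("chrom", "pos", "p")]
    want <- prune_oracle(h)[, c("chrom", "pos", "p")]
    expect_equal(got, want, ignore_attr = TRUE)

    shuf <- prune_hits(h[sample.int(n), , drop = FALSE])
    shuf <- shuf[order(shuf$chrom, shuf$pos), c("chrom", "pos", "p")]
    expect_equal(shuf, want, ignore_attr = TRUE)
  }
})

test_that("temperature adjustment fixes confounded phenotypes and stays calibrated", {
  set.seed(56)
  n <- 100
  n_rep <- 200
  p_with <- p_without <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    g <- rbinom(n, 2, 0.4)
    # acclimation temperature assigned with a genotype bias: confounding
    temp <- ifelse(runif(n) < 0.2 + 0.3 * g / 2, 28, 12)
    temp_z <- (temp - 20) / 8
    y <- temp_z + rnorm(n) # temperature-driven phenotype, no genotype effect
    p_with[k] <- score_test(g, y, cbind(1, temp_z))$p
    p_without[k] <- score_test(g, y)$p
  }
  expect_gt(mean(p_without < 0.05), 0.15) # inflated without the covariate
  rej <- mean(p_with < 0.05)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.12)
  expect_gt(stats::ks.test(p_with, "punif")$p.value, 0.01)
})

test_that("the association suite ties phenotypes, filters, BH and pruning together", {
  set.seed(57)
  cfg <- sim_config(
    n_ind = 80, n_expr = 80, n_pheno = 60, n_sites = 120,
    n_modules = 3, genes_per_module = 8, n_trans_eqtl = 2, n_cis_eqtl = 1,
    mean_depth = 25, n_traits = 2, seed = 99
  )
  st <- simulate_study(cfg)
  suite <- run_association_suite(st$gl, st$pheno, st$es)

  res <- suite$results
  expect_setequal(unique(res$class), c("trait", "single_mRNA", "module_ME"))
  # BH is applied within one phenotype's tested set
  one <- res[res$phenotype == res$phenotype[1] & res$status == "tested", ]
  expect_equal(one$p_adj, bh_adjust(one$p))
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  # pruned hits respect the window within each phenotype
  for (ph in unique(suite$pruned$phenotype)) {
    hp <- suite$pruned[suite$pruned$phenotype == ph, ]
    for (ch in unique(hp$chrom)) {
      pos <- sort(hp$pos[hp$chrom == ch])
      if (length(pos) > 1) expect_true(all(diff(pos) > 500))
    }
  }
  # a trait with too few complete cases is skipped with a reason
  ph2 <- st$pheno
  ph2$trait_rare <- NA_real_
  ph2$trait_rare[1:4] <- rnorm(4)
  attr(ph2, "traits") <- c(attr(st$pheno, "traits"), "trait_rare")
  suite2 <- run_association_suite(st$gl, ph2, es = NULL)
  expect_true("trait_rare" %in% names(suite2$skipped))
})
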