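test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(
    n_ind = 30, n_expr = 20, n_pheno = 10, n_sites = 40,
    n_modules = 2, genes_per_module = 5, n_trans_eqtl = 2, n_cis_eqtl = 1,
    n_traits = 2, seed = 123
  )
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$geno, b$geno)
  expect_identical(a$gl$lik, b$gl$lik)
  expect_identical(a$es$expr, b$es$expr)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth$planted, b$truth$planted)
  # config bound: no drawn frequency below the MAF floor
  expect_true(all(a$p_true >= 0.05))
})

test_that("genotypes follow HWE at the drawn allele frequency", {
  cfg <- sim_config(
    n_ind = 10000, n_sites = 1, maf_range = c(0.5, 0.5),
    n_modules = 1, genes_per_module = 2, n_trans_eqtl = 0, n_cis_eqtl = 0,
    n_expr = 10, n_pheno = 5, seed = 71
  )
  sim <- simulate_genotypes(cfg)
  expect_lt(abs(mean(sim$geno) - 1), 0.03)
  expect_true(all(sim$sites$pos >= 1))
  expect_true(all(sim$sites$ref != sim$sites$alt))
})

test_that("the read model produces calibrated genotype likelihoods", {
  set.seed(72)
  sites <- data.frame(
    id = "chr01_100", chrom = "chr01", pos = 100L, ref = "A", alt = "C",
    stringsAsFactors = FALSE
  )
  # deep coverage of hom-ref: the true genotype wins the likelihood
  geno <- matrix(0L, 2000, 1, dimnames = list(sprintf("i%04d", 1:2000), "chr01_100"))
  gl <- simulate_gls(geno, sites, depth = 30, base_error = 0.01, seed = 72)
  reads <- attr(gl, "reads")
  covered <- reads[, 1] > 0
  argmax <- apply(gl$lik[covered, 1, ], 1, which.max) - 1
  expect_gt(mean(argmax == 0), 0.99)

  # zero depth: all three likelihoods equal (missing)
  gl0 <- simulate_gls(geno[1:5, , drop = FALSE], sites, depth = 0, seed = 73)
  expect_true(all(gl_missing(gl0)))

  # posteriors concentrate on the truth as depth grows
  set.seed(74)
  geno2 <- matrix(rbinom(300, 2, 0.4), 300, 1,
    dimnames = list(sprintf("i%04d", 1:300), "chr01_100")
  )
  gl_hi <- simulate_gls(geno2, sites, depth = 60, base_error = 0.01, seed = 74)
  gp <- genotype_posteriors(gl_hi, p = 0.4)
  map <- apply(gp$posterior[, 1, ], 1, which.max) - 1
  expect_gt(mean(map == as.vector(geno2)), 0.995)
})

test_that("planted module-factor eQTL induce the predicted gene-dosage correlation", {
  cfg <- sim_config(
    n_ind = 300, n_expr = 300, n_pheno = 100, n_sites = 50,
    maf_range = c(0.3, 0.5),
    n_modules = 2, genes_per_module = 15, n_trans_eqtl = 1, n_cis_eqtl = 0,
    loading_range = c(0.8, 0.8), expr_noise_sd = 0.6, eqtl_beta = 1,
    temp_effect_expr = 0, n_traits = 0, seed = 75
  )
  sim <- simulate_genotypes(cfg)
  ex <- simulate_expression(cfg, sim, expr_individuals = sim$individuals)
  tr <- ex$truth$planted
  expect_equal(tr$target_type, "module")
  g <- sim$geno[, tr$site_id]
  members <- ex$es$modules$mrna_id[ex$es$modules$module == tr$target]
  lambda <- 0.8
  beta <- 1
  for (m in members) {
    x <- ex$es$expr[, m]
    pred <- lambda * beta * sd(g) / sd(x)
    expect_lt(abs(cor(x, g) - pred), 0.15)
  }
  # every member mRNA visibly correlates with the planted dosage
  cors <- cor(ex$es$expr[, members], g)
  expect_true(all(cors > 0.2))
})

test_that("a null generator yields uniform association p-values", {
  cfg <- sim_config(
    n_ind = 150, n_expr = 150, n_pheno = 50, n_sites = 200,
    n_modules = 2, genes_per_module = 5, n_trans_eqtl = 0, n_cis_eqtl = 0,
    mean_depth = 8, temp_effect_expr = 0, n_traits = 0, seed = 76
  )
  st <- simulate_study(cfg)
  freq <- estimate_allele_freq_em(st$gl)
  gp <- genotype_posteriors(st$gl, freq$p)
  y <- st$es$expr[, 1]
  res <- score_test_matrix(gp$dosage, y, NULL)
  keep <- res$status == "tested"
  expect_gt(stats::ks.test(res$p[keep], "punif")$p.value, 0.01)
})

test_that("truth-set bookkeeping matches the planted design exactly", {
  cfg <- sim_config(
    n_ind = 50, n_expr = 30, n_pheno = 25, n_sites = 100,
    n_modules = 4, genes_per_module = 6, n_trans_eqtl = 19, n_cis_eqtl = 1,
    n_traits = 3, seed = 77
  )
  st <- simulate_study(cfg)
  tr <- st$truth$planted
  expect_equal(mean(tr$label == "trans"), 0.95)
  expect_equal(mean(tr$label == "cis"), 0.05)
  # every planted eQTL references an existing site and target
  expect_true(all(tr$site_id %in% st$sites$id))
  expect_true(all(tr$target[tr$target_type == "gene"] %in% colnames(st$es$expr)))
  expect_true(all(tr$target[tr$target_type == "module"] %in% st$es$modules$module))
  # cis label iff site and target gene share a sequence
  cis <- tr[tr$label == "cis", ]
  gch <- st$es$genes$chrom[match(cis$target, st$es$genes$gene_id)]
  expect_equal(cis$chrom, gch)
  # exactly n_pheno non-missing values per trait
  for (t in attr(st$pheno, "traits")) {
    expect_equal(sum(!is.na(st$pheno[[t]])), 25)
  }
})

test_that("a near-noiseless single-module trait reproduces its eigengene", {
  cfg <- sim_config(
    n_ind = 60, n_expr = 60, n_pheno = 60, n_sites = 30,
    n_modules = 1, genes_per_module = 10, n_trans_eqtl = 0, n_cis_eqtl = 0,
    n_traits = 1, trait_weight = 1, temp_effect_trait = 0,
    order_effect_trait = 0, trait_noise_sd = 0.01, temp_effect_expr = 0,
    seed = 78
  )
  st <- simulate_study(cfg)
  f <- st$truth$factors[, 1]
  y <- st$pheno$trait1[match(rownames(st$truth$factors), st$pheno$individual)]
  expect_gt(abs(cor(y, f)), 0.99)
})

test_that("emitted study files re-read into the in-memory objects", {
  cfg <- sim_config(
    n_ind = 25, n_expr = 15, n_pheno = 10, n_sites = 30,
    n_modules = 2, genes_per_module = 4, n_trans_eqtl = 2, n_cis_eqtl = 1,
    n_traits = 2, seed = 79
  )
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)

  gl <- read_beagle_gl(file.path(dir, "sites.beagle"))
  expect_equal(gl$sites, st$gl$sites)
  expect_equal(gl$lik, st$gl$lik, tolerance = 1e-5)

  genes <- read_gff_genes(file.path(dir, "genes.gff3"))
  g0 <- st$es$genes[order(st$es$genes$chrom, st$es$genes$start, st$es$genes$end), ]
  expect_equal(genes$gene_id, g0$gene_id)
  expect_equal(genes$start, g0$start)
  expect_equal(genes$end, g0$end)

  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(expr, st$es$expr, tolerance = 1e-8)

  mods <- read_module_table(file.path(dir, "modules.tsv"))
  expect_equal(mods, st$es$modules)

  ph <- read_phenotype_table(file.path(dir, "phenotypes.tsv"))
  expect_equal(attr(ph, "traits"), attr(st$pheno, "traits"))
  expect_equal(ph$trait1, st$pheno$trait1, tolerance = 1e-8)

  lay <- read_genome_layout(file.path(dir, "layout.tsv"))
  expect_equal(lay, st$layout, ignore_attr = TRUE)
})
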