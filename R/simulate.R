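#' Default genome layout for simulation
#'
#' 24 large chromosomes plus unplaced scaffolds, with the scaffolds making
#' up a fixed fraction of total genome length — the karyotype structure of
#' the killifish reference the pipeline was designed around (24
#' chromosomes > 28 Mb carrying 78.4% of the genome).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_scaffold number of scaffolds.
#' @param scaffold_fraction fraction of total genome length on scaffolds.
#' @return a [genome_layout()].
#' @export
default_genome_layout <- function(n_chrom = 24, chrom_length = 30e6,
                                  n_scaffold = 50, scaffold_fraction = 0.216) {
  chrom_total <- n_chrom * chrom_length
  scaf_total <- chrom_total * scaffold_fraction / (1 - scaffold_fraction)
  scaf_len <- round(scaf_total / n_scaffold)
  genome_layout(
    name = c(
      sprintf("chr%02d", seq_len(n_chrom)),
      sprintf("scaf%03d", seq_len(n_scaffold))
    ),
    length = c(rep(chrom_length, n_chrom), rep(scaf_len, n_scaffold)),
    class = c(rep("chromosome", n_chrom), rep("scaffold", n_scaffold))
  )
}

#' Simulation configuration
#'
#' Defines the generative model the pipeline is exercised on: HWE
#' genotypes at uniformly drawn minor allele frequencies across a
#' chromosomes-plus-scaffolds layout, Poisson-coverage sequencing reads
#' converted to genotype likelihoods, module-structured expression with
#' planted cis (per-gene) and trans (latent module-factor) eQTL, and
#' traits driven by module eigengenes plus acclimation covariates.
#' Defaults mirror the study design the pipeline targets: 172 genotyped
#' individuals at 4.1x mean depth, a minority (~25-35) with expression and
#' trait data, acclimation temperatures of 12/28 degrees C, and trans
#' effects planted on module factors so that eQTL hotspots arise
#' mechanistically.
#'
#' @param n_ind genotyped individuals.
#' @param n_expr individuals with expression data (the phenotyped pool,
#'   drawn once and shared across traits).
#' @param n_pheno non-missing individuals per trait (sampled within the
#'   pool).
#' @param genome a [genome_layout()].
#' @param mean_depth mean sequencing depth (Poisson), default 4.1.
#' @param base_error per-read base error rate, default 0.01.
#' @param maf_range range of the uniform allele-frequency draw.
#' @param n_sites number of biallelic sites.
#' @param n_modules,genes_per_module co-expression module structure.
#' @param loading_range range of uniform per-gene factor loadings.
#' @param expr_noise_sd residual sd of gene expression.
#' @param n_trans_eqtl module-factor (trans) eQTL planted.
#' @param n_cis_eqtl per-gene cis eQTL planted.
#' @param eqtl_beta planted effect size (per alternate-allele copy).
#' @param temp_effect_expr effect of (standardized) acclimation
#'   temperature on each module factor.
#' @param n_traits number of physiological traits; trait t is driven by
#'   module t's factor.
#' @param trait_weight weight of the driving module factor in each trait.
#' @param temp_effect_trait,order_effect_trait covariate effects.
#' @param trait_noise_sd residual sd of traits.
#' @param tissue tissue label of the expression set.
#' @param seed integer seed fixing the whole generative stream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_ind = 172, n_expr = 35, n_pheno = 25,
                       genome = default_genome_layout(),
                       mean_depth = 4.1, base_error = 0.01,
                       maf_range = c(0.05, 0.5), n_sites = 5000,
                       n_modules = 10, genes_per_module = 30,
                       loading_range = c(0.5, 0.9), expr_noise_sd = 0.6,
                       n_trans_eqtl = 20, n_cis_eqtl = 2, eqtl_beta = 1,
                       eqtl_maf_min = 0.1, temp_effect_expr = 0.5,
                       n_traits = 6, trait_weight = 1,
                       temp_effect_trait = 0.5, order_effect_trait = 0.25,
                       trait_noise_sd = 0.5,
                       tissue = "heart", seed = 1) {
  stopifnot(
    n_ind >= 1, n_expr >= 1, n_expr <= n_ind, n_pheno >= 0, n_pheno <= n_expr,
    mean_depth >= 0, base_error > 0, base_error < 0.5,
    n_sites >= 1, n_modules >= 1, genes_per_module >= 2,
    n_trans_eqtl >= 0, n_cis_eqtl >= 0,
    is.finite(eqtl_beta), n_traits >= 0
  )
  structure(
    list(
      n_ind = n_ind, n_expr = n_expr, n_pheno = n_pheno, genome = genome,
      mean_depth = mean_depth, base_error = base_error,
      maf_range = maf_range, n_sites = n_sites,
      n_modules = n_modules, genes_per_module = genes_per_module,
      loading_range = loading_range, expr_noise_sd = expr_noise_sd,
      n_trans_eqtl = n_trans_eqtl, n_cis_eqtl = n_cis_eqtl,
      eqtl_beta = eqtl_beta, eqtl_maf_min = eqtl_maf_min,
      temp_effect_expr = temp_effect_expr,
      n_traits = n_traits, trait_weight = trait_weight,
      temp_effect_trait = temp_effect_trait,
      order_effect_trait = order_effect_trait,
      trait_noise_sd = trait_noise_sd,
      tissue = tissue, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate genotypes under HWE
#'
#' Draws per-site alternate-allele frequencies uniformly from
#' `maf_range`, places sites uniformly over the genome layout
#' (length-weighted sequence choice, uniform position), and samples
#' genotypes Binomial(2, p) per individual.
#'
#' @param config a [sim_config()].
#' @return list: `geno` (`n_ind x n_sites` 0/1/2 matrix), `sites`
#'   (data.frame id/chrom/pos/ref/alt), `p_true` (drawn frequencies),
#'   `individuals`.
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed + 1L)
  m <- config$n_sites
  n <- config$n_ind
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  seq_idx <- sample.int(nrow(config$genome), m,
    replace = TRUE,
    prob = config$genome$length
  )
  pos <- floor(stats::runif(m, 1, config$genome$length[seq_idx] + 1))
  key <- paste(seq_idx, pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos[dup] <- floor(stats::runif(sum(dup), 1, config$genome$length[seq_idx[dup]] + 1))
    key <- paste(seq_idx, pos)
  }
  chrom <- config$genome$name[seq_idx]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ord <- order(match(chrom, config$genome$name), pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  p <- p[ord]
  ref <- ref[ord]
  alt <- alt[ord]
  geno <- matrix(
    stats::rbinom(n * m, 2L, rep(p, each = n)),
    nrow = n, ncol = m
  )
  individuals <- sprintf("ind%04d", seq_len(n))
  sites <- data.frame(
    id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
    ref = ref, alt = unname(alt), stringsAsFactors = FALSE
  )
  rownames(geno) <- individuals
  colnames(geno) <- sites$id
  list(geno = geno, sites = sites, p_true = p, individuals = individuals)
}

#' Simulate lcWGS genotype likelihoods from true genotypes
#'
#' Per individual and site, the read count is Poisson(`depth`); alternate
#' reads are Binomial(n_reads, e_g) with
#' `e_g = g/2 (1 - eps) + (1 - g/2) eps` for true genotype g; the three
#' genotype likelihoods are the same binomial likelihood evaluated at
#' g = 0, 1, 2. Zero reads give a flat (missing) triplet.
#'
#' @param geno `n x m` 0/1/2 genotype matrix.
#' @param sites site data.frame (as from [simulate_genotypes()]).
#' @param depth mean depth (scalar or per-individual vector).
#' @param base_error per-read error rate eps.
#' @param seed RNG seed.
#' @return a [gl_set()]; the realized read-count matrix is attached as
#'   attribute `"reads"`.
#' @export
simulate_gls <- function(geno, sites, depth = 4.1, base_error = 0.01, seed = 1) {
  set.seed(seed)
  n <- nrow(geno)
  m <- ncol(geno)
  reads <- matrix(stats::rpois(n * m, depth), n, m)
  e_g <- function(g) g / 2 * (1 - base_error) + (1 - g / 2) * base_error
  alt_reads <- matrix(
    stats::rbinom(n * m, as.vector(reads), e_g(as.vector(geno))),
    n, m
  )
  lik <- array(NA_real_, dim = c(n, m, 3L))
  for (g in 0:2) {
    lik[, , g + 1L] <- matrix(
      stats::dbinom(as.vector(alt_reads), as.vector(reads), e_g(g)),
      n, m
    )
  }
  flat <- reads == 0L
  for (g in 1:3) {
    slab <- lik[, , g]
    slab[flat] <- 1 / 3
    lik[, , g] <- slab
  }
  out <- gl_set(sites, lik, rownames(geno))
  attr(out, "reads") <- reads
  out
}

#' Simulate module-structured expression with planted eQTL
#'
#' Per module m a latent factor `f_m ~ N(0, 1)` (plus a standardized
#' acclimation-temperature shift and the planted module-factor eQTL
#' effects `beta * g`) drives its member genes:
#' `x_gene = lambda_gene * f_m + beta_cis * g (cis-planted genes only)
#' + N(0, sigma^2)`. Trans eQTL therefore act on whole modules — the
#' mechanism that produces hotspots — while cis eQTL act on single genes
#' whose coordinates are forced onto the SNP's sequence. Gene coordinates
#' are otherwise uniform over the layout; module-factor SNPs and their
#' member genes are not co-located by construction.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genotypes()].
#' @param expr_individuals ids of the expression pool (defaults to the
#'   first draw of `n_expr` individuals under the config seed).
#' @param temperature named temperature covariate (12/28) for the pool;
#'   NULL simulates expression without a temperature shift.
#' @return list: `es` (an [expression_set()]), `truth` (class
#'   `truth_set`: `planted` data.frame with site/target/beta/label,
#'   `factors` matrix, `loadings`, `expr_individuals`).
#' @export
simulate_expression <- function(config, sim, expr_individuals = NULL,
                                temperature = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(expr_individuals)) {
    expr_individuals <- sort(sample(sim$individuals, config$n_expr))
  }
  n <- length(expr_individuals)
  n_genes <- config$n_modules * config$genes_per_module
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  module_ids <- sprintf("M%02d", rep(seq_len(config$n_modules),
    each = config$genes_per_module
  ))
  # random gene placement: length-weighted sequence, uniform start
  seq_idx <- sample.int(nrow(config$genome), n_genes,
    replace = TRUE,
    prob = config$genome$length
  )
  glen <- floor(stats::runif(n_genes, 2000, 20000))
  gstart <- floor(stats::runif(
    n_genes, 1,
    pmax(2, config$genome$length[seq_idx] - glen)
  ))
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = config$genome$name[seq_idx],
    start = gstart, end = gstart + glen,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )

  m_sites <- nrow(sim$sites)
  n_plant <- config$n_trans_eqtl + config$n_cis_eqtl
  if (n_plant > m_sites) stop("more planted eQTL than sites")
  # plant on intermediate-frequency sites: planted effects stay
  # identifiable under the pipeline's own MAF filter, mirroring the
  # elevated heterozygosity of detectable eQTL
  maf <- pmin(sim$p_true, 1 - sim$p_true)
  eligible <- which(maf >= config$eqtl_maf_min)
  if (length(eligible) < n_plant) eligible <- seq_len(m_sites)
  plant_sites <- sample(eligible, n_plant)
  trans_sites <- utils::head(plant_sites, config$n_trans_eqtl)
  cis_sites <- utils::tail(plant_sites, config$n_cis_eqtl)

  planted <- list()
  # trans eQTL: each acts on a module factor (round-robin over modules)
  if (config$n_trans_eqtl > 0) {
    mod_for <- rep(seq_len(config$n_modules), length.out = config$n_trans_eqtl)
    planted$trans <- data.frame(
      site_id = sim$sites$id[trans_sites],
      chrom = sim$sites$chrom[trans_sites],
      pos = sim$sites$pos[trans_sites],
      target_type = "module",
      target = sprintf("M%02d", mod_for),
      beta = config$eqtl_beta, label = "trans",
      stringsAsFactors = FALSE
    )
  }
  # cis eQTL: each acts on one gene, relocated onto the SNP's sequence
  if (config$n_cis_eqtl > 0) {
    cis_genes <- sample.int(n_genes, config$n_cis_eqtl)
    for (k in seq_len(config$n_cis_eqtl)) {
      gi <- cis_genes[k]
      si <- cis_sites[k]
      chrom_len <- config$genome$length[config$genome$name == sim$sites$chrom[si]]
      new_start <- max(1, min(
        sim$sites$pos[si] - floor(glen[gi] / 2),
        chrom_len - glen[gi]
      ))
      genes$chrom[gi] <- sim$sites$chrom[si]
      genes$start[gi] <- new_start
      genes$end[gi] <- new_start + glen[gi]
    }
    planted$cis <- data.frame(
      site_id = sim$sites$id[cis_sites],
      chrom = sim$sites$chrom[cis_sites],
      pos = sim$sites$pos[cis_sites],
      target_type = "gene",
      target = gene_ids[cis_genes],
      beta = config$eqtl_beta, label = "cis",
      stringsAsFactors = FALSE
    )
  }
  planted <- Filter(Negate(is.null), planted)
  planted <- if (length(planted)) {
    do.call(rbind, c(planted, list(make.row.names = FALSE)))
  } else {
    data.frame(
      site_id = character(), chrom = character(), pos = integer(),
      target_type = character(), target = character(), beta = numeric(),
      label = character(), stringsAsFactors = FALSE
    )
  }

  g_expr <- sim$geno[expr_individuals, , drop = FALSE]
  temp_z <- if (is.null(temperature)) {
    rep(0, n)
  } else {
    (as.numeric(temperature[expr_individuals]) - 20) / 8
  }
  factors <- matrix(stats::rnorm(n * config$n_modules), n, config$n_modules,
    dimnames = list(expr_individuals, sprintf("M%02d", seq_len(config$n_modules)))
  )
  factors <- factors + config$temp_effect_expr * temp_z
  if (config$n_trans_eqtl > 0) {
    for (k in seq_len(nrow(planted))) {
      if (planted$target_type[k] != "module") next
      factors[, planted$target[k]] <- factors[, planted$target[k]] +
        planted$beta[k] * g_expr[, planted$site_id[k]]
    }
  }
  lambda <- stats::runif(n_genes, config$loading_range[1], config$loading_range[2])
  names(lambda) <- gene_ids
  # planted cis targets emulate detectable cis eQTL: mRNAs that are both
  # strongly module-affiliated and cis-regulated. They get the top loading
  # and halved residual noise so their membership rank survives the extra
  # cis-dosage variance and they enter the tested top-k set.
  cis_targets <- planted$target[planted$target_type == "gene"]
  lambda[cis_targets] <- config$loading_range[2]
  noise_sd <- rep(config$expr_noise_sd, n_genes)
  names(noise_sd) <- gene_ids
  noise_sd[cis_targets] <- config$expr_noise_sd / 2
  expr <- factors[, match(module_ids, colnames(factors)), drop = FALSE] *
    matrix(lambda, n, n_genes, byrow = TRUE) +
    matrix(stats::rnorm(n * n_genes, sd = rep(noise_sd, each = n)), n, n_genes)
  for (k in seq_len(nrow(planted))) {
    if (planted$target_type[k] != "gene") next
    gi <- planted$target[k]
    expr[, match(gi, gene_ids)] <- expr[, match(gi, gene_ids)] +
      planted$beta[k] * g_expr[, planted$site_id[k]]
  }
  colnames(expr) <- gene_ids
  rownames(expr) <- expr_individuals

  # invariant: a cis label must mean same-sequence site and gene
  cis_rows <- planted$label == "cis"
  if (any(cis_rows)) {
    gsame <- genes$chrom[match(planted$target[cis_rows], genes$gene_id)] ==
      planted$chrom[cis_rows]
    if (!all(gsame)) stop("planted cis site on wrong sequence")
  }

  es <- expression_set(
    expr = expr,
    genes = genes,
    modules = data.frame(
      mrna_id = gene_ids, module = module_ids,
      stringsAsFactors = FALSE
    ),
    tissue = config$tissue
  )
  truth <- structure(
    list(
      planted = planted, factors = factors, loadings = lambda,
      expr_individuals = expr_individuals
    ),
    class = "truth_set"
  )
  list(es = es, truth = truth)
}

#' Simulate physiological traits from module factors and covariates
#'
#' `trait_t = w * f_t + a * temp_z + b * order + N(0, sigma^2)`, where
#' `f_t` is module t's latent factor (standardized), `temp_z` the
#' standardized acclimation temperature and `order` the 0/1 acclimation
#' order. Exactly `n_pheno` individuals per trait (sampled from the
#' expression pool) receive non-missing values.
#'
#' @param config a [sim_config()].
#' @param factors latent module-factor matrix (pool individuals x
#'   modules), from [simulate_expression()].
#' @param covariates data.frame `individual`, `temperature`,
#'   `acclimation_order` covering at least the pool.
#' @return phenotype data.frame (`individual`, covariates, trait columns
#'   `trait1..trait_n`, NA outside the per-trait samples), with attribute
#'   `"traits"`.
#' @export
simulate_traits <- function(config, factors, covariates) {
  set.seed(config$seed + 3L)
  pool <- rownames(factors)
  ci <- match(pool, covariates$individual)
  if (anyNA(ci)) stop("covariates missing for expression-pool individuals")
  temp_z <- (as.numeric(covariates$temperature[ci]) - 20) / 8
  ord01 <- as.numeric(factor(covariates$acclimation_order[ci])) - 1
  out <- covariates
  traits <- character(0)
  for (t in seq_len(config$n_traits)) {
    mcol <- 1 + (t - 1) %% ncol(factors)
    f <- as.vector(scale(factors[, mcol]))
    y <- config$trait_weight * f +
      config$temp_effect_trait * temp_z +
      config$order_effect_trait * ord01 +
      stats::rnorm(length(pool), sd = config$trait_noise_sd)
    obs <- sample(seq_along(pool), min(config$n_pheno, length(pool)))
    tr <- paste0("trait", t)
    out[[tr]] <- NA_real_
    out[[tr]][match(pool[obs], out$individual)] <- y[obs]
    traits <- c(traits, tr)
  }
  attr(out, "traits") <- traits
  out
}

#' Simulate a complete study
#'
#' One call producing every input the pipeline consumes, under a single
#' seed: genotypes, genotype likelihoods, covariates, module-structured
#' expression with planted eQTL, and traits.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study`: `config`, `layout`, `sites`,
#'   `geno`, `p_true`, `gl`, `es`, `truth`, `pheno` (phenotype table with
#'   covariates for all genotyped individuals), `expr_individuals`.
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_genotypes(config)
  gl <- simulate_gls(sim$geno, sim$sites,
    depth = config$mean_depth,
    base_error = config$base_error, seed = config$seed + 4L
  )
  set.seed(config$seed + 5L)
  n <- config$n_ind
  covariates <- data.frame(
    individual = sim$individuals,
    temperature = sample(rep(c(12, 28), length.out = n)),
    acclimation_order = sample(rep(c("12then28", "28then12"), length.out = n)),
    stringsAsFactors = FALSE
  )
  temp_named <- stats::setNames(covariates$temperature, covariates$individual)
  ex <- simulate_expression(config, sim, temperature = temp_named)
  pheno <- simulate_traits(config, ex$truth$factors, covariates)
  structure(
    list(
      config = config, layout = config$genome, sites = sim$sites,
      geno = sim$geno, p_true = sim$p_true, gl = gl,
      es = ex$es, truth = ex$truth, pheno = pheno,
      expr_individuals = ex$truth$expr_individuals
    ),
    class = "sim_study"
  )
}

#' Write a simulated study to a directory of standard text files
#'
#' Emits `sites.beagle`, `genes.gff3`, `modules.tsv`, `expression.tsv`,
#' `phenotypes.tsv`, `truth.tsv` and `layout.tsv`, each re-readable by the
#' package's readers into the in-memory objects.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_beagle_gl(study$gl, file.path(dir, "sites.beagle"))
  write_gff_genes(study$es$genes, file.path(dir, "genes.gff3"))
  utils::write.table(study$es$modules, file.path(dir, "modules.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_expression_matrix(study$es$expr, file.path(dir, "expression.tsv"))
  write_phenotype_table(study$pheno, file.path(dir, "phenotypes.tsv"))
  utils::write.table(study$truth$planted, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_genome_layout(study$layout, file.path(dir, "layout.tsv"))
  invisible(dir)
}
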