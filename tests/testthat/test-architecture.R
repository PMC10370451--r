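genes_fix <- data.frame(
  gene_id = c("gA", "gB", "tf1"),
  chrom = c("chr02", "chr01", "chr01"),
  start = c(1L, 90L, 100000L),
  end = c(500L, 200L, 105000L),
  strand = "+",
  is_tf = c(FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

test_that("cis/trans classification follows the chromosome-level rule", {
  eqtl <- data.frame(
    id = c("s1", "s2", "s3"),
    chrom = c("chr01", "chr01", "chr01"),
    pos = c(100L, 100L, 10000L),
    target = c("gA", "gB", "gB"),
    stringsAsFactors = FALSE
  )
  cl <- classify_cis_trans(eqtl, genes_fix)
  # different sequence: trans, no distance
  expect_equal(cl$classification[1], "trans")
  expect_true(is.na(cl$distance[1]))
  # inside the gene: cis at distance 0
  expect_equal(cl$classification[2], "cis")
  expect_equal(cl$distance[2], 0)
  # same sequence but distal: still cis (chromosome-level definition)
  expect_equal(cl$classification[3], "cis")
  expect_equal(cl$distance[3], 9800) # to the nearest boundary (end = 200)
  # trans fraction complements cis fraction
  expect_equal(
    mean(cl$classification == "trans") + mean(cl$classification == "cis"), 1
  )

  unknown <- data.frame(
    id = "s4", chrom = "chr01", pos = 5L, target = "nope",
    stringsAsFactors = FALSE
  )
  expect_warning(cl2 <- classify_cis_trans(unknown, genes_fix), "absent")
  expect_equal(cl2$classification, "unclassifiable")
})

test_that("hotspots are SNPs associated with more than one mRNA per tissue", {
  eqtl <- data.frame(
    id = c("s1", "s1", "s2", "s3", "s3", "s3"),
    target = c("mA", "mB", "mA", "mC", "mD", "mE"),
    tissue = c(rep("heart", 3), rep("brain", 3)),
    stringsAsFactors = FALSE
  )
  hs <- find_hotspots(eqtl)
  heart <- hs$per_snp[hs$per_snp$tissue == "heart", ]
  expect_equal(heart$hotspot[heart$id == "s1"], TRUE)
  expect_equal(heart$n_mrna[heart$id == "s1"], 2L)
  expect_equal(heart$hotspot[heart$id == "s2"], FALSE)
  brain <- hs$summary[hs$summary$tissue == "brain", ]
  expect_equal(brain$n_hotspot, 1L)
  expect_equal(brain$mrna_per_snp_max, 3L)
  hsum <- hs$summary[hs$summary$tissue == "heart", ]
  expect_equal(hsum$mrna_per_snp_mean, 1.5)
  expect_equal(hsum$eqtl_per_mrna_max, 2L) # mA has eQTL s1 and s2
})

test_that("the chromosome-aware trans null gives closed-form expected counts", {
  # 24 equally covered sequences, all eQTL cis: expected trans = 23/24 of n
  chroms <- sprintf("chr%02d", 1:24)
  site_chroms <- rep(chroms, each = 10)
  cl <- data.frame(
    classification = rep("cis", 48),
    target_chrom = rep(chroms, 2),
    stringsAsFactors = FALSE
  )
  tt <- expected_trans_test(cl, site_chroms)
  expect_equal(unname(tt$expected["trans"]), 48 * 23 / 24, tolerance = 1e-10)
  expect_equal(unname(tt$observed["cis"]), 48)
  expect_lt(tt$p, 1e-10)

  # single eQTL: computed but flagged as low-count
  tt1 <- expected_trans_test(cl[1, ], site_chroms)
  expect_true(is.finite(tt1$statistic))
  expect_equal(tt1$note, "low_count")

  # degenerate: every tested site on the target's own sequence
  cl2 <- data.frame(
    classification = "cis", target_chrom = "chr01",
    stringsAsFactors = FALSE
  )
  tt2 <- expected_trans_test(cl2, rep("chr01", 5))
  expect_equal(tt2$note, "undefined")
  expect_true(is.na(tt2$p))
})

test_that("proximity annotation honors the inclusive 5-kb window", {
  # tf1 spans chr01:100000-105000
  sites <- data.frame(
    id = c("up4999", "edge5000", "up5001", "inside_gB", "far"),
    chrom = "chr01",
    pos = c(95001L, 95000L, 94999L, 150L, 500000L),
    stringsAsFactors = FALSE
  )
  ann <- annotate_proximity(sites, genes_fix, window = 5000)
  expect_true(ann$near_tf[ann$id == "up4999"])
  expect_true(ann$near_tf[ann$id == "edge5000"]) # exactly 5,000 bp: inclusive
  expect_false(ann$near_tf[ann$id == "up5001"])
  # genic in a non-TF gene, no TF within the window
  expect_equal(ann$annotation[ann$id == "inside_gB"], "genic")
  expect_equal(ann$genes[ann$id == "inside_gB"], "gB")
  expect_false(ann$near_tf[ann$id == "inside_gB"])
  expect_equal(ann$annotation[ann$id == "far"], "intergenic")
})

test_that("eigengene eQTL are checked against their module's gene neighborhoods", {
  es <- list(
    genes = data.frame(
      gene_id = c("m1", "m2", "x1"),
      chrom = c("chr01", "chr02", "chr03"),
      start = c(1000L, 1000L, 1000L),
      end = c(2000L, 2000L, 2000L),
      stringsAsFactors = FALSE
    ),
    modules = data.frame(
      mrna_id = c("m1", "m2", "x1"),
      module = c("M01", "M01", "M02"),
      stringsAsFactors = FALSE
    )
  )
  me <- data.frame(
    id = c("a", "b"),
    chrom = c("chr01", "chr04"),
    pos = c(1500L, 1500L),
    module = "M01",
    stringsAsFactors = FALSE
  )
  out <- me_overlap_check(me, es)
  expect_true(out$near_module_gene[1]) # inside a member gene
  expect_false(out$near_module_gene[2]) # sequence without member genes
})

test_that("the sharing test contrasts within- and among-module mRNA pairs", {
  modules <- data.frame(
    mrna_id = c(paste0("a", 1:6), paste0("b", 1:6)),
    module = rep(c("MA", "MB"), each = 6),
    stringsAsFactors = FALSE
  )
  # sharing planted only across modules: a_i and b_i share SNP s_i
  eqtl <- data.frame(
    id = rep(paste0("s", 1:6), 2),
    target = c(paste0("a", 1:6), paste0("b", 1:6)),
    stringsAsFactors = FALSE
  )
  st <- sharing_test(eqtl, modules, modules$mrna_id)
  expect_equal(st$mean_within, 0)
  expect_gt(st$mean_among, 0)
  expect_lt(st$p, 0.05)
  expect_lt(st$statistic, 0)

  # everyone shares a single eQTL: degenerate, reported as no difference
  eqtl_all <- data.frame(
    id = "s0", target = modules$mrna_id, stringsAsFactors = FALSE
  )
  st2 <- sharing_test(eqtl_all, modules, modules$mrna_id)
  expect_equal(st2$note, "degenerate")
  expect_equal(st2$mean_within, 1)
  expect_equal(st2$mean_among, 1)
  expect_true(is.na(st2$p))

  # no sharing anywhere: also degenerate with zero means
  eqtl_none <- data.frame(
    id = paste0("u", 1:12), target = modules$mrna_id, stringsAsFactors = FALSE
  )
  st3 <- sharing_test(eqtl_none, modules, modules$mrna_id)
  expect_equal(st3$note, "degenerate")
  expect_equal(st3$mean_within, 0)
  expect_equal(st3$mean_among, 0)
})

test_that("heterozygosity comparison reports means, t-test and permutation", {
  set.seed(91)
  background <- heterozygosity(runif(500, 0.05, 0.5))
  # focal set drawn near p = 0.5: higher He than background
  focal <- heterozygosity(runif(40, 0.45, 0.5))
  hc <- he_comparison(focal, background, n_perm = 2000, seed = 1)
  expect_gt(hc$diff, 0)
  expect_lt(hc$t_p, 1e-6)
  expect_lt(hc$perm_p, 0.01)

  # focal equal to background: no difference
  hc2 <- he_comparison(background, background, n_perm = 500, seed = 1)
  expect_equal(hc2$diff, 0)
  expect_gt(hc2$t_p, 0.99)
  expect_equal(hc2$perm_p, 1, tolerance = 0.01)

  # singleton focal: t-test undefined, permutation still reported
  hc3 <- he_comparison(focal[1], background, n_perm = 500, seed = 1)
  expect_equal(hc3$note, "t_test_undefined")
  expect_true(is.finite(hc3$perm_p))
})

test_that("overlap sets intersect catalogs at SNP and containing-gene level", {
  genes <- data.frame(
    gene_id = "big", chrom = "chr01", start = 100L, end = 10000L,
    strand = "+", is_tf = FALSE, stringsAsFactors = FALSE
  )
  trait_snps <- data.frame(id = "chr01_200", chrom = "chr01", pos = 200L)
  eqtl_snps <- data.frame(id = "chr01_9000", chrom = "chr01", pos = 9000L)
  other <- data.frame(id = "chr02_5", chrom = "chr02", pos = 5L)

  ov <- overlap_sets(
    list(trait = trait_snps, eqtl = eqtl_snps, me = other),
    genes = genes
  )
  # two different SNPs inside one gene: gene-level hit, SNP-level miss
  tr_eq_snp <- ov$snp[ov$snp$set_a == "trait" & ov$snp$set_b == "eqtl", ]
  expect_equal(tr_eq_snp$n_overlap, 0L)
  tr_eq_gene <- ov$gene[ov$gene$set_a == "trait" & ov$gene$set_b == "eqtl", ]
  expect_equal(tr_eq_gene$n_overlap, 1L)
  expect_equal(tr_eq_gene$shared, "big")
  # disjoint catalogs stay disjoint everywhere
  expect_equal(ov$snp[ov$snp$set_b == "me", "n_overlap"], c(0L, 0L))

  # a shared SNP appears in the SNP-level intersection
  ov2 <- overlap_sets(list(a = trait_snps, b = trait_snps))
  expect_equal(ov2$snp$n_overlap, 1L)
  expect_equal(ov2$snp$shared, "chr01_200")

  # an mRNA's eQTL colliding with its own module's eQTL_ME is reported
  modules <- data.frame(mrna_id = "mX", module = "M01", stringsAsFactors = FALSE)
  eqtl <- data.frame(
    id = "chr01_200", chrom = "chr01", pos = 200L, target = "mX",
    stringsAsFactors = FALSE
  )
  eqtl_me <- data.frame(
    id = "chr01_200", chrom = "chr01", pos = 200L, module = "M01",
    stringsAsFactors = FALSE
  )
  ov3 <- overlap_sets(list(eqtl = eqtl, me = eqtl_me),
    genes = genes,
    eqtl = eqtl, eqtl_me = eqtl_me, modules = modules
  )
  expect_equal(nrow(ov3$mrna_module_conflicts), 1L)
  expect_true(ov3$mrna_module_conflicts$snp_level)
})
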