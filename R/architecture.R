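#' Classify eQTL as cis or trans
#'
#' The classification is chromosome-level: an eQTL is trans when the SNP
#' sits on a different chromosome or scaffold than the gene encoding the
#' mRNA it is associated with, and cis when it shares the sequence, however
#' distal. For cis eQTL the distance is 0 when the SNP falls inside the
#' gene interval and otherwise the distance to the nearest gene boundary.
#' Module-eigengene associations are never classified (a module has no
#' single location).
#'
#' @param eqtl data.frame with columns `chrom`, `pos` (SNP) and `target`
#'   (gene id of the associated mRNA); extra columns carried through.
#' @param genes gene annotation as from [read_gff_genes()].
#' @return the input with added columns `classification`
#'   (`"cis"`/`"trans"`/`"unclassifiable"`), `distance` (bp, NA for
#'   trans/unclassifiable), `target_chrom`.
#' @export
classify_cis_trans <- function(eqtl, genes) {
  eqtl <- as.data.frame(eqtl, stringsAsFactors = FALSE)
  gi <- match(eqtl$target, genes$gene_id)
  if (anyNA(gi)) {
    warning(sum(is.na(gi)), " eQTL target(s) absent from annotation; left unclassifiable")
  }
  tchrom <- genes$chrom[gi]
  tstart <- genes$start[gi]
  tend <- genes$end[gi]
  same <- !is.na(tchrom) & eqtl$chrom == tchrom
  inside <- same & eqtl$pos >= tstart & eqtl$pos <= tend
  dist <- rep(NA_real_, nrow(eqtl))
  dist[inside] <- 0
  edge <- same & !inside
  dist[edge] <- pmin(
    abs(eqtl$pos[edge] - tstart[edge]),
    abs(eqtl$pos[edge] - tend[edge])
  )
  eqtl$classification <- ifelse(is.na(tchrom), "unclassifiable",
    ifelse(same, "cis", "trans")
  )
  eqtl$distance <- dist
  eqtl$target_chrom <- tchrom
  eqtl
}

#' Hotspot detection among single-mRNA eQTL
#'
#' A hotspot is a SNP associated with the expression of more than one
#' mRNA within one tissue. Also summarizes the per-SNP target-mRNA counts
#' and the per-mRNA eQTL counts (mean, sd, max) per tissue.
#'
#' @param eqtl data.frame of significant single-mRNA associations with
#'   columns `id` (SNP), `target` (mRNA) and optionally `tissue` (a single
#'   tissue is assumed when absent).
#' @return list: `per_snp` (tissue, id, n_mrna, hotspot), `per_mrna`
#'   (tissue, target, n_eqtl), `summary` (per-tissue mean/sd/max of both
#'   count distributions and hotspot counts).
#' @export
find_hotspots <- function(eqtl) {
  eqtl <- as.data.frame(eqtl, stringsAsFactors = FALSE)
  if (!"tissue" %in% names(eqtl)) eqtl$tissue <- "tissue"
  eqtl <- unique(eqtl[, c("tissue", "id", "target")])
  per_snp <- do.call(rbind, lapply(split(eqtl, eqtl$tissue), function(d) {
    cnt <- table(d$id)
    data.frame(
      tissue = d$tissue[1], id = names(cnt), n_mrna = as.integer(cnt),
      hotspot = as.integer(cnt) >= 2L, stringsAsFactors = FALSE
    )
  }))
  per_mrna <- do.call(rbind, lapply(split(eqtl, eqtl$tissue), function(d) {
    cnt <- table(d$target)
    data.frame(
      tissue = d$tissue[1], target = names(cnt), n_eqtl = as.integer(cnt),
      stringsAsFactors = FALSE
    )
  }))
  summary <- do.call(rbind, lapply(unique(eqtl$tissue), function(ti) {
    s <- per_snp[per_snp$tissue == ti, ]
    m <- per_mrna[per_mrna$tissue == ti, ]
    data.frame(
      tissue = ti,
      n_assoc = sum(s$n_mrna),
      n_snp = nrow(s), n_mrna = nrow(m),
      n_hotspot = sum(s$hotspot),
      hotspot_fraction = mean(s$hotspot),
      mrna_per_snp_mean = mean(s$n_mrna),
      mrna_per_snp_sd = stats::sd(s$n_mrna),
      mrna_per_snp_max = max(s$n_mrna),
      eqtl_per_mrna_mean = mean(m$n_eqtl),
      eqtl_per_mrna_sd = stats::sd(m$n_eqtl),
      eqtl_per_mrna_max = max(m$n_eqtl),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_snp) <- rownames(per_mrna) <- rownames(summary) <- NULL
  list(per_snp = per_snp, per_mrna = per_mrna, summary = summary)
}

#' Chromosome-aware test of the trans proportion
#'
#' Under random placement of eQTL over the tested sites, an eQTL whose
#' target gene lies on sequence s is trans with probability
#' `1 - n_sites(s) / n_sites(total)`. Summing these probabilities over the
#' classified eQTL gives expected cis/trans counts; a 1-df goodness-of-fit
#' chi-square compares them with the observed counts. A non-significant
#' result says the observed trans fraction matches what the SNP
#' distribution among chromosomes alone would produce.
#'
#' @param classified output of [classify_cis_trans()] (rows with
#'   classification `"cis"`/`"trans"`).
#' @param site_chroms character vector: the sequence of every tested site
#'   (defines the SNP distribution among chromosomes).
#' @return list: `observed` (cis, trans), `expected`, `statistic`, `p`,
#'   `note` (`"ok"`, `"low_count"` when any expected count < 5, or
#'   `"undefined"` when an expected count is 0).
#' @export
expected_trans_test <- function(classified, site_chroms) {
  cls <- classified$classification
  keep <- cls %in% c("cis", "trans")
  classified <- classified[keep, , drop = FALSE]
  if (nrow(classified) == 0L) stop("no classified eQTL")
  n_total <- length(site_chroms)
  tab <- table(site_chroms)
  p_same <- as.numeric(tab[classified$target_chrom]) / n_total
  p_same[is.na(p_same)] <- 0
  e_cis <- sum(p_same)
  e_trans <- sum(1 - p_same)
  o_cis <- sum(classified$classification == "cis")
  o_trans <- sum(classified$classification == "trans")
  if (e_cis <= 0 || e_trans <= 0) {
    return(list(
      observed = c(cis = o_cis, trans = o_trans),
      expected = c(cis = e_cis, trans = e_trans),
      statistic = NA_real_, p = NA_real_, note = "undefined"
    ))
  }
  stat <- (o_cis - e_cis)^2 / e_cis + (o_trans - e_trans)^2 / e_trans
  list(
    observed = c(cis = o_cis, trans = o_trans),
    expected = c(cis = e_cis, trans = e_trans),
    statistic = stat,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    note = if (min(e_cis, e_trans) < 5) "low_count" else "ok"
  )
}

# bp distance between a point and an interval set on matching sequences:
# 0 inside an interval, else distance to the nearest boundary
.site_gene_distance <- function(chrom, pos, genes) {
  vapply(seq_along(pos), function(i) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(Inf)
    inside <- pos[i] >= g$start & pos[i] <= g$end
    if (any(inside)) return(0)
    min(abs(pos[i] - g$start), abs(pos[i] - g$end))
  }, numeric(1))
}

#' Regulatory-proximity annotation of SNPs
#'
#' Annotates each SNP as genic (inside any gene interval; introns and
#' exons are not distinguished) or intergenic, reporting all overlapping
#' genes, and flags SNPs within `window` bp (inclusive) of a
#' transcription-factor gene or inside one. Distance is to the nearest
#' gene boundary and strand-symmetric.
#'
#' @param sites data.frame with `id`, `chrom`, `pos`.
#' @param genes annotation from [read_gff_genes()] (`is_tf` column used).
#' @param window proximity window in bp, default 5000.
#' @return data.frame: `id`, `chrom`, `pos`, `annotation`
#'   (`"genic"`/`"intergenic"`), `genes` (comma-joined overlapping gene
#'   ids, "" if none), `tf_distance` (bp to nearest TF gene, Inf if none
#'   on the sequence), `near_tf`.
#' @export
annotate_proximity <- function(sites, genes, window = 5000) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L)
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end)
  )
  # sites on sequences absent from the annotation are simply non-genic
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
  )
  hit_genes <- vapply(seq_len(nrow(sites)), function(i) {
    g <- genes$gene_id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    paste(g, collapse = ",")
  }, character(1))
  tf_genes <- genes[genes$is_tf, , drop = FALSE]
  tf_dist <- .site_gene_distance(sites$chrom, sites$pos, tf_genes)
  data.frame(
    id = sites$id, chrom = sites$chrom, pos = sites$pos,
    annotation = ifelse(nzchar(hit_genes), "genic", "intergenic"),
    genes = hit_genes,
    tf_distance = tf_dist,
    near_tf = tf_dist <= window,
    stringsAsFactors = FALSE
  )
}

#' Module-overlap check for eigengene eQTL
#'
#' An eigengene association (eQTL_ME) cannot be cis/trans-classified, but
#' one can ask whether the SNP sits within or near (<= `window` bp) any
#' gene whose mRNA belongs to the associated module. A FALSE flag for all
#' eQTL_ME says module-level associations are not disguised cis effects on
#' a single member mRNA.
#'
#' @param eqtl_me data.frame with `id`, `chrom`, `pos`, `module`.
#' @param es an [expression_set()] supplying gene coordinates and module
#'   membership.
#' @param window proximity window in bp, default 5000.
#' @return the input with added `near_module_gene` flag and
#'   `module_gene_distance`.
#' @export
me_overlap_check <- function(eqtl_me, es, window = 5000) {
  eqtl_me <- as.data.frame(eqtl_me, stringsAsFactors = FALSE)
  dist <- numeric(nrow(eqtl_me))
  for (i in seq_len(nrow(eqtl_me))) {
    members <- es$modules$mrna_id[es$modules$module == eqtl_me$module[i]]
    g <- es$genes[es$genes$gene_id %in% members, , drop = FALSE]
    dist[i] <- .site_gene_distance(eqtl_me$chrom[i], eqtl_me$pos[i], g)
  }
  eqtl_me$module_gene_distance <- dist
  eqtl_me$near_module_gene <- dist <= window
  eqtl_me
}

#' Within- versus among-module eQTL sharing test
#'
#' For every unordered pair of tested mRNAs, the sharing indicator is 1
#' when their significant eQTL SNP sets intersect. A Welch two-sample
#' t-test compares the indicators of within-module pairs against
#' among-module pairs; fewer shared eQTL within than among modules argues
#' against a simple module-wide cis architecture.
#'
#' @param eqtl data.frame of significant single-mRNA associations:
#'   columns `id` (SNP, or containing gene when `unit = "gene"`),
#'   `target` (mRNA).
#' @param modules data.frame `mrna_id`, `module`.
#' @param tested_mrnas character vector of all tested mRNAs (pairs are
#'   formed over these; mRNAs with no eQTL share nothing).
#' @param unit `"snp"` (identical SNP, default) or `"gene"` (the caller
#'   supplies gene-level ids in `id`).
#' @return list: `statistic`, `p`, `mean_within`, `mean_among`,
#'   `n_within`, `n_among`, `note` (`"ok"`, `"degenerate"` when the
#'   indicators have no variance — reported as no difference — or
#'   `"too_few_pairs"`).
#' @export
sharing_test <- function(eqtl, modules, tested_mrnas, unit = c("snp", "gene")) {
  unit <- match.arg(unit)
  tested_mrnas <- sort(unique(tested_mrnas))
  if (length(tested_mrnas) < 2L) stop("need >= 2 tested mRNAs")
  sets <- lapply(tested_mrnas, function(m) unique(eqtl$id[eqtl$target == m]))
  names(sets) <- tested_mrnas
  mod <- modules$module[match(tested_mrnas, modules$mrna_id)]
  if (length(unique(mod[!is.na(mod)])) < 2L) stop("need tested mRNAs in >= 2 modules")
  pr <- utils::combn(seq_along(tested_mrnas), 2)
  share <- vapply(seq_len(ncol(pr)), function(k) {
    length(intersect(sets[[pr[1, k]]], sets[[pr[2, k]]])) > 0
  }, logical(1))
  within <- mod[pr[1, ]] == mod[pr[2, ]]
  x_within <- as.numeric(share[within])
  x_among <- as.numeric(share[!within])
  out <- list(
    statistic = NA_real_, p = NA_real_,
    mean_within = mean(x_within), mean_among = mean(x_among),
    n_within = length(x_within), n_among = length(x_among),
    note = "ok"
  )
  if (length(x_within) < 2L || length(x_among) < 2L) {
    out$note <- "too_few_pairs"
    return(out)
  }
  if (stats::var(x_within) == 0 && stats::var(x_among) == 0) {
    out$note <- "degenerate"
    return(out)
  }
  tt <- stats::t.test(x_within, x_among)
  out$statistic <- unname(tt$statistic)
  out$p <- tt$p.value
  out
}

#' Heterozygosity comparison between SNP sets
#'
#' Compares expected heterozygosity (He = 2p(1-p)) between a focal SNP
#' set (e.g. significant eQTL) and a background set (e.g. all tested
#' sites): means and sds per set, a two-sided Welch t-test, and an
#' optional permutation test drawing |focal|-sized sets from the
#' background.
#'
#' @param focal_he numeric He values of the focal set.
#' @param background_he numeric He values of the background set.
#' @param n_perm permutation draws (0 disables), default 10000.
#' @param seed optional RNG seed for the permutation.
#' @return list: `mean_focal`, `sd_focal`, `mean_background`,
#'   `sd_background`, `diff`, `t_p` (NA with note when |focal| < 2),
#'   `perm_p`, `note`.
#' @export
he_comparison <- function(focal_he, background_he, n_perm = 10000, seed = NULL) {
  if (length(focal_he) < 1L || length(background_he) < 1L) {
    stop("both SNP sets must be non-empty")
  }
  obs <- mean(focal_he) - mean(background_he)
  out <- list(
    mean_focal = mean(focal_he), sd_focal = stats::sd(focal_he),
    mean_background = mean(background_he), sd_background = stats::sd(background_he),
    diff = obs, t_p = NA_real_, perm_p = NA_real_, note = "ok"
  )
  if (length(focal_he) >= 2L && stats::sd(background_he) > 0) {
    out$t_p <- stats::t.test(focal_he, background_he)$p.value
  } else {
    out$note <- "t_test_undefined"
  }
  if (n_perm > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    k <- length(focal_he)
    perm <- replicate(n_perm, mean(sample(background_he, k)) - mean(background_he))
    out$perm_p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  }
  out
}

#' Overlap sets among association catalogs
#'
#' SNP-level and gene-level intersections between every pair of catalogs
#' (e.g. trait SNPs, heart/brain eQTL, heart/brain eQTL_ME), plus the
#' specific check whether any SNP (or its containing gene) is both an
#' eQTL for an mRNA and an eQTL_ME for that mRNA's module.
#'
#' @param catalogs named list of data.frames, each with columns `id`,
#'   `chrom`, `pos`.
#' @param genes gene annotation (for the gene-level mapping), or NULL to
#'   skip gene-level overlap.
#' @param eqtl single-mRNA catalog with `id`, `target` (mRNA), used for
#'   the mRNA/module conflict check (NULL skips it).
#' @param eqtl_me eigengene catalog with `id`, `module` (NULL skips).
#' @param modules data.frame `mrna_id`, `module` (NULL skips).
#' @return list: `snp` (data.frame set_a, set_b, n_a, n_b, n_overlap,
#'   shared ids), `gene` (same at containing-gene level, NULL if no
#'   annotation), `mrna_module_conflicts` (data.frame of SNP-level and
#'   gene-level conflicts between an mRNA's eQTL and its module's
#'   eQTL_ME).
#' @export
overlap_sets <- function(catalogs, genes = NULL, eqtl = NULL, eqtl_me = NULL,
                         modules = NULL) {
  stopifnot(length(catalogs) >= 2L, !is.null(names(catalogs)))
  snp_sets <- lapply(catalogs, function(d) unique(d$id))
  gene_of <- function(d) {
    if (is.null(genes)) return(NULL)
    ann <- annotate_proximity(d, genes, window = 0)
    unique(unlist(strsplit(ann$genes[nzchar(ann$genes)], ",")))
  }
  gene_sets <- if (is.null(genes)) NULL else lapply(catalogs, gene_of)
  pair_tab <- function(sets) {
    nm <- names(sets)
    pr <- utils::combn(seq_along(sets), 2)
    do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
      a <- sets[[pr[1, k]]]
      b <- sets[[pr[2, k]]]
      ov <- intersect(a, b)
      data.frame(
        set_a = nm[pr[1, k]], set_b = nm[pr[2, k]],
        n_a = length(a), n_b = length(b), n_overlap = length(ov),
        shared = paste(ov, collapse = ","), stringsAsFactors = FALSE
      )
    }))
  }
  conflicts <- NULL
  if (!is.null(eqtl) && !is.null(eqtl_me) && !is.null(modules)) {
    mod_of_mrna <- stats::setNames(modules$module, modules$mrna_id)
    rows <- list()
    for (i in seq_len(nrow(eqtl))) {
      m <- mod_of_mrna[eqtl$target[i]]
      if (is.na(m)) next
      me_rows <- eqtl_me[eqtl_me$module == m, , drop = FALSE]
      if (nrow(me_rows) == 0L) next
      snp_hit <- eqtl$id[i] %in% me_rows$id
      gene_hit <- FALSE
      if (!is.null(genes)) {
        g_e <- gene_of(eqtl[i, , drop = FALSE])
        g_m <- gene_of(me_rows)
        gene_hit <- length(intersect(g_e, g_m)) > 0
      }
      if (snp_hit || gene_hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          mrna = eqtl$target[i], module = unname(m), snp = eqtl$id[i],
          snp_level = snp_hit, gene_level = gene_hit, stringsAsFactors = FALSE
        )
      }
    }
    conflicts <- if (length(rows)) {
      unique(do.call(rbind, rows))
    } else {
      data.frame(
        mrna = character(), module = character(), snp = character(),
        snp_level = logical(), gene_level = logical(), stringsAsFactors = FALSE
      )
    }
  }
  list(
    snp = pair_tab(snp_sets),
    gene = if (is.null(gene_sets)) NULL else pair_tab(gene_sets),
    mrna_module_conflicts = conflicts
  )
}

#' Architecture summary of an eQTL catalog
#'
#' Assembles the recomputable headline numbers for one tissue's pruned
#' catalogs: cis/trans counts and fractions, hotspot counts and per-SNP
#' target statistics, the chromosome-aware trans test, and the
#' heterozygosity comparison against all tested sites.
#'
#' @param classified output of [classify_cis_trans()] on the single-mRNA
#'   catalog (one row per significant association).
#' @param site_chroms chromosomes of all tested sites (trans null).
#' @param freq per-site frequency table from [estimate_allele_freq_em()]
#'   covering all tested sites (`id`, `he`).
#' @param tissue tissue label.
#' @param n_perm permutation draws for the He comparison.
#' @param seed RNG seed for the permutation.
#' @return list with elements `tissue`, `counts` (cis/trans/total and
#'   fractions), `hotspots` (from [find_hotspots()]), `trans_test`,
#'   `he` (from [he_comparison()]).
#' @export
architecture_summary <- function(classified, site_chroms, freq, tissue = "tissue",
                                 n_perm = 10000, seed = NULL) {
  cls <- classified$classification
  n_cis <- sum(cls == "cis")
  n_trans <- sum(cls == "trans")
  hs <- find_hotspots(cbind(classified, tissue = tissue))
  tt <- expected_trans_test(classified, site_chroms)
  focal <- freq$he[freq$id %in% classified$id]
  he <- he_comparison(focal, freq$he, n_perm = n_perm, seed = seed)
  list(
    tissue = tissue,
    counts = list(
      cis = n_cis, trans = n_trans, classified = n_cis + n_trans,
      cis_fraction = n_cis / max(1, n_cis + n_trans),
      trans_fraction = n_trans / max(1, n_cis + n_trans)
    ),
    hotspots = hs,
    trans_test = tt,
    he = he
  )
}
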