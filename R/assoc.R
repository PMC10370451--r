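#' Score test of a dosage against a phenotype with covariates
#'
#' Genotype-likelihood association in the style of the ANGSD score test:
#' the null model `y ~ X` (X must include an intercept) is fit by least
#' squares; with residuals `r` and `sigma2 = RSS / n`, the expected dosage
#' `d` is residualized against the covariate space (`d_tilde`), and
#'
#'   `U = d_tilde' r / sigma2`,  `V = d_tilde' d_tilde / sigma2`,
#'   `T = U^2 / V`,
#'
#' with the p-value from the upper tail of chi-squared on 1 df. With
#' certain genotypes T equals the classical score statistic for adding the
#' genotype to the null regression.
#'
#' @param d numeric dosage vector (expected alternate-allele copies,
#'   in `[0, 2]`).
#' @param y numeric phenotype; missing values drop the individual.
#' @param X covariate matrix including an intercept column; `NULL` means
#'   intercept only.
#' @return list: `statistic` (T), `p`, `n` (complete cases used), `status`
#'   (`"tested"`, `"n_too_small"` or `"untestable"` for a dosage collinear
#'   with the covariates, e.g. monomorphic posteriors).
#' @export
score_test <- function(d, y, X = NULL) {
  res <- score_test_matrix(matrix(d, ncol = 1), y, X)
  list(statistic = res$statistic[1], p = res$p[1], n = res$n[1], status = res$status[1])
}

#' Score tests of many dosage vectors against one phenotype
#'
#' Vectorized form of [score_test()]: the null fit and projection are done
#' once and applied to every column of `D`.
#'
#' @param D numeric matrix of dosages, individuals x sites.
#' @param y numeric phenotype vector.
#' @param X covariate matrix including intercept (`NULL` = intercept only).
#' @return data.frame with one row per column of `D`: `statistic`, `p`,
#'   `n`, `status`.
#' @export
score_test_matrix <- function(D, y, X = NULL) {
  D <- as.matrix(D)
  n_all <- length(y)
  if (nrow(D) != n_all) stop("dosages and phenotype must cover the same individuals")
  if (is.null(X)) X <- matrix(1, n_all, 1)
  X <- as.matrix(X)
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  D <- D[ok, , drop = FALSE]
  n <- length(y)
  m <- ncol(D)
  out <- data.frame(
    statistic = rep(NA_real_, m), p = NA_real_, n = n,
    status = rep("tested", m), stringsAsFactors = FALSE
  )
  qrX <- qr(X)
  if (n < 2L + qrX$rank) {
    out$status <- "n_too_small"
    return(out)
  }
  r <- qr.resid(qrX, y)
  sigma2 <- sum(r^2) / n
  if (sigma2 <= 0) {
    out$status <- "untestable"
    return(out)
  }
  Dt <- qr.resid(qrX, D)
  v0 <- colSums(Dt^2)
  scale0 <- colSums(D^2) + 1
  degen <- v0 <= 1e-10 * scale0
  U <- colSums(Dt * r) / sigma2
  V <- v0 / sigma2
  stat <- U^2 / V
  out$statistic <- ifelse(degen, NA_real_, stat)
  out$p <- ifelse(degen, NA_real_, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  out$status[degen] <- "untestable"
  out
}

#' ANGSD-style per-site testability filters
#'
#' Reproduces the default association filters of genotype-likelihood
#' association tools. `minCount`: the expected minor-allele count,
#' `min(sum d, 2n - sum d)`, must reach `min_count`. `minHigh`: at least
#' `min_high` individuals must carry a genotype posterior >= `high_thresh`
#' in each of the two most populous high-credibility genotype classes.
#' Both must pass for a site to be tested.
#'
#' @param posterior `n x 3` genotype-posterior matrix for one site, or an
#'   `n x m x 3` array for many sites.
#' @param dosage expected dosages (vector for one site, `n x m` matrix).
#' @param min_high,min_count filter thresholds (defaults 10 and 10).
#' @param high_thresh posterior credibility threshold (default 0.9).
#' @return character vector of statuses: `"tested"`, `"minCount_fail"` or
#'   `"minHigh_fail"`.
#' @export
apply_site_filters <- function(posterior, dosage, min_high = 10, min_count = 10,
                               high_thresh = 0.9) {
  if (length(dim(posterior)) == 2L) {
    posterior <- array(posterior, dim = c(nrow(posterior), 1L, 3L))
    dosage <- matrix(dosage, ncol = 1)
  }
  n <- dim(posterior)[1]
  m <- dim(posterior)[2]
  alt_sum <- colSums(dosage)
  minor <- pmin(alt_sum, 2 * n - alt_sum)
  highs <- cbind(
    colSums(matrix(posterior[, , 1], n, m) >= high_thresh),
    colSums(matrix(posterior[, , 2], n, m) >= high_thresh),
    colSums(matrix(posterior[, , 3], n, m) >= high_thresh)
  )
  second <- apply(highs, 1, function(v) sort(v, decreasing = TRUE)[2])
  first <- apply(highs, 1, max)
  status <- rep("tested", m)
  status[first < min_high | second < min_high] <- "minHigh_fail"
  status[minor < min_count] <- "minCount_fail"
  status
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, applied within one phenotype's
#' set of tested sites. Thin wrapper around `stats::p.adjust(method =
#' "BH")` with input validation; adjusted values are always >= the raw
#' p-values and capped at 1.
#'
#' @param p numeric vector of raw p-values in `(0, 1]` (NA passed through).
#' @return numeric vector of BH-adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Prune significant hits to independent SNPs (> window bp apart)
#'
#' Greedy pruning by significance: hits are visited in order of ascending
#' raw p (ties broken by chromosome then position) and accepted unless an
#' already-accepted hit on the same sequence lies within `window` bp.
#' Within one phenotype the retained set therefore contains no two sites
#' <= `window` bp apart, and every retained hit is the most significant
#' among those it displaced. The result is independent of input order.
#'
#' @param hits data.frame with columns `chrom`, `pos`, `p` (raw p-value);
#'   extra columns are carried through.
#' @param window exclusion distance in bp (default 500; hits exactly
#'   `window` apart are considered linked and pruned).
#' @return data.frame of retained hits with an added `pruned_n` column:
#'   the number of displaced neighbors attributed to each retained hit.
#' @export
prune_hits <- function(hits, window = 500) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    hits$pruned_n <- integer(0)
    return(hits)
  }
  ord <- order(hits$p, hits$chrom, hits$pos)
  kept_idx <- integer(0)
  pruned_by <- integer(0)
  for (i in ord) {
    blocker <- NA_integer_
    for (kk in kept_idx) {
      if (hits$chrom[kk] == hits$chrom[i] &&
        abs(hits$pos[kk] - hits$pos[i]) <= window) {
        blocker <- kk
        break
      }
    }
    if (is.na(blocker)) {
      kept_idx <- c(kept_idx, i)
    } else {
      pruned_by <- c(pruned_by, blocker)
    }
  }
  out <- hits[sort(kept_idx), , drop = FALSE]
  out$pruned_n <- vapply(
    sort(kept_idx),
    function(kk) sum(pruned_by == kk), integer(1)
  )
  rownames(out) <- NULL
  out
}

#' Association-suite configuration
#'
#' Named thresholds of the pipeline, with the defaults used throughout:
#' 0.05 MAF, 500 bp pruning window, 5 kb proximity window, FDR 0.05,
#' minHigh 10, minCount 10, posterior credibility 0.9.
#'
#' @param fdr FDR significance level on BH-adjusted p.
#' @param prune_window pruning window in bp.
#' @param proximity_window regulatory-proximity window in bp.
#' @param maf_min site minor-allele-frequency filter.
#' @param site_miss_max,ind_miss_max missingness filters.
#' @param min_high,min_count,high_thresh testability filters.
#' @param top_k top-k mRNAs per module entered as single-mRNA phenotypes.
#' @param min_n minimum complete cases for a phenotype to be tested.
#' @param sensitivity_floor if TRUE, the significant set is additionally
#'   restricted to raw p above `p_floor`, a guard against likelihood-ratio
#'   p-value underflow in tiny samples.
#' @param p_floor lower raw-p bound used by the sensitivity subset.
#' @return list of class `assoc_config`.
#' @export
assoc_config <- function(fdr = 0.05, prune_window = 500, proximity_window = 5000,
                         maf_min = 0.05, site_miss_max = 0.10, ind_miss_max = 0.05,
                         min_high = 10, min_count = 10, high_thresh = 0.9,
                         top_k = 10, min_n = 10,
                         sensitivity_floor = FALSE, p_floor = 1.1102e-16) {
  structure(
    list(
      fdr = fdr, prune_window = prune_window,
      proximity_window = proximity_window,
      maf_min = maf_min, site_miss_max = site_miss_max,
      ind_miss_max = ind_miss_max,
      min_high = min_high, min_count = min_count, high_thresh = high_thresh,
      top_k = top_k, min_n = min_n,
      sensitivity_floor = sensitivity_floor, p_floor = p_floor
    ),
    class = "assoc_config"
  )
}

#' Run the full association suite
#'
#' Tests every site of a [gl_set()] against three phenotype classes:
#' physiological traits (covariates: acclimation temperature and
#' acclimation order), top-k single-mRNA expression and module eigengenes
#' (covariate: acclimation temperature). Per phenotype, testability
#' filters are applied on the complete-case cohort, score tests run on
#' the expected dosages, p-values are BH-adjusted within the phenotype's
#' tested set, and significant hits (adjusted p < `config$fdr`) are pruned
#' to independent SNPs.
#'
#' @param gl a [gl_set()] (already site-filtered; see [filter_sites()]).
#' @param pheno phenotype table as from [read_phenotype_table()]:
#'   `individual`, `temperature`, `acclimation_order`, trait columns.
#' @param es an [expression_set()], or NULL to test traits only.
#' @param config an [assoc_config()].
#' @param summaries optional precomputed [module_summaries()] (computed
#'   from `es` when NULL).
#' @return list of class `assoc_suite`: `results` (long data.frame over
#'   phenotype x site: `phenotype`, `class`, `id`, `chrom`, `pos`, `n`,
#'   `statistic`, `p`, `p_adj`, `status`, `significant`), `pruned`
#'   (significant independent hits with `pruned_n`), `skipped`
#'   (phenotypes not tested, with reasons), `freq` (per-site allele
#'   frequencies), `summaries`, `config`.
#' @export
run_association_suite <- function(gl, pheno, es = NULL, config = assoc_config(),
                                  summaries = NULL) {
  freq <- estimate_allele_freq_em(gl)
  gp <- genotype_posteriors(gl, freq$p)
  traits <- attr(pheno, "traits")
  if (is.null(traits)) {
    traits <- setdiff(names(pheno), c("individual", "temperature", "acclimation_order"))
  }

  phenotype_list <- list()
  for (tr in traits) {
    y <- stats::setNames(pheno[[tr]], pheno$individual)
    phenotype_list[[tr]] <- list(
      y = y, class = "trait",
      covars = c("temperature", "acclimation_order")
    )
  }
  if (!is.null(es)) {
    if (is.null(summaries)) summaries <- module_summaries(es, k = config$top_k)
    for (mrna in unique(summaries$top$mrna_id)) {
      y <- stats::setNames(es$expr[, mrna], rownames(es$expr))
      phenotype_list[[mrna]] <- list(
        y = y, class = "single_mRNA", covars = "temperature"
      )
    }
    for (m in colnames(summaries$me)) {
      y <- stats::setNames(summaries$me[, m], rownames(summaries$me))
      phenotype_list[[m]] <- list(
        y = y, class = "module_ME", covars = "temperature"
      )
    }
  }

  cov_tab <- pheno[, c("individual", "temperature", "acclimation_order"), drop = FALSE]
  results <- vector("list", length(phenotype_list))
  skipped <- list()
  for (k in seq_along(phenotype_list)) {
    ph <- names(phenotype_list)[k]
    spec <- phenotype_list[[k]]
    ids <- intersect(names(spec$y)[!is.na(spec$y)], gl$individuals)
    cv <- cov_tab[match(ids, cov_tab$individual), , drop = FALSE]
    keep <- !is.na(cv$temperature) &
      (!("acclimation_order" %in% spec$covars) | !is.na(cv$acclimation_order))
    ids <- ids[keep]
    n <- length(ids)
    X <- cbind(intercept = 1, temperature = as.numeric(
      cov_tab$temperature[match(ids, cov_tab$individual)]
    ))
    if ("acclimation_order" %in% spec$covars) {
      ord <- cov_tab$acclimation_order[match(ids, cov_tab$individual)]
      X <- cbind(X, order = as.numeric(factor(ord)) - 1)
    }
    if (n < max(config$min_n, 2L + qr(X)$rank)) {
      skipped[[ph]] <- sprintf("only %d complete cases", n)
      next
    }
    sub_idx <- match(ids, gl$individuals)
    post <- gp$posterior[sub_idx, , , drop = FALSE]
    dose <- gp$dosage[sub_idx, , drop = FALSE]
    fstat <- apply_site_filters(post, dose,
      min_high = config$min_high, min_count = config$min_count,
      high_thresh = config$high_thresh
    )
    res <- data.frame(
      phenotype = ph, class = spec$class,
      id = gl$sites$id, chrom = gl$sites$chrom, pos = gl$sites$pos,
      n = n, statistic = NA_real_, p = NA_real_, p_adj = NA_real_,
      status = fstat, significant = FALSE, stringsAsFactors = FALSE
    )
    testable <- fstat == "tested"
    if (any(testable)) {
      st <- score_test_matrix(dose[, testable, drop = FALSE], spec$y[ids], X)
      res$statistic[testable] <- st$statistic
      res$p[testable] <- st$p
      res$status[testable] <- st$status
      tested <- testable
      tested[testable] <- st$status == "tested"
      res$p_adj[tested] <- bh_adjust(res$p[tested])
      sig <- tested & !is.na(res$p_adj) & res$p_adj < config$fdr
      if (config$sensitivity_floor) sig <- sig & res$p > config$p_floor
      res$significant <- sig
    }
    results[[k]] <- res
  }
  results <- do.call(rbind, c(results, list(make.row.names = FALSE)))

  pruned <- NULL
  if (!is.null(results) && any(results$significant)) {
    sig <- results[results$significant, , drop = FALSE]
    pruned <- do.call(rbind, lapply(split(sig, sig$phenotype), function(h) {
      prune_hits(h, window = config$prune_window)
    }))
    rownames(pruned) <- NULL
  } else {
    pruned <- results[0, , drop = FALSE]
    pruned$pruned_n <- integer(0)
  }

  structure(
    list(
      results = results, pruned = pruned,
      skipped = skipped, freq = freq,
      summaries = if (is.null(es)) NULL else summaries,
      config = config
    ),
    class = "assoc_suite"
  )
}

#' @export
print.assoc_suite <- function(x, ...) {
  cat(sprintf(
    "assoc_suite: %d phenotype(s), %d sites, %d significant, %d pruned-independent\n",
    length(unique(x$results$phenotype)),
    length(unique(x$results$id)),
    sum(x$results$significant),
    nrow(x$pruned)
  ))
  if (length(x$skipped)) {
    cat("skipped:", paste(names(x$skipped), unlist(x$skipped), sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}
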