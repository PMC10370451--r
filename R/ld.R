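#' Pairwise r2 from genotype likelihoods via two-locus haplotype EM
#'
#' Estimates the four two-locus haplotype frequencies (AB, Ab, aB, ab,
#' where A/B denote the alternate allele at the first/second site) by EM
#' over the genotype-likelihood data of the same individuals at two sites,
#' assuming random union of haplotypes. Each EM iteration computes, per
#' individual, the posterior over ordered haplotype pairs given the current
#' frequencies and both sites' likelihoods, and resets the frequencies to
#' the expected haplotype counts over 2n chromosomes. From the fitted
#' frequencies, `D = f_AB - p_A p_B` and `r2 = D^2 / (p_A q_A p_B q_B)`.
#' At infinite genotype certainty this reduces to the classic
#' genotype-based haplotype EM on hard calls.
#'
#' @param lik_a,lik_b `n x 3` linear-scale likelihood matrices for the two
#'   sites (same individuals, same order), or a [gl_set()] plus two site
#'   indices via [ld_pair()].
#' @param tol convergence tolerance on the haplotype frequencies.
#' @param max_iter maximum EM iterations.
#' @return list: `hap_freq` (named numeric, AB/Ab/aB/ab), `p_a`, `p_b`
#'   (alternate-allele frequencies), `D`, `r2`, `n_iter`, `converged`,
#'   `loglik`.
#' @export
pairwise_r2_em <- function(lik_a, lik_b, tol = 1e-6, max_iter = 500) {
  la <- .norm_lik3(lik_a)
  lb <- .norm_lik3(lik_b)
  if (nrow(la) != nrow(lb)) stop("both sites need the same individuals")
  n <- nrow(la)

  pa <- estimate_allele_freq_em(la)$p
  pb <- estimate_allele_freq_em(lb)$p
  if (min(pa, 1 - pa) < 1e-8 || min(pb, 1 - pb) < 1e-8) {
    stop("r2 undefined at a monomorphic site (allele frequency 0 or 1)")
  }

  # haplotypes: columns 1..4 = AB, Ab, aB, ab (alt allele coded as A/B)
  hap_a <- c(1L, 1L, 0L, 0L) # alt copies contributed at site a
  hap_b <- c(1L, 0L, 1L, 0L)
  # linkage-equilibrium start from the marginal EM frequencies
  f <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))

  # per ordered haplotype pair (h1, h2): implied genotypes and data weight
  pair_h1 <- rep(1:4, times = 4)
  pair_h2 <- rep(1:4, each = 4)
  ga <- hap_a[pair_h1] + hap_a[pair_h2] # 0/1/2 at site a
  gb <- hap_b[pair_h1] + hap_b[pair_h2]
  w <- la[, ga + 1L, drop = FALSE] * lb[, gb + 1L, drop = FALSE] # n x 16

  n_iter <- 0L
  converged <- FALSE
  loglik <- NA_real_
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    prior <- f[pair_h1] * f[pair_h2]
    post <- sweep(w, 2, prior, `*`)
    tot <- rowSums(post)
    loglik <- sum(log(pmax(tot, 1e-300)))
    post <- post / pmax(tot, 1e-300)
    cnt <- numeric(4)
    for (h in 1:4) {
      cnt[h] <- sum(post[, pair_h1 == h, drop = FALSE]) +
        sum(post[, pair_h2 == h, drop = FALSE])
    }
    f_new <- cnt / (2 * n)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }

  p_a <- f[1] + f[2]
  p_b <- f[1] + f[3]
  D <- f[1] - p_a * p_b
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  r2 <- if (denom > 0) min(D^2 / denom, 1) else NA_real_
  list(
    hap_freq = stats::setNames(f, c("AB", "Ab", "aB", "ab")),
    p_a = p_a, p_b = p_b, D = D, r2 = r2,
    n_iter = n_iter, converged = converged, loglik = loglik
  )
}

#' @rdname pairwise_r2_em
#' @param gl a [gl_set()]
#' @param i,j site indices or ids
#' @param ... passed to [pairwise_r2_em()]
#' @export
ld_pair <- function(gl, i, j, ...) {
  pairwise_r2_em(site_lik(gl, i), site_lik(gl, j), ...)
}

.norm_lik3 <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("likelihood matrix must have 3 columns")
  if (any(!is.finite(x)) || any(x < 0)) stop("likelihoods must be finite and non-negative")
  s <- rowSums(x)
  if (any(s <= 0)) stop("each likelihood triplet needs positive mass")
  x / s
}

#' LD decay: mean r2 by distance bin
#'
#' Computes [pairwise_r2_em()] for all same-sequence site pairs separated
#' by at most `max_dist` bp and averages r2 in distance bins of width
#' `bin_width`. Pairs on different sequences have no defined distance and
#' are excluded; bins containing no pair are reported with `n_pairs = 0`
#' and `mean_r2 = NA` rather than zero.
#'
#' @param gl a [gl_set()].
#' @param max_dist maximum pair distance in bp.
#' @param bin_width bin width in bp.
#' @param tol,max_iter passed to [pairwise_r2_em()].
#' @return list: `pairs` (per-pair data.frame: site ids, chrom, distance,
#'   r2) and `bins` (data.frame: bin_start, bin_end, n_pairs, mean_r2).
#' @export
ld_decay <- function(gl, max_dist = 1000, bin_width = 100, tol = 1e-6,
                     max_iter = 500) {
  s <- gl$sites
  ord <- order(s$chrom, s$pos)
  pairs <- list()
  k <- 0L
  for (a in seq_along(ord)) {
    ia <- ord[a]
    b <- a + 1L
    while (b <= length(ord)) {
      ib <- ord[b]
      if (s$chrom[ib] != s$chrom[ia]) break
      dd <- s$pos[ib] - s$pos[ia]
      if (dd > max_dist) break
      r2 <- tryCatch(
        pairwise_r2_em(site_lik(gl, ia), site_lik(gl, ib),
          tol = tol, max_iter = max_iter
        )$r2,
        error = function(e) NA_real_
      )
      k <- k + 1L
      pairs[[k]] <- data.frame(
        id_a = s$id[ia], id_b = s$id[ib], chrom = s$chrom[ia],
        distance = dd, r2 = r2, stringsAsFactors = FALSE
      )
      b <- b + 1L
    }
  }
  pair_df <- if (k > 0L) {
    do.call(rbind, pairs)
  } else {
    data.frame(
      id_a = character(), id_b = character(), chrom = character(),
      distance = numeric(), r2 = numeric(), stringsAsFactors = FALSE
    )
  }
  breaks <- seq(0, max_dist, by = bin_width)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  bins <- data.frame(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1]
  )
  bins$n_pairs <- 0L
  bins$mean_r2 <- NA_real_
  if (nrow(pair_df) > 0L) {
    idx <- findInterval(pair_df$distance, breaks, rightmost.closed = TRUE,
      left.open = TRUE
    )
    idx[pair_df$distance == 0] <- 1L
    for (bi in seq_len(nrow(bins))) {
      sel <- idx == bi & !is.na(pair_df$r2)
      bins$n_pairs[bi] <- sum(idx == bi)
      if (any(sel)) bins$mean_r2[bi] <- mean(pair_df$r2[sel])
    }
  }
  list(pairs = pair_df, bins = bins)
}
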