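#' Expected heterozygosity
#'
#' He = 2 p (1 - p) at allele frequency p: the probability that a random
#' diploid individual is heterozygous under Hardy-Weinberg equilibrium.
#' Symmetric in p and 1 - p with maximum 0.5 at p = 0.5.
#'
#' @param p numeric vector of allele frequencies in `[0, 1]`.
#' @return numeric vector of He values in `[0, 0.5]`.
#' @export
heterozygosity <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("allele frequency must lie in [0, 1]")
  }
  2 * p * (1 - p)
}

#' Maximum-likelihood allele frequencies from genotype likelihoods
#'
#' EM estimate of the alternate-allele frequency at every site of a
#' [gl_set()], maximizing the marginal likelihood
#' sum_i log sum_g L_i(g) HWE(g; p) under a Hardy-Weinberg prior. The
#' E-step computes per-individual genotype posteriors at the current p; the
#' M-step sets p to half the mean expected alternate dosage. Missing
#' individuals (flat likelihoods) contribute nothing to the likelihood and
#' leave the fixed point at the informative-individual estimate.
#'
#' @param gl a [gl_set()], or a single-site `n x 3` likelihood matrix.
#' @param tol convergence tolerance on `|delta p|` per site.
#' @param max_iter maximum EM iterations.
#' @param trace if TRUE, attach the per-iteration log-likelihood matrix
#'   (iterations x sites) as attribute `"loglik_trace"` for monotonicity
#'   checks.
#' @return data.frame with one row per site: `id`, `chrom`, `pos`, `p`,
#'   `he` (= 2p(1-p)), `n_eff` (non-missing individuals), `n_iter`,
#'   `converged`.
#' @export
estimate_allele_freq_em <- function(gl, tol = 1e-6, max_iter = 200, trace = FALSE) {
  gl <- .as_gl(gl)
  l0 <- matrix(gl$lik[, , 1], nrow = n_individuals(gl))
  l1 <- matrix(gl$lik[, , 2], nrow = n_individuals(gl))
  l2 <- matrix(gl$lik[, , 3], nrow = n_individuals(gl))
  n <- nrow(l0)
  m <- ncol(l0)
  miss <- gl_missing(gl)
  n_eff <- n - colSums(miss)
  if (any(n_eff == 0)) {
    stop(
      "allele frequency undefined: all individuals missing at site(s) ",
      paste(utils::head(gl$sites$id[n_eff == 0], 3), collapse = ", ")
    )
  }

  p <- rep(0.25, m)
  n_iter <- integer(m)
  active <- rep(TRUE, m)
  ll_trace <- if (trace) vector("list", max_iter) else NULL
  it <- 0L
  while (any(active) && it < max_iter) {
    it <- it + 1L
    pa <- p
    w0 <- sweep(l0, 2, (1 - pa)^2, `*`)
    w1 <- sweep(l1, 2, 2 * pa * (1 - pa), `*`)
    w2 <- sweep(l2, 2, pa^2, `*`)
    tot <- w0 + w1 + w2
    if (trace) ll_trace[[it]] <- colSums(log(pmax(tot, 1e-300)))
    dose <- (w1 + 2 * w2) / pmax(tot, 1e-300)
    p_new <- colSums(dose) / (2 * n)
    moved <- abs(p_new - p) >= tol
    n_iter[active & moved] <- it
    active <- active & moved
    p <- p_new
  }
  out <- data.frame(
    id = gl$sites$id, chrom = gl$sites$chrom, pos = gl$sites$pos,
    p = p, he = 2 * p * (1 - p), n_eff = n_eff,
    n_iter = pmax(n_iter, 1L), converged = !active,
    stringsAsFactors = FALSE
  )
  if (trace) {
    attr(out, "loglik_trace") <- do.call(rbind, ll_trace[seq_len(it)])
  }
  out
}

#' HWE genotype posteriors and expected dosages
#'
#' Combines per-individual genotype likelihoods with a Hardy-Weinberg prior
#' at the supplied allele frequency. A missing individual (flat likelihood)
#' receives the prior itself. The expected dosage is
#' `d = P(g=1) + 2 P(g=2)`, always in `[0, 2]`.
#'
#' @param gl a [gl_set()], or a single-site `n x 3` likelihood matrix.
#' @param p numeric vector of alternate-allele frequencies, one per site
#'   (recycled if length 1).
#' @return list with `posterior` (`n x n_sites x 3` array) and `dosage`
#'   (`n x n_sites` matrix, individuals in rows).
#' @export
genotype_posteriors <- function(gl, p) {
  gl <- .as_gl(gl)
  m <- n_sites(gl)
  n <- n_individuals(gl)
  if (length(p) == 1L) p <- rep(p, m)
  if (length(p) != m) stop("need one allele frequency per site")
  if (any(p < 0 | p > 1)) stop("allele frequency must lie in [0, 1]")
  w0 <- sweep(matrix(gl$lik[, , 1], n), 2, (1 - p)^2, `*`)
  w1 <- sweep(matrix(gl$lik[, , 2], n), 2, 2 * p * (1 - p), `*`)
  w2 <- sweep(matrix(gl$lik[, , 3], n), 2, p^2, `*`)
  tot <- w0 + w1 + w2
  # degenerate prior (p = 0 or 1) with no overlapping likelihood support:
  # fall back to the prior itself
  bad <- tot <= 0
  if (any(bad)) {
    pri0 <- matrix(rep((1 - p)^2, each = n), n)
    pri1 <- matrix(rep(2 * p * (1 - p), each = n), n)
    pri2 <- matrix(rep(p^2, each = n), n)
    w0[bad] <- pri0[bad]
    w1[bad] <- pri1[bad]
    w2[bad] <- pri2[bad]
    tot[bad] <- 1
  }
  post <- array(c(w0 / tot, w1 / tot, w2 / tot), dim = c(n, m, 3L),
    dimnames = list(gl$individuals, gl$sites$id, c("g0", "g1", "g2"))
  )
  dosage <- post[, , 2, drop = FALSE][, , 1] + 2 * post[, , 3, drop = FALSE][, , 1]
  dosage <- matrix(dosage, n, m, dimnames = list(gl$individuals, gl$sites$id))
  list(posterior = post, dosage = dosage)
}

# accept a bare n x 3 matrix as a one-site gl_set
.as_gl <- function(x) {
  if (inherits(x, "gl_set")) return(x)
  if (is.matrix(x) && ncol(x) == 3L) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(x)))
    return(gl_set(
      sites = data.frame(
        id = "site_1", chrom = "site", pos = 1L, ref = "A", alt = "C",
        stringsAsFactors = FALSE
      ),
      lik = array(x, dim = c(nrow(x), 1L, 3L)),
      individuals = ids
    ))
  }
  stop("expected a gl_set or an n x 3 likelihood matrix")
}
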