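#' Genotype-likelihood container
#'
#' A `gl_set` holds per-site, per-individual genotype likelihoods for a set
#' of biallelic SNPs, the exchange currency of low-coverage (lcWGS)
#' pipelines. Likelihoods are stored on the linear scale, normalized so the
#' three genotype values (0, 1, 2 copies of the alternate allele) sum to one
#' for every individual at every site. An individual with no reads at a site
#' carries a flat triplet (1/3, 1/3, 1/3) and is treated as missing there.
#'
#' @param sites data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`. `(chrom, pos)` must be unique, `pos >= 1`, `ref != alt`.
#' @param lik numeric array of dimension `n_individuals x n_sites x 3`,
#'   non-negative, with no all-zero triplet.
#' @param individuals character vector of unique individual ids.
#' @return An object of class `gl_set` with elements `sites`, `lik`,
#'   `individuals`.
#' @export
gl_set <- function(sites, lik, individuals) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns: ", paste(need, collapse = ", "))
  }
  if (any(sites$pos < 1)) stop("site positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt allele must differ")
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) stop("(chrom, pos) must be unique across sites")
  if (anyDuplicated(individuals)) stop("individual ids must be unique")
  lik <- as.array(lik)
  if (length(dim(lik)) != 3L || dim(lik)[3] != 3L) {
    stop("lik must be an n_individuals x n_sites x 3 array")
  }
  if (dim(lik)[1] != length(individuals)) {
    stop("lik rows must match number of individuals")
  }
  if (dim(lik)[2] != nrow(sites)) stop("lik columns must match number of sites")
  if (any(!is.finite(lik)) || any(lik < 0)) {
    stop("likelihoods must be finite and non-negative")
  }
  tot <- lik[, , 1] + lik[, , 2] + lik[, , 3]
  if (any(tot <= 0)) stop("each genotype-likelihood triplet needs positive mass")
  for (g in 1:3) lik[, , g] <- lik[, , g] / tot
  structure(
    list(sites = sites, lik = lik, individuals = as.character(individuals)),
    class = "gl_set"
  )
}

#' @export
print.gl_set <- function(x, ...) {
  cat(sprintf(
    "gl_set: %d sites x %d individuals (%.1f%% missing triplets)\n",
    n_sites(x), n_individuals(x), 100 * mean(gl_missing(x))
  ))
  invisible(x)
}

#' Number of sites / individuals in a gl_set
#' @param gl a [gl_set()]
#' @return integer count.
#' @export
n_sites <- function(gl) nrow(gl$sites)

#' @rdname n_sites
#' @export
n_individuals <- function(gl) length(gl$individuals)

#' Per-individual likelihood matrix for one site
#'
#' @param gl a [gl_set()]
#' @param i site index or site id.
#' @return `n_individuals x 3` matrix of normalized linear-scale likelihoods.
#' @export
site_lik <- function(gl, i) {
  if (is.character(i)) i <- match(i, gl$sites$id)
  if (is.na(i) || i < 1 || i > n_sites(gl)) stop("site not found")
  m <- gl$lik[, i, , drop = TRUE]
  m <- matrix(m, ncol = 3, dimnames = list(gl$individuals, c("g0", "g1", "g2")))
  m
}

#' Missingness mask of a gl_set
#'
#' An individual is missing at a site when its three genotype likelihoods
#' are equal (uninformative), the convention used for zero-read individuals.
#'
#' @param gl a [gl_set()]
#' @param tol numeric comparison tolerance.
#' @return logical `n_individuals x n_sites` matrix, TRUE where missing.
#' @export
gl_missing <- function(gl, tol = 1e-9) {
  n <- n_individuals(gl)
  m <- n_sites(gl)
  l1 <- matrix(gl$lik[, , 1], n, m)
  l2 <- matrix(gl$lik[, , 2], n, m)
  l3 <- matrix(gl$lik[, , 3], n, m)
  abs(l1 - l2) < tol & abs(l2 - l3) < tol
}

#' Subset a gl_set
#'
#' @param gl a [gl_set()]
#' @param sites logical/integer index over sites (default all).
#' @param individuals logical/integer/character index over individuals.
#' @return a new [gl_set()].
#' @export
gl_subset <- function(gl, sites = NULL, individuals = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(gl)) else seq_len(n_sites(gl))[sites]
  ii <- seq_len(n_individuals(gl))
  if (!is.null(individuals)) {
    ii <- if (is.character(individuals)) {
      match(individuals, gl$individuals)
    } else {
      ii[individuals]
    }
    if (anyNA(ii)) stop("unknown individual id in subset")
  }
  gl_set(
    sites = gl$sites[si, , drop = FALSE],
    lik = gl$lik[ii, si, , drop = FALSE],
    individuals = gl$individuals[ii]
  )
}

# allele letters <-> beagle integer codes (ANGSD convention 0=A,1=C,2=G,3=T)
.allele_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.encode_allele <- function(a) {
  out <- .allele_codes[toupper(a)]
  if (anyNA(out)) stop("alleles must be A/C/G/T")
  unname(out)
}

.decode_allele <- function(x) {
  x <- as.character(x)
  letters4 <- names(.allele_codes)
  out <- ifelse(x %in% c("0", "1", "2", "3"),
    letters4[as.integer(x) + 1L],
    toupper(x)
  )
  if (!all(out %in% letters4)) stop("unrecognized allele code: ", paste(unique(x), collapse = ","))
  out
}

#' Read a beagle genotype-likelihood file
#'
#' Parses the text exchange format used by ANGSD and friends: a header line
#' `marker allele1 allele2 Ind0 Ind0 Ind0 ...` followed by one row per site
#' with three genotype likelihoods per individual. The marker name is
#' `<chrom>_<pos>`; the chromosome name may itself contain underscores, so
#' the position is taken after the last underscore.
#'
#' @param path file path (plain text, tab- or space-separated).
#' @return a [gl_set()]. Likelihood triplets are renormalized to sum to one.
#' @export
read_beagle_gl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("beagle file needs a header and at least one site: ", path)
  split_row <- function(x) strsplit(trimws(x), "[\t ]+")[[1]]
  header <- split_row(lines[1])
  n_field <- length(header)
  if (n_field < 6L || (n_field - 3L) %% 3L != 0L) {
    stop("malformed beagle header: expected 3 + 3*n_individuals columns")
  }
  n_ind <- (n_field - 3L) %/% 3L
  ind_ids <- header[seq(4L, n_field, by = 3L)]
  if (anyDuplicated(ind_ids)) ind_ids <- make.unique(ind_ids)

  n_site <- length(lines) - 1L
  lik <- array(NA_real_, dim = c(n_ind, n_site, 3L))
  marker <- character(n_site)
  a1 <- character(n_site)
  a2 <- character(n_site)
  for (j in seq_len(n_site)) {
    f <- split_row(lines[j + 1L])
    if (length(f) != n_field) {
      stop(sprintf(
        "malformed beagle row at line %d: expected %d fields, found %d",
        j + 1L, n_field, length(f)
      ))
    }
    marker[j] <- f[1]
    a1[j] <- f[2]
    a2[j] <- f[3]
    v <- suppressWarnings(as.numeric(f[-(1:3)]))
    if (anyNA(v)) stop(sprintf("non-numeric likelihood at line %d", j + 1L))
    lik[, j, ] <- matrix(v, ncol = 3L, byrow = TRUE)
  }
  us <- regexpr("_[^_]*$", marker)
  if (any(us < 0)) stop("marker names must be <chrom>_<pos>")
  chrom <- substr(marker, 1L, us - 1L)
  pos <- suppressWarnings(as.integer(substring(marker, us + 1L)))
  if (anyNA(pos)) stop("marker names must end in _<pos> with integer pos")
  sites <- data.frame(
    id = marker, chrom = chrom, pos = pos,
    ref = .decode_allele(a1), alt = .decode_allele(a2),
    stringsAsFactors = FALSE
  )
  gl_set(sites, lik, ind_ids)
}

#' Write a beagle genotype-likelihood file
#'
#' @param gl a [gl_set()]
#' @param path output path (plain text).
#' @param digits decimal digits used for the likelihoods.
#' @return `path`, invisibly.
#' @export
write_beagle_gl <- function(gl, path, digits = 6) {
  n_ind <- n_individuals(gl)
  header <- c("marker", "allele1", "allele2", rep(gl$individuals, each = 3L))
  fmt <- paste0("%.", digits, "f")
  rows <- vapply(seq_len(n_sites(gl)), function(j) {
    m <- gl$lik[, j, , drop = TRUE]
    m <- matrix(m, ncol = 3L)
    vals <- sprintf(fmt, as.vector(t(m)))
    paste(c(
      gl$sites$id[j],
      .encode_allele(gl$sites$ref[j]),
      .encode_allele(gl$sites$alt[j]),
      vals
    ), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}
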