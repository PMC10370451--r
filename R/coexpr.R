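#' Module eigengene
#'
#' The module eigengene (ME) is the first principal component of a
#' co-expression module's mRNA expression, one score per individual:
#' columns are standardized (mean 0, sd 1; missing values mean-imputed per
#' mRNA first), the first right singular direction gives the individual
#' scores, and the ME is scaled to unit variance. The sign is fixed so
#' that the mean correlation with the member mRNAs is non-negative, making
#' the result fully deterministic.
#'
#' @param x numeric matrix, individuals x member mRNAs (>= 3 individuals,
#'   >= 2 mRNAs).
#' @return list: `me` (named numeric, unit variance), `var_explained`
#'   (fraction of standardized variance carried by the first component),
#'   `dropped` (ids of zero-variance mRNAs removed with a warning).
#' @export
module_eigengene <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("module eigengene needs >= 3 individuals")
  n_imputed <- 0L
  if (anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) {
        x[nas, j] <- mean(x[, j], na.rm = TRUE)
        n_imputed <- n_imputed + sum(nas)
      }
    }
    message(n_imputed, " missing expression value(s) mean-imputed")
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance mRNA(s) dropped from module")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("module eigengene needs >= 2 mRNAs with variance")
  z <- scale(x)
  sv <- svd(z, nu = 1, nv = 0)
  me <- sv$u[, 1] * sv$d[1]
  me <- me / stats::sd(me)
  kme <- suppressWarnings(stats::cor(z, me))
  if (mean(kme, na.rm = TRUE) < 0) me <- -me
  names(me) <- rownames(x)
  list(
    me = me,
    var_explained = sv$d[1]^2 / sum(sv$d^2),
    dropped = dropped
  )
}

#' Module membership (kME)
#'
#' Pearson correlation between each mRNA's expression and its module
#' eigengene; always in `[-1, 1]`. Zero-variance mRNAs get `NA`.
#'
#' @param x numeric matrix, individuals x mRNAs.
#' @param me module eigengene (numeric, same individuals).
#' @return named numeric vector of kME values.
#' @export
module_membership <- function(x, me) {
  x <- as.matrix(x)
  if (nrow(x) != length(me)) stop("expression and eigengene must share individuals")
  kme <- suppressWarnings(as.vector(stats::cor(x, me)))
  names(kme) <- colnames(x)
  kme
}

#' Top-k mRNAs of a module by module membership
#'
#' @param kme named numeric vector of kME values for one module's mRNAs.
#' @param k number of mRNAs to select (default 10). A module with fewer
#'   than `k` members returns all of them, flagged `short`.
#' @param use_abs rank by `|kME|` instead of signed kME.
#' @return data.frame `mrna_id`, `kme`, `rank`; attribute `"short"` is TRUE
#'   when the module had fewer than `k` members. Ties broken by mRNA id.
#' @export
select_top_k <- function(kme, k = 10, use_abs = FALSE) {
  stopifnot(!is.null(names(kme)))
  key <- if (use_abs) abs(kme) else kme
  ord <- order(-key, names(kme), na.last = TRUE)
  n <- min(k, length(kme))
  sel <- ord[seq_len(n)]
  out <- data.frame(
    mrna_id = names(kme)[sel], kme = unname(kme[sel]), rank = seq_len(n),
    stringsAsFactors = FALSE
  )
  attr(out, "short") <- length(kme) < k
  out
}

#' Eigengenes, memberships and top-k lists for every module
#'
#' @param es an [expression_set()].
#' @param k top-k size passed to [select_top_k()].
#' @param use_abs rank top-k by absolute kME.
#' @return list: `me` (individuals x modules matrix of unit-variance
#'   eigengenes), `kme` (data.frame mrna_id, module, kme), `top`
#'   (data.frame mrna_id, module, kme, rank over all modules),
#'   `var_explained` (named numeric per module), `short_modules`.
#' @export
module_summaries <- function(es, k = 10, use_abs = FALSE) {
  mods <- es$modules[es$modules$mrna_id %in% colnames(es$expr), , drop = FALSE]
  ids <- sort(unique(mods$module))
  me <- matrix(NA_real_, nrow(es$expr), length(ids),
    dimnames = list(rownames(es$expr), ids)
  )
  ve <- stats::setNames(numeric(length(ids)), ids)
  kme_all <- list()
  top_all <- list()
  short <- character()
  for (m in ids) {
    members <- mods$mrna_id[mods$module == m]
    sub <- es$expr[, members, drop = FALSE]
    eg <- module_eigengene(sub)
    me[, m] <- eg$me
    ve[m] <- eg$var_explained
    kme <- module_membership(sub, eg$me)
    kme_all[[m]] <- data.frame(
      mrna_id = names(kme), module = m, kme = unname(kme),
      stringsAsFactors = FALSE
    )
    tk <- select_top_k(kme, k = k, use_abs = use_abs)
    tk$module <- m
    if (isTRUE(attr(tk, "short"))) short <- c(short, m)
    top_all[[m]] <- tk
  }
  list(
    me = me,
    kme = do.call(rbind, c(kme_all, list(make.row.names = FALSE))),
    top = do.call(rbind, c(top_all, list(make.row.names = FALSE))),
    var_explained = ve,
    short_modules = short
  )
}
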