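#' Genome layout
#'
#' Ordered table of the reference sequences (large chromosomes plus
#' unplaced scaffolds) a dataset lives on. Used to place simulated sites
#' and genes and by the chromosome-aware trans null.
#'
#' @param name character vector of unique sequence names.
#' @param length integer vector of sequence lengths in bp (> 0).
#' @param class character vector, each `"chromosome"` or `"scaffold"`.
#' @return data.frame of class `genome_layout` with columns
#'   `name`, `length`, `class`.
#' @export
genome_layout <- function(name, length, class) {
  if (length(name) < 1L) stop("need at least one sequence")
  if (anyDuplicated(name)) stop("sequence names must be unique")
  if (any(length <= 0)) stop("sequence lengths must be > 0")
  if (!all(class %in% c("chromosome", "scaffold"))) {
    stop('sequence class must be "chromosome" or "scaffold"')
  }
  structure(
    data.frame(
      name = as.character(name), length = as.numeric(length),
      class = as.character(class), stringsAsFactors = FALSE
    ),
    class = c("genome_layout", "data.frame")
  )
}

#' Read / write a genome layout TSV
#' @param path file path; columns `name`, `length`, `class`.
#' @return a [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_layout(d$name, d$length, d$class)
}

#' @rdname read_genome_layout
#' @param layout a [genome_layout()]
#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(layout, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read gene intervals from a GFF3/GTF annotation
#'
#' Imports `gene` features (falling back to `mRNA`/`transcript` when no
#' `gene` features are present) and returns 1-based inclusive intervals
#' sorted within chromosome. The transcription-factor flag is set from a
#' caller-supplied gene-id list; annotation files carry no such flag
#' themselves.
#'
#' @param path GFF3 or GTF file.
#' @param tf_ids character vector of gene ids to flag as transcription
#'   factors (empty default leaves all flags FALSE).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `is_tf`.
#' @export
read_gff_genes <- function(path, tf_ids = character()) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop("failed to parse annotation ", path, ": ", conditionMessage(e))
  )
  type <- as.character(gr$type)
  keep <- type == "gene"
  if (!any(keep)) keep <- type %in% c("mRNA", "transcript")
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no gene features found in ", path)
  md <- S4Vectors::mcols(gr)
  gene_id <- NULL
  for (col in c("ID", "gene_id", "Name", "gene")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) {
      gene_id <- as.character(md[[col]])
      break
    }
  }
  if (is.null(gene_id)) stop("no gene identifier attribute found in ", path)
  out <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(out$end < out$start)) stop("gene interval with end < start in ", path)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$is_tf <- out$gene_id %in% tf_ids
  out
}

#' Write gene intervals as GFF3
#'
#' @param genes data.frame as returned by [read_gff_genes()] (the `is_tf`
#'   column, if present, is not written; TF status travels in a separate
#'   list).
#' @param path output path.
#' @export
write_gff_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = if ("strand" %in% names(genes)) genes$strand else "*"
  )
  gr$type <- "gene"
  gr$source <- "lceqtl"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' TSV with one row per individual: an `individual` id column, a
#' `temperature` covariate (acclimation temperature, 12 or 28 degrees C),
#' an `acclimation_order` covariate, and one column per physiological
#' trait (missing values allowed; only a minority of genotyped individuals
#' are phenotyped).
#'
#' @param path file path.
#' @return data.frame; attribute `"traits"` names the trait columns.
#' @export
read_phenotype_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"individual" %in% names(d)) stop("phenotype table needs an 'individual' column")
  if (anyDuplicated(d$individual)) stop("individual ids must be unique")
  covs <- c("temperature", "acclimation_order")
  if (!all(covs %in% names(d))) {
    stop("phenotype table needs covariate columns: ", paste(covs, collapse = ", "))
  }
  traits <- setdiff(names(d), c("individual", covs))
  for (tr in traits) {
    if (all(is.na(d[[tr]]))) stop("trait '", tr, "' has no non-missing value")
    bad <- !is.na(d[[tr]]) & (is.na(d$temperature) | is.na(d$acclimation_order))
    if (any(bad)) {
      stop("covariates missing for phenotyped individuals in trait '", tr, "'")
    }
  }
  attr(d, "traits") <- traits
  d
}

#' @rdname read_phenotype_table
#' @param pheno phenotype data.frame
#' @export
write_phenotype_table <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an mRNA -> module assignment table
#' @param path TSV with columns `mrna_id`, `module`.
#' @return data.frame with those two columns.
#' @export
read_module_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mrna_id", "module") %in% names(d))) {
    stop("module table needs columns mrna_id, module")
  }
  if (anyDuplicated(d$mrna_id)) stop("every mRNA must map to exactly one module")
  d$module <- as.character(d$module)
  d
}

#' Read a transcription-factor gene list
#' @param path TSV/plain list with gene ids in the first column.
#' @return character vector of gene ids.
#' @export
read_tf_list <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  as.character(d[[1]])
}

#' Read an expression matrix TSV (individuals x mRNAs)
#'
#' @param path TSV whose first column is `individual`; remaining columns
#'   are per-mRNA expression values.
#' @return numeric matrix with individual row names.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "individual") stop("first column must be 'individual'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$individual
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param expr numeric matrix, individuals in rows.
#' @export
write_expression_matrix <- function(expr, path) {
  d <- data.frame(individual = rownames(expr), expr, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expression set: matrix + gene coordinates + module assignments
#'
#' @param expr numeric matrix, individuals x mRNAs.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end` (gene ids
#'   matching `colnames(expr)`); extra columns kept.
#' @param modules data.frame with `mrna_id`, `module`.
#' @param tissue tissue label, e.g. `"heart"` or `"brain"`.
#' @return object of class `expression_set`.
#' @export
expression_set <- function(expr, genes, modules, tissue = "heart") {
  if (is.null(colnames(expr)) || is.null(rownames(expr))) {
    stop("expression matrix needs individual row names and mRNA column names")
  }
  if (!all(colnames(expr) %in% modules$mrna_id)) {
    stop("every mRNA must have a module assignment")
  }
  if (anyDuplicated(modules$mrna_id)) stop("every mRNA must have exactly one module")
  sz <- table(modules$module[modules$mrna_id %in% colnames(expr)])
  if (any(sz < 2)) stop("module sizes must be >= 2")
  if (!all(colnames(expr) %in% genes$gene_id)) {
    stop("every mRNA needs gene coordinates")
  }
  structure(
    list(
      expr = expr,
      genes = as.data.frame(genes, stringsAsFactors = FALSE),
      modules = as.data.frame(modules, stringsAsFactors = FALSE),
      tissue = tissue
    ),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf(
    "expression_set (%s): %d individuals x %d mRNAs in %d modules\n",
    x$tissue, nrow(x$expr), ncol(x$expr),
    length(unique(x$modules$module[x$modules$mrna_id %in% colnames(x$expr)]))
  ))
  invisible(x)
}

#' Site-level filtering
#'
#' Reproduces the variant-level filters of the source pipeline on a
#' [gl_set()]: keep biallelic sites (structural in the container) with
#' minor allele frequency above `maf_min` and per-site missingness below
#' `site_miss_max`. Individuals whose overall missingness exceeds
#' `ind_miss_max` are flagged (with a warning) but not dropped: association
#' sample sizes are already small, and dropping is left to the caller.
#'
#' @param gl a [gl_set()].
#' @param freq optional precomputed output of [estimate_allele_freq_em()];
#'   computed when NULL.
#' @param maf_min minimum minor allele frequency (exclusive), default 0.05.
#' @param site_miss_max maximum per-site missingness (exclusive), default
#'   0.10.
#' @param ind_miss_max per-individual missingness above which the
#'   individual is flagged, default 0.05.
#' @return list: `gl` (filtered set), `kept` (logical over input sites),
#'   `site_stats` (data.frame id, maf, missingness, kept),
#'   `flagged_individuals` (ids over the `ind_miss_max` threshold).
#' @export
filter_sites <- function(gl, freq = NULL, maf_min = 0.05, site_miss_max = 0.10,
                         ind_miss_max = 0.05) {
  if (is.null(freq)) freq <- estimate_allele_freq_em(gl)
  miss <- gl_missing(gl)
  site_miss <- colMeans(miss)
  ind_miss <- rowMeans(miss)
  maf <- pmin(freq$p, 1 - freq$p)
  kept <- maf > maf_min & site_miss < site_miss_max
  flagged <- gl$individuals[ind_miss > ind_miss_max]
  if (length(flagged)) {
    warning(
      length(flagged), " individual(s) exceed ", ind_miss_max,
      " missingness (flagged, not dropped): ",
      paste(utils::head(flagged, 5), collapse = ", ")
    )
  }
  list(
    gl = gl_subset(gl, sites = kept),
    kept = kept,
    site_stats = data.frame(
      id = gl$sites$id, maf = maf, missingness = site_miss, kept = kept,
      stringsAsFactors = FALSE
    ),
    flagged_individuals = flagged
  )
}

#' Convert 1-based sites to BED intervals
#'
#' Internal coordinates are 1-based inclusive (VCF/GFF convention); BED is
#' 0-based half-open, so a SNP at pos becomes `[pos - 1, pos)`.
#'
#' @param sites data.frame with `chrom`, `pos` and optionally `id`.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
sites_to_bed <- function(sites) {
  data.frame(
    chrom = sites$chrom,
    start = sites$pos - 1L,
    end = sites$pos,
    name = if ("id" %in% names(sites)) sites$id else paste0(sites$chrom, "_", sites$pos),
    stringsAsFactors = FALSE
  )
}

#' @rdname sites_to_bed
#' @param bed data.frame from [sites_to_bed()]
#' @param path output path
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
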