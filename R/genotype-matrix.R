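#' Genotype matrix for panels of inbred lines
#'
#' The central data structure of the package: an individuals x sites call
#' matrix with site and individual metadata. Calls are integer-coded:
#' \describe{
#'   \item{0}{homozygous major (reference) allele}
#'   \item{2}{homozygous minor (alternate) allele}
#'   \item{1}{heterozygous call (pre-QC only)}
#'   \item{3}{tertiary call: a third or higher allele state (pre-QC only)}
#'   \item{NA}{missing}
#' }
#' After quality control only \{0, 2, NA\} remain, and after imputation only
#' \{0, 2\}. Sites are kept strictly sorted by (chromosome, position) and
#' keyed on that pair; positions are 1-based as in HapMap/VCF and all
#' internal intervals are closed.
#'
#' @param calls integer matrix, individuals in rows (rownames = individual
#'   names), sites in columns, values in \{0, 1, 2, 3, NA\}.
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (integer, 1-based), `ref` and `alt` (single upper-case bases). One row
#'   per column of `calls`.
#' @param provenance optional character vector, one source tag per
#'   individual (e.g. which genotyping platform it came from).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, provenance = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) {
    if (nrow(calls) > 0) stop("`calls` must have rownames giving individual names")
    rownames(calls) <- character(0)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    stop("`sites` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (nrow(sites) != ncol(calls)) {
    stop("nrow(sites) must equal ncol(calls)")
  }
  if (anyDuplicated(rownames(calls))) {
    stop("duplicate individual names")
  }
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    stop("duplicate (chromosome, position) site keys")
  }
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(sites) <- NULL
  bad <- calls[!is.na(calls) & !(calls %in% c(0L, 1L, 2L, 3L))]
  if (length(bad) > 0) {
    stop("invalid call codes: ", paste(unique(bad), collapse = ", "))
  }
  if (is.null(provenance)) {
    provenance <- rep(NA_character_, nrow(calls))
  }
  stopifnot(length(provenance) == nrow(calls))
  structure(
    list(calls = calls, sites = sites, provenance = provenance),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  n_na <- sum(is.na(x$calls))
  cat(sprintf(
    "genotype_matrix: %d individuals x %d sites (%d chromosome%s), %.2f%% missing\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$sites$chrom)),
    if (length(unique(x$sites$chrom)) == 1) "" else "s",
    100 * n_na / length(x$calls)
  ))
  invisible(x)
}

#' Individual names of a genotype matrix
#' @param gm a `genotype_matrix`
#' @return character vector of individual names
#' @export
individuals <- function(gm) rownames(gm$calls)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`
#' @param i individual index (names, logical or integer)
#' @param j site index (logical or integer, in sorted site order)
#' @param ... unused
#' @return a `genotype_matrix`
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  prov <- x$provenance
  names(prov) <- rownames(x$calls)
  calls <- x$calls[i, j, drop = FALSE]
  genotype_matrix(calls, x$sites[j, , drop = FALSE],
                  provenance = unname(prov[rownames(calls)]))
}

#' Does the matrix contain any missing calls?
#' @param gm a `genotype_matrix`
#' @return logical scalar
#' @export
is_complete <- function(gm) !anyNA(gm$calls)

# Internal: site keys "chrom:pos"
site_key <- function(sites) paste(sites$chrom, sites$pos, sep = ":")

# Internal: check the matrix is post-QC haploid-coded ({0,2,NA})
assert_haploid <- function(gm, what = "matrix") {
  if (any(gm$calls %in% c(1L, 3L))) {
    stop(what, " must contain only {0, 2, NA} calls; run apply_filters() first")
  }
  invisible(TRUE)
}
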