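# Merging of two partially overlapping marker platforms, with the
# site/individual/missingness accounting breeders expect from a GBS panel
# compilation step. Sites are identified by (chromosome, position) only;
# sites present in both inputs whose allele pairs disagree are dropped and
# counted rather than guessed at.

#' Arithmetic of a two-platform site merge
#'
#' The inclusion-exclusion identities of a site-union merge: given the two
#' platform site counts and the number of sites common to both, the merged
#' panel has `n1 + n2 - n_common` sites, and the share of common sites is
#' `n_common / merged`.
#'
#' @param n_sites_1,n_sites_2 site counts of the two platforms.
#' @param n_common sites present (same chromosome and position) in both.
#' @return list with `n_sites_merged` and `pct_common` (percent of merged
#'   sites common to both platforms).
#' @export
merge_site_accounting <- function(n_sites_1, n_sites_2, n_common) {
  stopifnot(n_common <= min(n_sites_1, n_sites_2))
  merged <- n_sites_1 + n_sites_2 - n_common
  list(n_sites_merged = merged, pct_common = 100 * n_common / merged)
}

# Internal: panel-level summary used for each column of the merge report
panel_stats <- function(gm) {
  n_cells <- length(gm$calls)
  n_missing <- sum(is.na(gm$calls))
  n_het <- sum(gm$calls == 1L, na.rm = TRUE)
  list(
    n_individuals = nrow(gm$calls),
    n_sites = ncol(gm$calls),
    total_data_points = n_cells,
    n_missing = n_missing,
    pct_missing = if (n_cells > 0) 100 * n_missing / n_cells else 0,
    n_het = n_het,
    pct_het = if (n_cells > 0) 100 * n_het / n_cells else 0
  )
}

#' Merge two genotype matrices over the union of their sites
#'
#' Individual name sets must be disjoint (the two platforms genotype
#' different lines). The merged site set is the union keyed on
#' (chromosome, position); an individual absent from a platform carries
#' missing calls at that platform's private sites. Sites present in both
#' inputs with conflicting allele pairs are dropped from the merge and
#' counted in the report.
#'
#' @param gm1,gm2 [genotype_matrix()] objects.
#' @return list with `gm` (the merged matrix) and `report`, a
#'   `merge_report`: per-input and merged panel statistics (individuals,
#'   sites, total data points, missing and heterozygous counts and
#'   percentages), the number of common sites, the percent of merged sites
#'   common to both, and the number of allele-conflict sites dropped.
#' @export
merge_panels <- function(gm1, gm2) {
  stopifnot(inherits(gm1, "genotype_matrix"), inherits(gm2, "genotype_matrix"))
  if (length(intersect(rownames(gm1$calls), rownames(gm2$calls))) > 0) {
    stop("individual names overlap between the two inputs; merging assumes ",
         "disjoint line sets")
  }
  k1 <- site_key(gm1$sites)
  k2 <- site_key(gm2$sites)
  common <- intersect(k1, k2)
  # allele-pair conflicts among common sites (unordered pair comparison)
  pair1 <- with(gm1$sites, paste(pmin(ref, alt), pmax(ref, alt)))
  pair2 <- with(gm2$sites, paste(pmin(ref, alt), pmax(ref, alt)))
  i1 <- match(common, k1)
  i2 <- match(common, k2)
  conflict <- common[pair1[i1] != pair2[i2]]
  keep1 <- !(k1 %in% conflict)
  keep2 <- !(k2 %in% conflict)
  g1 <- gm1[, which(keep1)]
  g2 <- gm2[, which(keep2)]
  k1 <- k1[keep1]; k2 <- k2[keep2]
  union_sites <- rbind(g1$sites, g2$sites[!(k2 %in% k1), , drop = FALSE])
  ord <- order(union_sites$chrom, union_sites$pos)
  union_sites <- union_sites[ord, , drop = FALSE]
  ku <- site_key(union_sites)
  n1 <- nrow(g1$calls); n2 <- nrow(g2$calls)
  calls <- matrix(NA_integer_, n1 + n2, nrow(union_sites),
                  dimnames = list(c(rownames(g1$calls), rownames(g2$calls)),
                                  NULL))
  calls[seq_len(n1), match(k1, ku)] <- g1$calls
  calls[n1 + seq_len(n2), match(k2, ku)] <- g2$calls
  merged <- genotype_matrix(calls, union_sites,
                            provenance = c(g1$provenance, g2$provenance))
  n_common_kept <- length(common) - length(conflict)
  acct <- merge_site_accounting(ncol(g1$calls), ncol(g2$calls), n_common_kept)
  stopifnot(acct$n_sites_merged == ncol(merged$calls))
  report <- structure(list(
    input1 = panel_stats(gm1),
    input2 = panel_stats(gm2),
    merged = panel_stats(merged),
    n_common_sites = n_common_kept,
    pct_common = acct$pct_common,
    n_conflict_sites = length(conflict)
  ), class = "merge_report")
  list(gm = merged, report = report)
}

#' @export
print.merge_report <- function(x, digits = 1, ...) {
  row <- function(s) {
    sprintf("%10d %12d %16d %12d %7s%% %9d %6s%%",
            s$n_individuals, s$n_sites, s$total_data_points, s$n_missing,
            format(round_half_up(s$pct_missing, digits), nsmall = digits),
            s$n_het,
            format(round_half_up(s$pct_het, 2), nsmall = 2))
  }
  cat("merge report (individuals, sites, data points, missing, %missing, het, %het)\n")
  cat("  input 1:", row(x$input1), "\n")
  cat("  input 2:", row(x$input2), "\n")
  cat("  merged :", row(x$merged), "\n")
  cat(sprintf("  sites common to both: %d (%.1f%% of merged); allele conflicts dropped: %d\n",
              x$n_common_sites, x$pct_common, x$n_conflict_sites))
  invisible(x)
}

#' Write a merge report as TSV
#' @param report a `merge_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(report, path) {
  tab <- do.call(rbind, lapply(c("input1", "input2", "merged"), function(nm) {
    data.frame(panel = nm, as.data.frame(report[[nm]]))
  }))
  tab$n_common_sites <- report$n_common_sites
  tab$pct_common <- report$pct_common
  tab$n_conflict_sites <- report$n_conflict_sites
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
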