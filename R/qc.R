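# Quality control of a merged inbred-panel genotype matrix. Inbred lines
# are expected homozygous, so residual heterozygous calls and third-allele
# (tertiary) states are treated as genotyping error and converted to
# missing before site-level filters run; minor allele frequency and site
# missingness are recomputed after that conversion so the filters see the
# data they will actually ship.

#' Filtering configuration
#'
#' @param maf_min minimum minor allele frequency for a site to survive
#'   (default 0.05).
#' @param site_missing_max maximum tolerated per-site missing fraction
#'   (default 0.172).
#' @param het_to_missing,tertiary_to_missing convert heterozygous /
#'   tertiary calls to missing before the site filters (default both on).
#' @param recompute_maf_after_conversion compute MAF and missingness after
#'   the het/tertiary conversion (default) or on the raw calls.
#' @param individual_missing_cap advisory cap on per-individual missing
#'   fraction; exceedances are reported, never filtered (default 0.30).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05,
                          site_missing_max = 0.172,
                          het_to_missing = TRUE,
                          tertiary_to_missing = TRUE,
                          recompute_maf_after_conversion = TRUE,
                          individual_missing_cap = 0.30) {
  cfg <- list(maf_min = maf_min, site_missing_max = site_missing_max,
              het_to_missing = het_to_missing,
              tertiary_to_missing = tertiary_to_missing,
              recompute_maf_after_conversion = recompute_maf_after_conversion,
              individual_missing_cap = individual_missing_cap)
  for (nm in c("maf_min", "site_missing_max", "individual_missing_cap")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop("`", nm, "` must lie in [0, 1]")
  }
  class(cfg) <- "filter_config"
  cfg
}

#' Per-site summary statistics
#'
#' MAF is computed from non-missing homozygous calls only (heterozygous
#' and tertiary calls are excluded from the allele count): with p the
#' frequency of the minor-coded allele among those calls, MAF =
#' min(p, 1 - p). Sites with no usable calls get `NA` MAF and are flagged.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with one row per site: `chrom`, `pos`,
#'   `missing_frac`, `maf`, `het_frac`, `n_alleles` (observed allele count
#'   including tertiary states), `maf_defined`.
#' @export
site_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$calls) == 0) stop("empty genotype matrix")
  calls <- gm$calls
  n_ind <- nrow(calls)
  n_missing <- colSums(is.na(calls))
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n_ter <- colSums(calls == 3L, na.rm = TRUE)
  n_major <- colSums(calls == 0L, na.rm = TRUE)
  n_minor <- colSums(calls == 2L, na.rm = TRUE)
  n_used <- n_major + n_minor
  p_minor <- ifelse(n_used > 0, n_minor / n_used, NA_real_)
  maf <- pmin(p_minor, 1 - p_minor)
  n_alleles <- (n_major > 0 | n_het > 0) + (n_minor > 0 | n_het > 0) +
    (n_ter > 0)
  data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    missing_frac = n_missing / n_ind,
    maf = maf,
    het_frac = n_het / n_ind,
    n_alleles = as.integer(n_alleles),
    maf_defined = n_used > 0
  )
}

#' Apply the panel's site filters
#'
#' Fixed order of operations: (1) heterozygous calls to missing, (2)
#' tertiary calls to missing, (3) drop sites whose missing fraction
#' (recomputed after the conversions) exceeds `site_missing_max`, (4) drop
#' sites with MAF below `maf_min` (sites with undefined MAF drop here
#' too). The output matrix contains only \{0, 2, NA\} calls.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return list with `gm` (filtered matrix) and `report`, a
#'   `filter_report`: site counts before/after, per-rule removed-site
#'   counts, converted-call counts, the per-individual missing-fraction
#'   vector with mean/median/max/min, overall percent missing, percent
#'   heterozygous after conversion, and the individuals exceeding the
#'   advisory per-individual missing cap.
#' @export
apply_filters <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!inherits(cfg, "filter_config")) cfg <- do.call(filter_config, cfg)
  calls <- gm$calls
  n_het_converted <- 0L
  n_ter_converted <- 0L
  if (cfg$het_to_missing) {
    idx <- which(calls == 1L)
    n_het_converted <- length(idx)
    calls[idx] <- NA_integer_
  }
  if (cfg$tertiary_to_missing) {
    idx <- which(calls == 3L)
    n_ter_converted <- length(idx)
    calls[idx] <- NA_integer_
  }
  work <- gm
  work$calls <- calls
  stats_src <- if (cfg$recompute_maf_after_conversion) work else gm
  st <- site_stats(stats_src)
  # step 3 then 4; a site failing both is charged to the missingness rule
  fail_miss <- st$missing_frac > cfg$site_missing_max
  fail_maf <- !fail_miss & (!st$maf_defined | st$maf < cfg$maf_min)
  keep <- !fail_miss & !fail_maf
  if (!any(keep)) stop("no sites survive the configured filters")
  out <- work[, which(keep)]
  ind_missing <- rowMeans(is.na(out$calls))
  report <- structure(list(
    n_sites_before = ncol(gm$calls),
    n_sites_after = ncol(out$calls),
    n_removed_missing = sum(fail_miss),
    n_removed_maf = sum(fail_maf),
    n_het_converted = n_het_converted,
    n_tertiary_converted = n_ter_converted,
    individual_missing = ind_missing,
    individual_missing_summary = c(
      mean = mean(ind_missing), median = stats::median(ind_missing),
      max = max(ind_missing), min = min(ind_missing)
    ),
    pct_missing = 100 * mean(is.na(out$calls)),
    pct_het = 100 * mean(out$calls == 1L, na.rm = TRUE),
    over_cap = names(ind_missing)[ind_missing > cfg$individual_missing_cap],
    config = cfg
  ), class = "filter_report")
  stopifnot(report$n_sites_before - report$n_removed_missing -
              report$n_removed_maf == report$n_sites_after)
  list(gm = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    paste0("filter report: %d -> %d sites ",
           "(%d dropped for missingness > %.3f, %d for MAF < %.2f)\n"),
    x$n_sites_before, x$n_sites_after, x$n_removed_missing,
    x$config$site_missing_max, x$n_removed_maf, x$config$maf_min
  ))
  cat(sprintf("  converted to missing: %d het, %d tertiary calls\n",
              x$n_het_converted, x$n_tertiary_converted))
  s <- x$individual_missing_summary
  cat(sprintf(
    "  per-individual missing: mean %.2f%%, median %.2f%%, max %.2f%%, min %.2f%%\n",
    100 * s["mean"], 100 * s["median"], 100 * s["max"], 100 * s["min"]
  ))
  cat(sprintf("  overall missing %.2f%%, het %.2f%%\n",
              x$pct_missing, x$pct_het))
  if (length(x$over_cap) > 0) {
    cat("  individuals over the advisory missing cap:",
        paste(x$over_cap, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  s <- report$individual_missing_summary
  tab <- data.frame(
    statistic = c("sites_before", "sites_after", "removed_missing",
                  "removed_maf", "het_converted", "tertiary_converted",
                  "pct_missing", "pct_het",
                  "ind_missing_mean", "ind_missing_median",
                  "ind_missing_max", "ind_missing_min"),
    value = c(report$n_sites_before, report$n_sites_after,
              report$n_removed_missing, report$n_removed_maf,
              report$n_het_converted, report$n_tertiary_converted,
              report$pct_missing, report$pct_het,
              100 * s["mean"], 100 * s["median"], 100 * s["max"],
              100 * s["min"])
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
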