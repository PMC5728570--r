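# Linkage disequilibrium within chromosomes: pairwise r^2 between
# haploid-coded sites, distance-binned decay curves smoothed on a
# log-distance axis, and the distance at which the smoothed curve crosses
# r^2 = 0.2. For fully homozygous lines the squared Pearson correlation of
# the two call vectors equals the classical haplotype-count r^2
# (D^2 / (p_A p_a p_B p_b)), which a test verifies by brute force.

#' Pairwise r-squared within chromosomes
#'
#' @param gm a fully imputed \{0, 2\} [genotype_matrix()].
#' @param max_dist only site pairs at most this many bp apart are scored
#'   (default `Inf`, all within-chromosome pairs).
#' @param max_pairs cap on the number of scored pairs per chromosome; when
#'   the candidate pairs exceed it a seeded uniform subsample is taken and
#'   flagged (default 5e5).
#' @param seed seed for the pair subsample.
#' @return object of class `ld_pairs`: data.frame `pairs` with columns
#'   `chrom`, `dist` (bp), `r2`, plus counters `n_monomorphic_skipped` and
#'   `subsampled` (logical per chromosome).
#' @export
pairwise_r2 <- function(gm, max_dist = Inf, max_pairs = 5e5, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_haploid(gm, "LD input")
  if (!is_complete(gm)) stop("LD input must be fully imputed (no missing calls)")
  poly <- apply(gm$calls, 2, function(x) length(unique(x)) > 1)
  n_mono <- sum(!poly)
  chroms <- unique(gm$sites$chrom)
  set.seed(seed)
  out <- list()
  subsampled <- logical(0)
  any_ok <- FALSE
  for (ch in chroms) {
    j <- which(gm$sites$chrom == ch & poly)
    if (length(j) < 2) {
      subsampled[ch] <- FALSE
      next
    }
    any_ok <- TRUE
    pos <- gm$sites$pos[j]
    cmb <- utils::combn(length(j), 2)
    d <- pos[cmb[2, ]] - pos[cmb[1, ]]
    ok <- d > 0 & d <= max_dist
    cmb <- cmb[, ok, drop = FALSE]
    d <- d[ok]
    subsampled[ch] <- ncol(cmb) > max_pairs
    if (subsampled[ch]) {
      pick <- sample.int(ncol(cmb), max_pairs)
      cmb <- cmb[, pick, drop = FALSE]
      d <- d[pick]
    }
    z <- scale(gm$calls[, j, drop = FALSE])
    n <- nrow(z)
    r <- colSums(z[, cmb[1, ], drop = FALSE] * z[, cmb[2, ], drop = FALSE]) /
      (n - 1)
    out[[ch]] <- data.frame(chrom = ch, dist = d, r2 = r^2,
                            stringsAsFactors = FALSE)
  }
  if (!any_ok) {
    stop("fewer than 2 polymorphic sites on every chromosome; cannot ",
         "compute LD")
  }
  structure(list(
    pairs = do.call(rbind, out),
    n_monomorphic_skipped = n_mono,
    subsampled = subsampled
  ), class = "ld_pairs")
}

#' Smoothed LD decay curve and r^2 = 0.2 crossing distance
#'
#' Nadaraya-Watson kernel regression (Gaussian kernel) of r^2 on
#' log10(distance), evaluated per chromosome and pooled over all pairs, on
#' a log-spaced distance grid. `d02` is the first grid distance at which
#' the pooled smoothed curve drops to 0.2 or below; it is `NA` when the
#' curve never crosses.
#'
#' @param ld an [pairwise_r2()] result.
#' @param n_grid grid resolution (default 200).
#' @param bandwidth kernel bandwidth on the log10 scale; `NULL` (default)
#'   uses Silverman's rule on the pooled log-distances, floored at 0.05.
#' @return object of class `ld_decay`: `grid` (bp), `pooled` (smoothed
#'   r^2 on the grid), `per_chrom` (matrix, one column per chromosome),
#'   `d02` (pooled crossing distance, bp) and `d02_per_chrom`.
#' @export
decay_curve <- function(ld, n_grid = 200, bandwidth = NULL) {
  stopifnot(inherits(ld, "ld_pairs"))
  pairs <- ld$pairs
  if (is.null(pairs) || nrow(pairs) == 0) stop("no LD pairs to smooth")
  lx <- log10(pairs$dist)
  if (is.null(bandwidth)) {
    bandwidth <- max(stats::bw.nrd0(lx), 0.05)
  }
  grid_l <- seq(min(lx), max(lx), length.out = n_grid)
  if (min(lx) == max(lx)) grid_l <- min(lx)  # all pairs at one distance
  smooth_at <- function(x, y) {
    vapply(grid_l, function(g) {
      w <- stats::dnorm((x - g) / bandwidth)
      sum(w * y) / sum(w)
    }, 0)
  }
  pooled <- smooth_at(lx, pairs$r2)
  chroms <- unique(pairs$chrom)
  per_chrom <- vapply(chroms, function(ch) {
    sel <- pairs$chrom == ch
    smooth_at(lx[sel], pairs$r2[sel])
  }, numeric(length(grid_l)))
  if (length(grid_l) == 1) per_chrom <- matrix(per_chrom, nrow = 1,
                                               dimnames = list(NULL, chroms))
  crossing <- function(curve) {
    hit <- which(curve <= 0.2)
    if (length(hit) == 0) NA_real_ else 10^grid_l[hit[1]]
  }
  structure(list(
    grid = 10^grid_l,
    pooled = pooled,
    per_chrom = per_chrom,
    d02 = crossing(pooled),
    d02_per_chrom = apply(per_chrom, 2, crossing),
    bandwidth = bandwidth
  ), class = "ld_decay")
}

#' Write LD pairs and decay curves as TSV
#' @param ld an `ld_pairs` object.
#' @param decay an `ld_decay` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ld_tables <- function(ld, decay, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ld$pairs, file.path(dir, "ld_pairs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  curve <- data.frame(dist_bp = decay$grid, pooled = decay$pooled,
                      decay$per_chrom, check.names = FALSE)
  utils::write.table(curve, file.path(dir, "ld_decay.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
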