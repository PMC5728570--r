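# Genetic diversity between groups: Weir-Cockerham theta (F_ST) per locus
# in its haploid form (no heterozygote component - lines are inbred and QC
# removes residual hets), balanced maximally-unrelated subsampling,
# moving-window genome scans, top-region extraction, and candidate-gene
# queries around high-theta SNPs.

#' Balanced, maximally unrelated subsample of each group
#'
#' Within each group, repeatedly finds the closest pair of remaining
#' members and removes the pair member with the smaller average distance
#' to the rest of the group (ties broken lexicographically by name), until
#' `target_per_group` members remain. Exact duplicates (distance 0) are
#' therefore eliminated first. Deterministic.
#'
#' @param dm distance matrix (e.g. [nei_distance()]) over all individuals.
#' @param labels named group labels covering the rows of `dm`.
#' @param target_per_group members to keep in every group.
#' @return list with `keep` (character vector of kept individuals) and
#'   `roster` (data.frame of every removal: individual, group, step, the
#'   closest-pair distance that triggered it).
#' @export
select_balanced_unrelated <- function(dm, labels, target_per_group) {
  dm <- as.matrix(dm)
  stopifnot(!is.null(rownames(dm)))
  if (is.null(names(labels))) names(labels) <- rownames(dm)
  keep <- character(0)
  roster <- list()
  for (g in sort(unique(labels))) {
    members <- sort(intersect(rownames(dm), names(labels)[labels == g]))
    if (length(members) < target_per_group) {
      stop("group ", g, " has ", length(members),
           " members, fewer than the target ", target_per_group)
    }
    step <- 0L
    while (length(members) > target_per_group) {
      step <- step + 1L
      sub <- dm[members, members]
      diag(sub) <- Inf
      min_d <- min(sub)
      hit <- which(sub == min_d, arr.ind = TRUE)[1, ]
      pair <- sort(members[hit])
      avg <- rowMeans(dm[pair, setdiff(members, pair), drop = FALSE])
      drop_ind <- if (avg[1] < avg[2]) pair[1]
                  else if (avg[2] < avg[1]) pair[2]
                  else pair[1]   # lexicographic tie-break (pair is sorted)
      members <- setdiff(members, drop_ind)
      roster[[length(roster) + 1]] <- data.frame(
        individual = drop_ind, group = g, step = step,
        closest_pair_dist = min_d, stringsAsFactors = FALSE
      )
    }
    keep <- c(keep, members)
  }
  list(keep = keep,
       roster = if (length(roster)) do.call(rbind, roster)
                else data.frame(individual = character(0), group = character(0),
                                step = integer(0),
                                closest_pair_dist = numeric(0)))
}

#' Weir-Cockerham theta (F_ST) per locus, haploid form
#'
#' For each locus with r groups, group sample sizes n_i (non-missing
#' lines) and minor-allele frequencies p_i:
#' \deqn{\bar p = \sum n_i p_i / \sum n_i}
#' \deqn{n_c = (\sum n_i - \sum n_i^2 / \sum n_i) / (r - 1)}
#' \deqn{MSP = \sum n_i (p_i - \bar p)^2 / (r - 1)}
#' \deqn{MSG = \sum n_i p_i (1 - p_i) / \sum (n_i - 1)}
#' \deqn{\theta = (MSP - MSG) / (MSP + (n_c - 1) MSG)}
#' Loci monomorphic across all groups have undefined theta and are
#' flagged and excluded from the overall mean. A locus needs at least 2
#' non-missing calls in every group to be estimable.
#'
#' @param gm a post-QC [genotype_matrix()] (\{0, 2, NA\}).
#' @param labels group labels, named by individual or in row order.
#' @param overall `"average"` (default): overall F_ST is the simple
#'   average of defined per-locus theta values; `"ratio"`: the
#'   ratio-of-sums estimator sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG).
#' @return object of class `fst_result`: data.frame `loci` with per-locus
#'   chrom, pos, group frequencies, sample sizes, p_bar, n_c, MSP, MSG,
#'   theta and a `defined` flag; `overall` (the overall F_ST) and
#'   `overall_method`.
#' @export
fst_weir_cockerham <- function(gm, labels, overall = c("average", "ratio")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_haploid(gm, "F_ST input")
  overall <- match.arg(overall)
  if (!is.null(names(labels))) {
    labels <- labels[rownames(gm$calls)]
  }
  if (length(labels) != nrow(gm$calls)) {
    stop("`labels` must cover every individual")
  }
  groups <- sort(unique(as.character(labels)))
  r <- length(groups)
  if (r < 2) stop("F_ST needs at least 2 groups")
  x <- gm$calls / 2
  n_i <- vapply(groups, function(g) {
    colSums(!is.na(x[labels == g, , drop = FALSE]))
  }, numeric(ncol(x)))
  p_i <- vapply(groups, function(g) {
    colMeans(x[labels == g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(x)))
  if (ncol(gm$calls) == 1) {
    n_i <- matrix(n_i, nrow = 1, dimnames = list(NULL, groups))
    p_i <- matrix(p_i, nrow = 1, dimnames = list(NULL, groups))
  }
  estimable <- rowSums(n_i >= 2) == r
  n_tot <- rowSums(n_i)
  p_bar <- rowSums(n_i * p_i) / n_tot
  n_c <- (n_tot - rowSums(n_i^2) / n_tot) / (r - 1)
  msp <- rowSums(n_i * (p_i - p_bar)^2) / (r - 1)
  msg <- rowSums(n_i * p_i * (1 - p_i)) / rowSums(n_i - 1)
  denom <- msp + (n_c - 1) * msg
  theta <- ifelse(denom > 0, (msp - msg) / denom, NA_real_)
  theta[!estimable] <- NA_real_
  defined <- !is.na(theta)
  loci <- data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    p_bar = p_bar, n_c = n_c, msp = msp, msg = msg,
    theta = theta, defined = defined
  )
  colnames(p_i) <- paste0("p_", groups)
  colnames(n_i) <- paste0("n_", groups)
  loci <- cbind(loci, p_i, n_i)
  overall_val <- if (overall == "average") {
    mean(theta[defined])
  } else {
    sum(msp[defined] - msg[defined]) /
      sum(denom[defined])
  }
  structure(list(loci = loci, overall = overall_val,
                 overall_method = overall, groups = groups),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "Weir-Cockerham F_ST over %d groups: overall %.4f (%s of %d defined loci; %d undefined)\n",
    length(x$groups), x$overall,
    if (x$overall_method == "average") "simple average" else "ratio of sums",
    sum(x$loci$defined), sum(!x$loci$defined)
  ))
  invisible(x)
}

#' Moving-window scan of per-locus theta
#'
#' Per chromosome, a sliding window of `window_snps` consecutive
#' defined-theta loci (step 1); each window is anchored to its first and
#' last marker positions. Chromosomes with fewer defined loci than the
#' window are skipped (and listed in `skipped`). Windows never span
#' chromosome boundaries.
#'
#' @param fst an [fst_weir_cockerham()] result.
#' @param window_snps window width in SNPs (default 70).
#' @return object of class `fst_scan`: data.frame `windows` with `chrom`,
#'   `start_pos`, `end_pos`, `mean_theta`, plus `window_snps` and
#'   `skipped`.
#' @export
fst_window_scan <- function(fst, window_snps = 70) {
  stopifnot(inherits(fst, "fst_result"))
  if (window_snps < 1) stop("`window_snps` must be positive")
  loci <- fst$loci[fst$loci$defined, , drop = FALSE]
  if (nrow(loci) == 0) stop("no defined theta values to scan")
  out <- list()
  skipped <- character(0)
  for (ch in unique(loci$chrom)) {
    sub <- loci[loci$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    if (n < window_snps) {
      skipped <- c(skipped, ch)
      next
    }
    means <- as.numeric(stats::filter(sub$theta, rep(1 / window_snps,
                                                     window_snps),
                                      sides = 1))
    means <- means[window_snps:n]
    out[[ch]] <- data.frame(
      chrom = ch,
      start_pos = sub$pos[seq_len(n - window_snps + 1)],
      end_pos = sub$pos[window_snps:n],
      mean_theta = means,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    stop("every chromosome has fewer than ", window_snps, " defined loci")
  }
  structure(list(windows = do.call(rbind, out),
                 window_snps = window_snps, skipped = skipped),
            class = "fst_scan")
}

#' Top differentiated genomic regions
#'
#' Windows are visited in decreasing order of mean theta. A window
#' overlapping an already-formed region on the same chromosome is merged
#' into it (the region's span becomes the union; its reported mean stays
#' the maximum window mean, i.e. the first - highest - window that seeded
#' it); otherwise it seeds a new region. Finally the `n_regions` regions
#' with the highest means are returned, ordered by mean theta, ties by
#' (chromosome, position). Region size is last-marker minus first-marker
#' position, in bp.
#'
#' @param scan an [fst_window_scan()] result.
#' @param n_regions number of regions to report (default 4).
#' @return data.frame of regions: `chrom`, `first_marker`, `last_marker`,
#'   `region_size`, `mean_theta`.
#' @export
top_regions <- function(scan, n_regions = 4) {
  stopifnot(inherits(scan, "fst_scan"))
  w <- scan$windows
  if (nrow(w) == 0) stop("empty scan")
  ord <- order(-w$mean_theta, w$chrom, w$start_pos)
  w <- w[ord, , drop = FALSE]
  regions <- data.frame(chrom = character(0), first_marker = numeric(0),
                        last_marker = numeric(0), mean_theta = numeric(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(w))) {
    hit <- which(regions$chrom == w$chrom[i] &
                   regions$first_marker <= w$end_pos[i] &
                   regions$last_marker >= w$start_pos[i])
    if (length(hit) > 0) {
      h <- hit[1]
      regions$first_marker[h] <- min(regions$first_marker[h], w$start_pos[i])
      regions$last_marker[h] <- max(regions$last_marker[h], w$end_pos[i])
    } else {
      regions <- rbind(regions, data.frame(
        chrom = w$chrom[i], first_marker = w$start_pos[i],
        last_marker = w$end_pos[i], mean_theta = w$mean_theta[i],
        stringsAsFactors = FALSE
      ))
    }
  }
  if (n_regions > nrow(regions)) {
    warning("only ", nrow(regions), " regions available; returning all")
    n_regions <- nrow(regions)
  }
  regions <- regions[order(-regions$mean_theta, regions$chrom,
                           regions$first_marker), , drop = FALSE]
  regions <- regions[seq_len(n_regions), , drop = FALSE]
  regions$region_size <- regions$last_marker - regions$first_marker
  rownames(regions) <- NULL
  regions[, c("chrom", "first_marker", "last_marker", "region_size",
              "mean_theta")]
}

#' Read a gene annotation table
#'
#' Accepts GFF3 (gene features extracted via rtracklayer) or a 4+ column
#' TSV with header `chrom`, `start`, `end`, `gene_id` (optional
#' `description`). Intervals are 1-based inclusive.
#'
#' @param path annotation file.
#' @return data.frame with `chrom`, `start`, `end`, `gene_id`,
#'   `description`.
#' @export
read_gene_table <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::readGFF(path)
    g <- as.data.frame(g)
    g <- g[g$type == "gene", , drop = FALSE]
    id <- if ("ID" %in% names(g)) g$ID else g$Name
    desc <- if ("description" %in% names(g)) g$description
            else rep(NA_character_, nrow(g))
    data.frame(chrom = as.character(g$seqid), start = g$start, end = g$end,
               gene_id = as.character(id), description = as.character(desc),
               stringsAsFactors = FALSE)
  } else {
    g <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "gene_id")
    if (!all(need %in% names(g))) {
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    }
    if (!"description" %in% names(g)) g$description <- NA_character_
    g$chrom <- as.character(g$chrom)
    g[, c("chrom", "start", "end", "gene_id", "description")]
  }
}

#' Candidate genes near high-theta SNPs
#'
#' For every locus with defined theta at least `theta_min`, reports the
#' genes whose interval intersects the closed window
#' [pos - half_window, pos + half_window]. Distance is 0 when the SNP lies
#' inside the gene, otherwise the gap to the nearer gene end. Annotation
#' rows on chromosomes absent from the panel are skipped with a warning.
#'
#' @param fst an [fst_weir_cockerham()] result.
#' @param annotation a [read_gene_table()] data.frame.
#' @param half_window bp on either side of the SNP (default 10000).
#' @param theta_min minimum theta for a SNP to be queried.
#' @return data.frame of hits: `chrom`, `pos`, `theta`, `gene_id`,
#'   `description`, `distance_bp`.
#' @export
candidate_genes <- function(fst, annotation, half_window = 10000,
                            theta_min = 0.6) {
  stopifnot(inherits(fst, "fst_result"))
  loci <- fst$loci[fst$loci$defined & fst$loci$theta >= theta_min, ,
                   drop = FALSE]
  unknown <- setdiff(unique(annotation$chrom), unique(fst$loci$chrom))
  if (length(unknown) > 0) {
    warning("annotation chromosomes absent from the panel skipped: ",
            paste(unknown, collapse = ", "))
    annotation <- annotation[!(annotation$chrom %in% unknown), , drop = FALSE]
  }
  hits <- list()
  for (i in seq_len(nrow(loci))) {
    pos <- loci$pos[i]
    g <- annotation[annotation$chrom == loci$chrom[i] &
                      annotation$end >= pos - half_window &
                      annotation$start <= pos + half_window, , drop = FALSE]
    if (nrow(g) == 0) next
    dist <- ifelse(g$start <= pos & pos <= g$end, 0,
                   pmin(abs(pos - g$end), abs(g$start - pos)))
    hits[[length(hits) + 1]] <- data.frame(
      chrom = loci$chrom[i], pos = pos, theta = loci$theta[i],
      gene_id = g$gene_id, description = g$description,
      distance_bp = as.numeric(dist), stringsAsFactors = FALSE
    )
  }
  if (length(hits) == 0) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      theta = numeric(0), gene_id = character(0),
                      description = character(0), distance_bp = numeric(0)))
  }
  do.call(rbind, hits)
}

#' Write regions as BED
#'
#' Internal coordinates are 1-based closed; BED is 0-based half-open, so
#' `chromStart = first_marker - 1` and `chromEnd = last_marker`.
#'
#' @param regions a [top_regions()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    chromStart = regions$first_marker - 1,
    chromEnd = regions$last_marker,
    name = sprintf("region_%d", seq_len(nrow(regions))),
    score = round(1000 * regions$mean_theta)
  )
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
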