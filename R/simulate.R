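#' Configuration for the structured inbred-panel simulator
#'
#' Defaults describe a desk-scale panel with the statistical features of a
#' maize ex-PVP GBS panel: three diverged heterotic groups, strong
#' within-group pedigree relatedness ("recycled" lines bred by
#' cross-and-self from a small founder set), chromosome-scale linkage
#' disequilibrium, per-individual missingness coupled to distance from a
#' reference line (reference-alignment bias), a residual trickle of
#' heterozygous and tertiary calls, and two marker platforms whose site
#' sets only partially overlap.
#'
#' @param n_groups number of diverged subpopulations.
#' @param lines_per_group inbred lines emitted per group.
#' @param n_founders_per_group founder haplotypes drawn per group under the
#'   Balding-Nichols model; descendants are recombinant mosaics of these.
#' @param n_chrom,sites_per_chrom,chrom_length_bp genome shape: chromosomes,
#'   SNP sites per chromosome, and chromosome length in bp.
#' @param divergence_F Balding-Nichols divergence parameter in [0, 1);
#'   scalar or one value per group. Expected Weir-Cockerham F_ST of the
#'   panel equals this value.
#' @param recycle_generations rounds of within-group cross-and-self
#'   breeding after the founders. 0 means every line is an independent
#'   draw from its group's allele frequencies (no pedigree LD).
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (Poisson count, uniform breakpoints).
#' @param elite_weight geometric weight for parent sampling during
#'   recycling: the parent pool is sampled with probability proportional
#'   to `elite_weight^(rank - 1)`, so values below 1 concentrate ancestry
#'   in a few "elite" lines the way commercial programs recycle key
#'   inbreds; 1 gives uniform parent choice. Uneven founder contribution
#'   is what makes the panel LD-rich (allele frequencies within a group
#'   skew away from 50/50, and long shared haplotypes dominate).
#' @param miss_rate_mean,miss_rate_sd per-individual missing-call fraction:
#'   Normal(mean, sd) before the reference-bias term, clamped to [0, 0.95].
#' @param ref_bias_weight coefficient coupling an individual's missing rate
#'   to its allele-sharing distance from the designated reference line
#'   (founder 1 of group 1), mimicking reference-alignment bias.
#' @param het_rate,tertiary_rate fractions of observed calls replaced by
#'   heterozygous / third-allele calls, uniformly at random (they exist to
#'   exercise the QC rules).
#' @param platform_overlap fraction of the site union shared by the two
#'   emitted platforms, in (0, 1].
#' @param seed integer seed; identical seeds give bit-identical panels.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 3,
                       lines_per_group = 30,
                       n_founders_per_group = 4,
                       n_chrom = 10,
                       sites_per_chrom = 500,
                       chrom_length_bp = 2e8,
                       divergence_F = 0.15,
                       recycle_generations = 3,
                       recomb_rate = 2,
                       elite_weight = 0.3,
                       miss_rate_mean = 0.0622,
                       miss_rate_sd = 0.03,
                       ref_bias_weight = 0.1,
                       het_rate = 0.0025,
                       tertiary_rate = 0.001,
                       platform_overlap = 0.172,
                       seed = 1L) {
  cfg <- list(
    n_groups = as.integer(n_groups),
    lines_per_group = as.integer(lines_per_group),
    n_founders_per_group = as.integer(n_founders_per_group),
    n_chrom = as.integer(n_chrom),
    sites_per_chrom = as.integer(sites_per_chrom),
    chrom_length_bp = as.numeric(chrom_length_bp),
    divergence_F = as.numeric(divergence_F),
    recycle_generations = as.integer(recycle_generations),
    recomb_rate = as.numeric(recomb_rate),
    elite_weight = as.numeric(elite_weight),
    miss_rate_mean = as.numeric(miss_rate_mean),
    miss_rate_sd = as.numeric(miss_rate_sd),
    ref_bias_weight = as.numeric(ref_bias_weight),
    het_rate = as.numeric(het_rate),
    tertiary_rate = as.numeric(tertiary_rate),
    platform_overlap = as.numeric(platform_overlap),
    seed = as.integer(seed)
  )
  counts <- c("n_groups", "lines_per_group", "n_founders_per_group",
              "n_chrom", "sites_per_chrom")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop("`", nm, "` must be a positive count")
  }
  if (length(cfg$divergence_F) == 1) {
    cfg$divergence_F <- rep(cfg$divergence_F, cfg$n_groups)
  }
  if (length(cfg$divergence_F) != cfg$n_groups) {
    stop("`divergence_F` must be scalar or one value per group")
  }
  if (any(cfg$divergence_F < 0 | cfg$divergence_F >= 1)) {
    stop("`divergence_F` values must lie in [0, 1)")
  }
  fracs <- c("miss_rate_mean", "het_rate", "tertiary_rate")
  for (nm in fracs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop("`", nm, "` must lie in [0, 1]")
  }
  if (cfg$platform_overlap <= 0 || cfg$platform_overlap > 1) {
    stop("`platform_overlap` must lie in (0, 1]")
  }
  if (cfg$recycle_generations > 0) {
    if (cfg$lines_per_group < 2) {
      stop("`lines_per_group` must be >= 2 when `recycle_generations` > 0 ",
           "(crossing needs two distinct parents)")
    }
    if (cfg$n_founders_per_group < 2) {
      stop("`n_founders_per_group` must be >= 2 when `recycle_generations` > 0")
    }
  }
  if (cfg$recomb_rate < 0) stop("`recomb_rate` must be non-negative")
  if (cfg$elite_weight <= 0) stop("`elite_weight` must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# Internal: one recombinant gamete from two homozygous parent haplotypes.
# Haplotypes are 0/1 vectors over all sites; `chrom_index` maps sites to
# chromosomes; `pos` gives bp positions; crossovers ~ Poisson(recomb_rate)
# per chromosome with uniform breakpoints.
recombine_gamete <- function(hap_a, hap_b, chrom_index, pos, chrom_length,
                             recomb_rate) {
  gamete <- hap_a
  for (ch in unique(chrom_index)) {
    idx <- which(chrom_index == ch)
    n_co <- stats::rpois(1, recomb_rate)
    breaks <- sort(stats::runif(n_co, 0, chrom_length))
    # segment id per site; alternate parents, random starting parent
    seg <- findInterval(pos[idx], breaks)
    start <- stats::rbinom(1, 1, 0.5)
    from_b <- (seg + start) %% 2 == 1
    gamete[idx[from_b]] <- hap_b[idx[from_b]]
  }
  gamete
}

#' Simulate a structured panel of inbred lines
#'
#' Draws ancestral allele frequencies p ~ Uniform(0.1, 0.9), per-group
#' frequencies from the Balding-Nichols Beta(p(1-F)/F, (1-p)(1-F)/F)
#' distribution, founder haplotypes as independent Bernoulli draws, and
#' (optionally) descendant lines by repeated within-group crossing of two
#' parents, Poisson-recombining their haplotypes, and collapsing one
#' gamete to a homozygous line. Observed calls then receive residual
#' heterozygous/tertiary calls and structured missingness, and the panel is
#' split into two partially overlapping marker platforms.
#'
#' @param config a [sim_config()].
#' @return A list with components `platform1` and `platform2` (the two
#'   platform-restricted [genotype_matrix()] objects, individuals split
#'   between them) and `truth`, a `sim_truth` list holding the group
#'   labels, ancestral and per-group allele frequencies, the complete
#'   (pre-masking, pre-error) genotype matrix over all individuals and
#'   sites, the observed (post-error, post-masking) full matrix, the
#'   pedigree edge table, and the name of the reference line used for the
#'   missingness bias.
#' @export
simulate_panel <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  G <- config$n_groups
  L <- config$n_chrom * config$sites_per_chrom

  chrom <- rep(sprintf("%d", seq_len(config$n_chrom)),
               each = config$sites_per_chrom)
  pos <- unlist(lapply(seq_len(config$n_chrom), function(ch) {
    sort(sample.int(config$chrom_length_bp, config$sites_per_chrom))
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)

  p_anc <- stats::runif(L, 0.1, 0.9)
  group_p <- matrix(NA_real_, L, G)
  for (g in seq_len(G)) {
    f <- config$divergence_F[g]
    if (f == 0) {
      group_p[, g] <- p_anc
    } else {
      a <- p_anc * (1 - f) / f
      b <- (1 - p_anc) * (1 - f) / f
      group_p[, g] <- stats::rbeta(L, a, b)
    }
  }

  # founders and (optionally) recycled descendant lines, per group
  haps <- matrix(0L, 0, L)
  labels <- character(0)
  pedigree <- data.frame(child = character(0), parent1 = character(0),
                         parent2 = character(0), generation = integer(0),
                         stringsAsFactors = FALSE)
  for (g in seq_len(G)) {
    if (config$recycle_generations == 0) {
      n_draw <- config$lines_per_group
      pool <- t(vapply(seq_len(n_draw), function(i) {
        stats::rbinom(L, 1, group_p[, g])
      }, integer(L)))
      pool_names <- sprintf("G%d_L%02d", g, seq_len(n_draw))
    } else {
      n_f <- config$n_founders_per_group
      pool <- t(vapply(seq_len(n_f), function(i) {
        stats::rbinom(L, 1, group_p[, g])
      }, integer(L)))
      pool_names <- sprintf("G%d_F%02d", g, seq_len(n_f))
      for (gen in seq_len(config$recycle_generations)) {
        kids <- matrix(0L, config$lines_per_group, L)
        kid_names <- if (gen == config$recycle_generations) {
          sprintf("G%d_L%02d", g, seq_len(config$lines_per_group))
        } else {
          sprintf("G%d_g%d_%02d", g, gen, seq_len(config$lines_per_group))
        }
        w <- config$elite_weight^(seq_len(nrow(pool)) - 1)
        for (k in seq_len(config$lines_per_group)) {
          par <- sample.int(nrow(pool), 2, prob = w)
          kids[k, ] <- recombine_gamete(pool[par[1], ], pool[par[2], ],
                                        chrom, pos, config$chrom_length_bp,
                                        config$recomb_rate)
          pedigree <- rbind(pedigree, data.frame(
            child = kid_names[k], parent1 = pool_names[par[1]],
            parent2 = pool_names[par[2]], generation = gen,
            stringsAsFactors = FALSE
          ))
        }
        pool <- kids
        pool_names <- kid_names
      }
    }
    rownames(pool) <- pool_names
    haps <- rbind(haps, pool)
    labels <- c(labels, rep(sprintf("G%d", g), nrow(pool)))
  }
  names(labels) <- rownames(haps)
  n_ind <- nrow(haps)

  complete_calls <- haps * 2L
  complete <- genotype_matrix(complete_calls, sites)

  # observed copy: residual het / tertiary calls, then structured missingness
  observed <- complete_calls
  n_cells <- length(observed)
  if (config$het_rate > 0) {
    n_het <- round(config$het_rate * n_cells)
    observed[sample.int(n_cells, n_het)] <- 1L
  }
  if (config$tertiary_rate > 0) {
    n_ter <- round(config$tertiary_rate * n_cells)
    observed[sample.int(n_cells, n_ter)] <- 3L
  }
  ref_line <- rownames(haps)[1]
  dist_to_ref <- colMeans(abs(t(haps) - haps[1, ]))
  miss_rate <- stats::rnorm(n_ind, config$miss_rate_mean, config$miss_rate_sd) +
    config$ref_bias_weight * dist_to_ref
  miss_rate <- pmin(pmax(miss_rate, 0), 0.95)
  for (i in seq_len(n_ind)) {
    hit <- stats::runif(L) < miss_rate[i]
    observed[i, hit] <- NA_integer_
  }

  # two platforms: shared sites plus platform-private halves of the rest
  n_shared <- round(config$platform_overlap * L)
  if (n_shared < 1) n_shared <- 1L
  shared <- sort(sample.int(L, n_shared))
  rest <- setdiff(seq_len(L), shared)
  priv1 <- sort(sample(rest, floor(length(rest) / 2)))
  priv2 <- sort(setdiff(rest, priv1))
  ind1 <- seq_len(n_ind) %% 2 == 1
  sites1 <- sort(c(shared, priv1))
  sites2 <- sort(c(shared, priv2))
  gm_full <- genotype_matrix(observed, sites)
  platform1 <- gm_full[which(ind1), sites1]
  platform1$provenance <- rep("platform1", sum(ind1))
  platform2 <- gm_full[which(!ind1), sites2]
  platform2$provenance <- rep("platform2", sum(!ind1))

  truth <- structure(list(
    group_label = labels,
    ancestral_p = p_anc,
    group_p = group_p,
    complete = complete,
    observed = gm_full,
    pedigree = pedigree,
    ref_line = ref_line,
    dist_to_ref = stats::setNames(dist_to_ref, rownames(haps)),
    miss_rate = stats::setNames(miss_rate, rownames(haps)),
    shared_sites = shared,
    config = config
  ), class = "sim_truth")

  list(platform1 = platform1, platform2 = platform2, truth = truth)
}

#' Simulate a haplotype-copying panel with known LD decay
#'
#' A single-chromosome generator used to calibrate linkage-disequilibrium
#' decay estimation. Alleles follow a copying chain along the chromosome:
#' the allele at each site copies the previous site's allele with
#' probability exp(-gap / lambda) and otherwise is a fresh Bernoulli(0.5)
#' draw. Under this model the true correlation between sites at distance d
#' is exp(-d / lambda), so true r^2(d) = exp(-2d / lambda) and r^2 crosses
#' 0.2 at exactly `r2_02_bp` when lambda = 2 * r2_02_bp / log(5).
#'
#' @param n_lines number of inbred lines.
#' @param n_sites number of sites on the single chromosome.
#' @param chrom_length_bp chromosome length in bp (positions uniform).
#' @param r2_02_bp distance (bp) at which true r^2 equals 0.2.
#' @param seed integer seed.
#' @return A complete \{0,2\} [genotype_matrix()] with attribute
#'   `lambda_bp`, the copying length scale.
#' @export
simulate_ld_panel <- function(n_lines = 200, n_sites = 400,
                              chrom_length_bp = 2e5, r2_02_bp = 1000,
                              seed = 1L) {
  set.seed(seed)
  lambda <- 2 * r2_02_bp / log(5)
  pos <- sort(sample.int(chrom_length_bp, n_sites))
  haps <- matrix(0L, n_lines, n_sites)
  haps[, 1] <- stats::rbinom(n_lines, 1, 0.5)
  for (j in 2:n_sites) {
    rho <- exp(-(pos[j] - pos[j - 1]) / lambda)
    copy <- stats::runif(n_lines) < rho
    fresh <- stats::rbinom(n_lines, 1, 0.5)
    haps[, j] <- ifelse(copy, haps[, j - 1], fresh)
  }
  rownames(haps) <- sprintf("L%03d", seq_len(n_lines))
  sites <- data.frame(chrom = "1", pos = pos, ref = "A", alt = "C",
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(haps * 2L, sites)
  attr(gm, "lambda_bp") <- lambda
  gm
}

#' Mask a fraction of non-missing calls
#'
#' Sets exactly `round(fraction * n_non_missing)` randomly chosen
#' non-missing cells to missing, returning both the masked matrix and the
#' index set so the original values can be scored after imputation.
#'
#' @param gm a [genotype_matrix()].
#' @param fraction fraction of currently non-missing cells to mask, in
#'   (0, 1).
#' @param seed integer seed.
#' @return list with `gm` (masked matrix), `mask` (two-column matrix of
#'   row/column indices of masked cells) and `values` (the original calls
#'   at those cells).
#' @export
mask_genotypes <- function(gm, fraction, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)")
  avail <- which(!is.na(gm$calls))
  if (length(avail) == 0) stop("no non-missing cells available to mask")
  n_mask <- round(fraction * length(avail))
  if (n_mask == 0) {
    stop("`fraction` too small: round(fraction * non-missing cells) is 0, ",
         "nothing to mask")
  }
  set.seed(seed)
  chosen <- sample(avail, n_mask)
  values <- gm$calls[chosen]
  masked <- gm
  masked$calls[chosen] <- NA_integer_
  mask <- cbind(row = ((chosen - 1) %% nrow(gm$calls)) + 1,
                col = ((chosen - 1) %/% nrow(gm$calls)) + 1)
  list(gm = masked, mask = mask, values = values)
}
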