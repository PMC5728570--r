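# Independent oracles and fixture builders used across the suite. Each
# oracle is a deliberately naive re-implementation kept separate from the
# package's code path.

# build a genotype_matrix from a plain matrix of call codes
make_gm <- function(calls, chrom = NULL, pos = NULL, ref = "A", alt = "C") {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("I%02d", seq_len(nrow(calls)))
  }
  n <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  genotype_matrix(calls, data.frame(chrom = chrom, pos = pos,
                                    ref = rep_len(ref, n),
                                    alt = rep_len(alt, n),
                                    stringsAsFactors = FALSE))
}

# haplotype-count r^2: D^2 / (pA pa pB pb) from {0,2} call vectors
r2_haplotype_oracle <- function(x, y) {
  pA <- mean(x == 2)
  pB <- mean(y == 2)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- mean(x == 2 & y == 2)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Nei standard distance between two {0,2} call vectors, straight from the
# definition (per-locus identity sums, no vectorized shortcuts)
nei_oracle <- function(x, y) {
  fx <- x / 2; fy <- y / 2
  jxy <- mean(fx * fy + (1 - fx) * (1 - fy))
  jx <- mean(fx^2 + (1 - fx)^2)
  jy <- mean(fy^2 + (1 - fy)^2)
  -log(jxy / sqrt(jx * jy))
}

# naive O(n^3) Ward (ward.D dialect) agglomeration: full re-scan of the
# active distance matrix at every step, Lance-Williams update with Ward
# coefficients. Returns the n-1 merge heights in merge order.
ward_oracle_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    idx <- which(active)
    for (a in idx) for (b in idx) {
      if (a < b && D[a, b] < best_d) { best_d <- D[a, b]; best <- c(a, b) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- best_d
    ni <- sizes[i]; nj <- sizes[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
  }
  heights
}

# per-locus haploid Weir-Cockerham theta computed scalar-by-scalar
wc_theta_oracle <- function(calls_col, labels) {
  groups <- sort(unique(labels))
  r <- length(groups)
  n_i <- p_i <- numeric(r)
  for (g in seq_len(r)) {
    v <- calls_col[labels == groups[g]]
    v <- v[!is.na(v)]
    n_i[g] <- length(v)
    p_i[g] <- mean(v == 2)
  }
  if (any(n_i < 2)) return(NA_real_)
  n_tot <- sum(n_i)
  p_bar <- sum(n_i * p_i) / n_tot
  n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  msp <- sum(n_i * (p_i - p_bar)^2) / (r - 1)
  msg <- sum(n_i * p_i * (1 - p_i)) / sum(n_i - 1)
  denom <- msp + (n_c - 1) * msg
  if (denom <= 0) return(NA_real_)
  (msp - msg) / denom
}
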