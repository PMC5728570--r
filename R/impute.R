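# Forward-only Markov-chain imputation for haploid-coded inbred
# genotypes. The model is a first-order chain along each chromosome over
# the states {0, 2}: per-site marginal state frequencies plus one 2x2
# transition table per adjacent site pair, estimated from the individuals
# non-missing at both sites of the pair and smoothed with a pseudocount.
# Decoding is a deterministic greedy forward argmax: scanning left to
# right, a missing call before any observed state takes the site-marginal
# argmax, and every later missing call takes the argmax of the transition
# row conditioned on the most recent (observed or imputed) state. Ties
# break toward the major allele.

#' Fit a forward Markov model of haploid genotype states
#'
#' @param gm post-QC [genotype_matrix()] containing only \{0, 2, NA\}.
#' @param pseudocount additive smoothing constant for both transition and
#'   marginal counts (default 0.5).
#' @return object of class `markov_model`: per chromosome, per-site
#'   marginal probabilities of state 0 and, for each adjacent site pair, a
#'   2x2 row-stochastic transition table over \{0, 2\}. Chromosomes with a
#'   single site carry marginals only.
#' @export
fit_markov <- function(gm, pseudocount = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_haploid(gm, "imputation input")
  a0 <- !is.na(gm$calls) & gm$calls == 0L
  a2 <- !is.na(gm$calls) & gm$calls == 2L
  chroms <- unique(gm$sites$chrom)
  per_chrom <- lapply(chroms, function(ch) {
    j <- which(gm$sites$chrom == ch)
    n0 <- colSums(a0[, j, drop = FALSE])
    n2 <- colSums(a2[, j, drop = FALSE])
    p0 <- (n0 + pseudocount) / (n0 + n2 + 2 * pseudocount)
    trans <- NULL
    if (length(j) >= 2) {
      from0 <- a0[, j[-length(j)], drop = FALSE]
      from2 <- a2[, j[-length(j)], drop = FALSE]
      to0 <- a0[, j[-1], drop = FALSE]
      to2 <- a2[, j[-1], drop = FALSE]
      c00 <- colSums(from0 & to0); c02 <- colSums(from0 & to2)
      c20 <- colSums(from2 & to0); c22 <- colSums(from2 & to2)
      # rows: from-state {0,2}; cols: to-state {0,2}
      p00 <- (c00 + pseudocount) / (c00 + c02 + 2 * pseudocount)
      p20 <- (c20 + pseudocount) / (c20 + c22 + 2 * pseudocount)
      trans <- list(p00 = p00, p20 = p20)
    }
    list(sites = j, p0 = p0, trans = trans)
  })
  names(per_chrom) <- chroms
  structure(list(
    chrom = per_chrom,
    site_keys = site_key(gm$sites),
    pseudocount = pseudocount
  ), class = "markov_model")
}

#' Impute missing calls by a greedy forward scan
#'
#' @param gm post-QC [genotype_matrix()] with the same site list the model
#'   was fitted on.
#' @param model a [fit_markov()] model.
#' @return a complete [genotype_matrix()]; observed calls are never
#'   altered. The scan is deterministic (argmax decoding with ties broken
#'   toward the major allele), so no randomness is involved.
#' @export
impute_forward <- function(gm, model) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(model, "markov_model"))
  assert_haploid(gm, "imputation input")
  if (!identical(site_key(gm$sites), model$site_keys)) {
    stop("site list of `gm` does not match the fitted model")
  }
  calls <- gm$calls
  n_ind <- nrow(calls)
  for (ch in names(model$chrom)) {
    m <- model$chrom[[ch]]
    # until an individual shows an observed call on this chromosome, its
    # missing calls carry no chain information and take the site marginal;
    # once anchored, the transition row from the most recent (observed or
    # imputed) state decides
    anchored <- rep(FALSE, n_ind)
    prev <- rep(0L, n_ind)
    for (k in seq_along(m$sites)) {
      j <- m$sites[k]
      obs <- calls[, j]
      miss <- is.na(obs)
      if (any(miss)) {
        chained <- miss & anchored
        if (any(chained)) {
          p_to0 <- ifelse(prev[chained] == 0L, m$trans$p00[k - 1],
                          m$trans$p20[k - 1])
          calls[chained, j] <- ifelse(p_to0 >= 0.5, 0L, 2L)
        }
        cold <- miss & !anchored
        if (any(cold)) {
          calls[cold, j] <- if (m$p0[k] >= 0.5) 0L else 2L
        }
      }
      anchored <- anchored | !miss
      prev <- calls[, j]
    }
  }
  out <- gm
  out$calls <- calls
  out
}

#' Masked-data estimate of imputation accuracy
#'
#' Mirrors the standard protocol for GBS panels: starting from a complete
#' matrix, mask a fraction of cells at random, refit the Markov model on
#' the masked data (the realistic situation - the model never sees the
#' truth), impute, and score the fraction of masked cells recovered
#' exactly. Repeated `reps` times with fresh mask draws.
#'
#' @param gm_complete a complete \{0, 2\} [genotype_matrix()].
#' @param fraction fraction of cells to mask per repetition (default
#'   0.0622).
#' @param reps number of repetitions (default 100).
#' @param seed integer seed; repetition r uses mask seed `seed + r`.
#' @param pseudocount passed to [fit_markov()].
#' @return list with `mean_accuracy`, `per_rep` (numeric vector of
#'   per-repetition accuracies) and `baseline`, the accuracy a
#'   marginal-argmax (major-allele) imputer would achieve on the same
#'   panel, for reference.
#' @export
estimate_accuracy <- function(gm_complete, fraction = 0.0622, reps = 100,
                              seed = 1L, pseudocount = 0.5) {
  stopifnot(inherits(gm_complete, "genotype_matrix"))
  if (!is_complete(gm_complete)) {
    stop("`gm_complete` must contain no missing calls")
  }
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)")
  if (reps < 1) stop("`reps` must be >= 1")
  per_rep <- numeric(reps)
  for (r in seq_len(reps)) {
    masked <- mask_genotypes(gm_complete, fraction, seed = seed + r)
    model <- fit_markov(masked$gm, pseudocount = pseudocount)
    imputed <- impute_forward(masked$gm, model)
    per_rep[r] <- mean(imputed$calls[masked$mask] == masked$values)
  }
  # marginal-argmax baseline: per site, frequency of the majority state
  p2 <- colMeans(gm_complete$calls == 2L)
  baseline <- mean(pmax(p2, 1 - p2))
  list(mean_accuracy = mean(per_rep), per_rep = per_rep, baseline = baseline)
}
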