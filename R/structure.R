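# Population-structure stack: PCA of the genotype matrix, Nei's standard
# genetic distance between inbred lines, Ward agglomerative clustering on
# that distance, tree cutting into k groups, and Newick export.

#' Principal component analysis of a genotype matrix
#'
#' Columns (sites) are centered (and optionally scaled) and the
#' individuals x sites matrix is decomposed with [stats::prcomp()].
#'
#' @param gm a fully imputed [genotype_matrix()].
#' @param center,scale. centering/scaling flags passed to prcomp; default
#'   centered, unscaled calls.
#' @return object of class `panel_pca`: `scores` (individuals x
#'   components), `eigenvalues` (variances of the components,
#'   non-increasing), `pct_var` (percent variance explained per component,
#'   summing to 100, or all `NA` with `degenerate = TRUE` when total
#'   variance is zero) and `advisory_k`, the elbow suggestion (largest
#'   second difference of the eigenvalue profile) - advisory only, the
#'   number of groups is always the analyst's decision.
#' @export
pca_genotypes <- function(gm, center = TRUE, scale. = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is_complete(gm)) stop("PCA input must be fully imputed")
  if (nrow(gm$calls) < 2) stop("PCA needs at least 2 individuals")
  x <- gm$calls
  storage.mode(x) <- "double"
  if (scale.) {
    keep <- apply(x, 2, stats::sd) > 0
    x <- x[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = center, scale. = scale.)
  ev <- pc$sdev^2
  total <- sum(ev)
  degenerate <- total <= .Machine$double.eps * length(ev)
  pct <- if (degenerate) rep(NA_real_, length(ev)) else 100 * ev / total
  advisory_k <- NA_integer_
  if (!degenerate && length(ev) >= 3) {
    d2 <- ev[seq_len(length(ev) - 2)] - 2 * ev[seq(2, length(ev) - 1)] +
      ev[seq(3, length(ev))]
    advisory_k <- which.max(d2) + 1L
  }
  structure(list(
    scores = pc$x,
    eigenvalues = ev,
    pct_var = pct,
    degenerate = degenerate,
    advisory_k = advisory_k,
    center = center, scale = scale.
  ), class = "panel_pca")
}

#' Nei's standard genetic distance between inbred lines
#'
#' For a pair of individuals X and Y with per-locus allele frequencies
#' X_u, Y_u (0 or 1 for a homozygous inbred), the normalized gene identity
#' is I = J_XY / sqrt(J_X * J_Y) with J_XY the mean over loci of
#' sum_u X_u Y_u, and J_X, J_Y the mean squared frequencies; the distance
#' is D = -ln I. For complete homozygous data J_X = J_Y = 1 and J_XY is
#' simply the fraction of loci with matching alleles. Mean-over-loci
#' normalization makes D invariant to duplicating loci.
#'
#' @param gm a fully imputed \{0, 2\} [genotype_matrix()].
#' @return object of class `nei_dist`: a symmetric matrix with zero
#'   diagonal and individual names as dimnames. Pairs sharing no allele at
#'   any locus get `Inf` and are flagged in attribute `infinite_pairs`.
#' @export
nei_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_haploid(gm, "Nei distance input")
  if (!is_complete(gm)) stop("Nei distance input must be fully imputed")
  x <- gm$calls / 2            # minor-allele frequency per line, 0 or 1
  L <- ncol(x)
  jxy <- (x %*% t(x) + (1 - x) %*% t(1 - x)) / L
  jx <- diag(jxy)
  denom <- sqrt(outer(jx, jx))
  i_norm <- jxy / denom
  d <- -log(i_norm)
  d[i_norm <= 0] <- Inf
  diag(d) <- 0
  d[d < 0] <- 0                # clip numeric fuzz at identical pairs
  dimnames(d) <- list(rownames(gm$calls), rownames(gm$calls))
  inf_pairs <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  structure(d, class = c("nei_dist", "matrix"), infinite_pairs = inf_pairs)
}

#' Ward agglomerative clustering of a distance matrix
#'
#' Runs [stats::hclust()] on the supplied dissimilarities. The default
#' dialect is the historical `ward.D` (Lance-Williams recurrence with Ward
#' coefficients applied directly to the supplied dissimilarities), which
#' is what classic hclust-based pipelines feeding a Nei matrix used;
#' `ward.D2` (squared-dissimilarity update) is available by flag. Height
#' inversions cannot occur with Ward on a metric input but are checked and
#' recorded.
#'
#' @param dm a `nei_dist` or any symmetric dissimilarity matrix / `dist`.
#' @param dialect `"ward.D"` (default) or `"ward.D2"`.
#' @return an [stats::hclust()] tree with attributes `dialect` and
#'   `inversions` (number of decreasing adjacent merge heights).
#' @export
ward_cluster <- function(dm, dialect = c("ward.D", "ward.D2")) {
  dialect <- match.arg(dialect)
  d <- stats::as.dist(dm)
  if (any(!is.finite(d))) {
    stop("distance matrix contains non-finite entries; resolve infinite-",
         "distance pairs before clustering")
  }
  if (attr(d, "Size") < 2) stop("need at least 2 individuals to cluster")
  tree <- stats::hclust(d, method = dialect)
  attr(tree, "dialect") <- dialect
  attr(tree, "inversions") <- sum(diff(tree$height) < 0)
  tree
}

#' Cut a tree into k groups
#'
#' Removes the k - 1 highest merges ([stats::cutree()]); group numbers
#' follow first appearance in leaf (input) order, so the labelling is
#' deterministic. Exactly tied merge heights at the cut boundary are
#' resolved by merge order, i.e. later merges are cut first.
#'
#' @param tree an [ward_cluster()] / hclust tree.
#' @param k number of groups, 1 <= k <= number of leaves.
#' @return named integer vector of group labels.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("`k` must lie in [1, ", n, "]")
  stats::cutree(tree, k = k)
}

# Internal: newick-quote a label if it needs it
quote_label <- function(x) {
  needs <- grepl("[][ \t(),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Export an hclust tree as Newick text
#'
#' Branch lengths derive from merge heights: each branch is the parent's
#' merge height minus the child's (leaves sit at height 0), so leaf-to-
#' leaf path lengths equal twice the height of the pair's lowest common
#' merge. Labels containing spaces or Newick metacharacters are
#' single-quoted.
#'
#' @param tree an hclust tree.
#' @return a single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  labels <- quote_label(tree$labels)
  heights <- tree$height
  node_str <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.10g", labels[-i], parent_h)
    } else {
      left <- node_str(tree$merge[i, 1], heights[i])
      right <- node_str(tree$merge[i, 2], heights[i])
      sprintf("(%s,%s):%.10g", left, right, parent_h - heights[i])
    }
  }
  root <- nrow(tree$merge)
  left <- node_str(tree$merge[root, 1], heights[root])
  right <- node_str(tree$merge[root, 2], heights[root])
  sprintf("(%s,%s);", left, right)
}

#' Write a tree as a Newick file
#' @param tree an hclust tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}
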