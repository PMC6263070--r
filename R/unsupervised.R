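#' Correlation distance between rows or columns
#'
#' `d(i, j) = 1 - Pearson(i, j)`, the standard metric for expression
#' heatmaps: 0 for identical profiles, 2 for perfectly anti-correlated ones.
#'
#' @param x An [expression_matrix()] or numeric matrix.
#' @param axis `"samples"` (columns, default) or `"genes"` (rows).
#' @return A `dist` object.
#' @export
correlation_distance <- function(x, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  v <- unclass(x)
  if (axis == "samples") v <- t(v)
  if (nrow(v) < 2) rlang::abort("Need >= 2 items to compute distances.")
  vars <- apply(v, 1, stats::var)
  zero <- rownames(v)[vars == 0]
  if (length(zero) > 0) {
    rlang::abort(paste0("Zero-variance item(s): ", paste(zero, collapse = ", ")))
  }
  stats::as.dist(1 - stats::cor(t(v)))
}

#' Agglomerative hierarchical clustering
#'
#' Thin, validated wrapper around [stats::hclust()]; the returned tree keeps
#' the merge history, heights and leaf labels needed to redraw dendrograms.
#'
#' @param distances A `dist` object.
#' @param linkage Linkage criterion: `"average"` (default), `"complete"` or
#'   `"single"`.
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(distances, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(distances, "dist")) rlang::abort("`distances` must be a dist object.")
  stats::hclust(distances, method = linkage)
}

#' Cut a cluster tree into k groups
#'
#' @param tree An `hclust` tree.
#' @param k Number of groups, `1 <= k <=` number of leaves.
#' @return Integer group labels named by leaf.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels %||% tree$order)
  if (k < 1 || k > n) {
    rlang::abort(sprintf("k = %d outside 1..%d (number of leaves).", k, n))
  }
  stats::cutree(tree, k = k)
}

#' Cluster samples on a gene-set-restricted matrix
#'
#' The "supervised clustering" pattern used for heatmaps of a chosen gene
#' set: restrict the gene axis to the set, then cluster samples unsupervised
#' on that restriction.
#'
#' @param x An [expression_matrix()].
#' @param genes Character vector of gene ids to restrict to.
#' @param k Number of sample groups.
#' @param linkage Passed to [hierarchical_cluster()].
#' @param distance `"correlation"` (profile shape; blind to uniform
#'   per-sample shifts) or `"euclidean"` (sensitive to overall level — the
#'   right choice when the signal of interest is a coordinated up/down shift
#'   of the whole set, as for infiltration stratification).
#' @param standardize Z-score each gene across samples before computing
#'   distances, so every gene contributes comparably.
#' @return A list: `labels` (named integer vector) and `tree`.
#' @export
cluster_samples_on_set <- function(x, genes, k, linkage = "average",
                                   distance = c("correlation", "euclidean"),
                                   standardize = FALSE) {
  distance <- match.arg(distance)
  genes <- intersect(genes, rownames(x))
  if (length(genes) == 0) rlang::abort("No genes of the set are in the matrix.")
  sub <- unclass(x)[genes, , drop = FALSE]
  if (standardize) {
    sds <- apply(sub, 1, stats::sd)
    sub <- sub[sds > 0, , drop = FALSE]
    sub <- (sub - rowMeans(sub)) / sds[sds > 0]
  }
  d <- if (distance == "correlation") {
    correlation_distance(sub, axis = "samples")
  } else {
    stats::dist(t(sub))
  }
  tree <- hierarchical_cluster(d, linkage)
  list(labels = cut_tree(tree, k), tree = tree)
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
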