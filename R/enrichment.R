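#' Single-sample gene-set enrichment score
#'
#' A rank-based running-sum statistic: genes are ranked by descending
#' expression within the sample (ties broken by gene id), the sum gains
#' `1 / |S|` at each member gene and loses `1 / (|U| - |S|)` elsewhere, and
#' the score is the signed maximum-magnitude deviation — an unweighted
#' Kolmogorov-Smirnov statistic in \[-1, 1\]. +1 means the whole set sits at
#' the very top of the sample's ranking, -1 at the very bottom. Because only
#' ranks enter, the score is invariant to any strictly monotone transform of
#' the sample's expression values.
#'
#' @param expr_values Named numeric vector: one sample's expression, names
#'   are the gene universe.
#' @param geneset Character vector of member gene ids.
#' @return A single score in \[-1, 1\].
#' @export
sample_enrichment_score <- function(expr_values, geneset) {
  genes <- names(expr_values)
  if (is.null(genes)) rlang::abort("expr_values must be named by gene id.")
  members <- genes %in% geneset
  n_in <- sum(members)
  n_out <- length(genes) - n_in
  if (n_in == 0) rlang::abort("Gene set does not intersect the universe.")
  if (n_out == 0) rlang::abort("Gene set equals the whole universe; score undefined.")
  ord <- order(-expr_values, genes)
  steps <- ifelse(members[ord], 1 / n_in, -1 / n_out)
  running <- cumsum(steps)
  running[which.max(abs(running))]
}

#' Enrichment-score matrix over sets and samples
#'
#' @param x A log2 [expression_matrix()].
#' @param genesets A [gene_sets()] collection.
#' @return A sets x samples numeric matrix of class `enrichment_profile`.
#' @export
enrichment_matrix <- function(x, genesets) {
  stopifnot(inherits(genesets, "gene_sets"))
  v <- unclass(x)
  scores <- vapply(seq_len(ncol(v)), function(j) {
    col <- v[, j]
    names(col) <- rownames(v)
    vapply(genesets, function(s) sample_enrichment_score(col, s), numeric(1))
  }, numeric(length(genesets)))
  scores <- matrix(scores, nrow = length(genesets),
                   dimnames = list(names(genesets), colnames(v)))
  structure(scores, class = c("enrichment_profile", "matrix", "array"))
}

#' @export
#' @method tidy enrichment_profile
tidy.enrichment_profile <- function(x, ...) {
  tibble::tibble(
    set = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    score = as.vector(unclass(x))
  )
}

#' @rdname enrichment_matrix
#' @param object An `enrichment_profile`.
#' @param annotation Optional annotation tibble to order samples by arm.
#' @param ... Unused.
#' @export
#' @method autoplot enrichment_profile
autoplot.enrichment_profile <- function(object, annotation = NULL, ...) {
  df <- tidy(object)
  if (!is.null(annotation)) {
    df <- dplyr::left_join(df, annotation, by = c(sample = "sample_id"))
    df$sample <- stats::reorder(df$sample, as.integer(factor(df$arm)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$set,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' One-way ANOVA of enrichment scores across treatment arms
#'
#' Textbook one-way F per gene set, comparing enrichment scores across arms,
#' with BH adjustment across sets.
#'
#' @param profile An `enrichment_profile` (sets x samples).
#' @param annotation Annotation tibble pairing samples to arms.
#' @return A tibble: `set`, `f`, `p`, `q`.
#' @export
groupwise_anova <- function(profile, annotation) {
  ann <- annotation[match(colnames(profile), annotation$sample_id), , drop = FALSE]
  if (any(is.na(ann$arm))) rlang::abort("Profile samples missing from annotation.")
  counts <- table(ann$arm)
  if (length(counts) < 2 || any(counts < 2)) {
    rlang::abort("Need >= 2 arms with >= 2 samples each.")
  }
  res <- rowwise_f(unclass(profile), ann$arm)
  tibble::tibble(set = rownames(profile), f = unname(res$f),
                 p = unname(res$p), q = bh_fdr(unname(res$p)))
}

#' Preranked gene-set enrichment with a random-set permutation null
#'
#' Scores a gene set against an externally ranked gene list (for example a
#' contrast's genes ordered by log2 fold-change) and compares the observed
#' running-sum score with `n_perm` random member sets of the same size drawn
#' from the list. The p-value is two-sided on |score| with the add-one
#' convention, so it can never be smaller than `1 / (n_perm + 1)`.
#'
#' @param ranked_genes Character vector, strictly ordered best-to-worst.
#' @param geneset Member gene ids (must all be drawn from a universe no
#'   larger than the list).
#' @param n_perm Number of random sets (>= 1).
#' @param seed Integer seed.
#' @return A tibble with `score`, `p`, `n_perm`.
#' @export
preranked_enrichment <- function(ranked_genes, geneset, n_perm = 1000, seed = 1) {
  if (anyDuplicated(ranked_genes)) rlang::abort("Ranked list must be strictly ordered (no duplicates).")
  size <- length(intersect(geneset, ranked_genes))
  if (size == 0) rlang::abort("Gene set does not intersect the ranked list.")
  if (size >= length(ranked_genes)) rlang::abort("Gene set must be smaller than the list.")
  if (n_perm < 1) rlang::abort("n_perm must be >= 1.")
  # fake descending "expression" = reversed positions, so rank order is the list order
  pseudo <- rev(seq_along(ranked_genes))
  names(pseudo) <- ranked_genes
  observed <- sample_enrichment_score(pseudo, geneset)
  null_scores <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sample_enrichment_score(pseudo, sample(ranked_genes, size))
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_scores) >= abs(observed))) / (n_perm + 1)
  tibble::tibble(score = observed, p = p, n_perm = as.integer(n_perm))
}
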