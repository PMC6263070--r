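#' Per-sample module score of a gene set
#'
#' Each member gene is z-scored across samples; the score is the mean z over
#' members, so scores average ~0 across the cohort. Zero-variance member
#' genes carry no information and are dropped with a warning.
#'
#' @param x A log2 [expression_matrix()] with >= 2 samples.
#' @param geneset Character vector of member gene ids.
#' @return Named numeric vector of per-sample scores.
#' @export
module_score <- function(x, geneset) {
  if (ncol(x) < 2) rlang::abort("Need >= 2 samples to z-score genes.")
  genes <- intersect(geneset, rownames(x))
  if (length(genes) == 0) rlang::abort("Gene set does not intersect the matrix.")
  v <- unclass(x)[genes, , drop = FALSE]
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(paste0("Dropping zero-variance gene(s): ",
                       paste(genes[sds == 0], collapse = ", ")))
    v <- v[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(v) == 0) rlang::abort("All member genes have zero variance.")
  }
  z <- (v - rowMeans(v)) / sds
  colMeans(z)
}

#' Stratify a cohort into ordered infiltration groups
#'
#' Samples are clustered hierarchically on the matrix restricted to a core
#' immune gene set — euclidean distance on gene-standardized values, because
#' infiltration moves the whole set up or down together and a correlation
#' metric is blind to exactly that coordinated shift — and the resulting
#' k-cut groups are relabelled low -> high by ascending mean immune module
#' score.
#'
#' @param x A log2 [expression_matrix()].
#' @param immune_set Core immune gene ids.
#' @param k Number of groups (default 3: low / medium / high).
#' @param linkage Linkage for the clustering.
#' @return A tibble: `sample_id`, `immune_score`, `group` (ordered factor;
#'   `low`/`medium`/`high` when k = 3).
#' @export
stratify_infiltration <- function(x, immune_set, k = 3, linkage = "average") {
  if (k < 2) rlang::abort("k must be >= 2.")
  if (k > ncol(x)) rlang::abort("k exceeds the number of samples.")
  cl <- cluster_samples_on_set(x, immune_set, k, linkage,
                               distance = "euclidean", standardize = TRUE)
  score <- module_score(x, immune_set)
  means <- tapply(score[names(cl$labels)], cl$labels, mean)
  ord <- order(means)  # cluster ids in ascending mean-score order
  level_names <- if (k == 3) c("low", "medium", "high") else paste0("grp", seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  tibble::tibble(
    sample_id = names(cl$labels),
    immune_score = unname(score[names(cl$labels)]),
    group = factor(level_names[relabel[cl$labels]], levels = level_names,
                   ordered = TRUE)
  )
}

#' Groupwise score tests: one-way ANOVA plus Bonferroni pairwise t tests
#'
#' @param scores Numeric vector of per-sample scores.
#' @param groups Factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 members each.
#' @return A list of class `score_group_tests`: `anova` (one-row tibble with
#'   `f`, `df1`, `df2`, `p`) and `pairwise` (tibble with raw and
#'   Bonferroni-adjusted two-sided Welch-free Student t p-values, adjusted =
#'   raw x number of pairs, capped at 1).
#' @export
score_group_tests <- function(scores, groups) {
  groups <- factor(groups)
  counts <- table(groups)
  if (length(counts) < 2) rlang::abort("Need >= 2 groups.")
  if (any(counts < 2)) {
    rlang::abort(paste0("Singleton group(s): ",
                        paste(names(counts)[counts < 2], collapse = ", ")))
  }
  fres <- rowwise_f(matrix(scores, nrow = 1), groups)
  pairs <- utils::combn(levels(groups), 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    a <- scores[groups == pairs[1, i]]
    b <- scores[groups == pairs[2, i]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                   t = unname(tt$statistic), p = tt$p.value)
  })
  pw$p_adj <- pmin(pw$p * n_pairs, 1)
  structure(list(
    anova = tibble::tibble(f = unname(fres$f), df1 = fres$df1,
                           df2 = fres$df2, p = unname(fres$p)),
    pairwise = pw
  ), class = "score_group_tests")
}

#' @export
print.score_group_tests <- function(x, ...) {
  cat(sprintf("<score_group_tests> one-way F = %.3f (p = %.3g); %d pairwise tests\n",
              x$anova$f, x$anova$p, nrow(x$pairwise)))
  invisible(x)
}

#' @export
#' @method tidy score_group_tests
tidy.score_group_tests <- function(x, ...) x$pairwise

#' @export
#' @method glance score_group_tests
glance.score_group_tests <- function(x, ...) x$anova

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks at ties) with the
#' large-sample t approximation `t = rho sqrt((n-2)/(1-rho^2))` for the
#' p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A tibble with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) rlang::abort("x and y must have equal length.")
  n <- length(x)
  if (n < 3) rlang::abort("Need >= 3 observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Spearman correlation undefined for a constant vector.")
  }
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p_two <- 0
    tstat <- sign(rho) * Inf
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_two <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  p <- switch(alternative,
    two.sided = p_two,
    greater = stats::pt(tstat, df = n - 2, lower.tail = FALSE),
    less = stats::pt(tstat, df = n - 2)
  )
  tibble::tibble(rho = rho, p = max(p, .Machine$double.xmin), n = n)
}

#' Gene-wise permutation test of module-score association
#'
#' Tests whether the module score of a target gene set (for example the
#' combination-induced IFN genes) is associated with a per-sample immune
#' infiltration score beyond what random gene sets of the same size achieve.
#' The null redraws `n_perm` uniform random gene sets from a background
#' universe (all genes minus the immune core by default, so the infiltration
#' score itself stays fixed — the "gene-wise" unit of permutation) and
#' recomputes the Spearman correlation each time. `p = (1 + #\{null >=
#' observed\}) / (n_perm + 1)` for the one-sided "greater" default.
#' `unit = "samples"` instead permutes the sample pairing of the two scores.
#'
#' @param x A log2 [expression_matrix()].
#' @param target_set Target gene ids.
#' @param immune_score Named per-sample score vector (see [module_score()]).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param sided `"greater"` (default), `"less"` or `"two.sided"` on the
#'   observed correlation.
#' @param background Optional character vector of background gene ids;
#'   defaults to all matrix genes not in `exclude`.
#' @param exclude Gene ids excluded from the background (defaults to none;
#'   pass the immune core set to keep the null independent of the score).
#' @param unit `"genes"` (default) or `"samples"`.
#' @return A tibble: `rho` (observed), `p`, `n_perm`.
#' @export
genewise_permutation_test <- function(x, target_set, immune_score,
                                      n_perm = 10000, seed = 1,
                                      sided = c("greater", "less", "two.sided"),
                                      background = NULL, exclude = character(),
                                      unit = c("genes", "samples")) {
  sided <- match.arg(sided)
  unit <- match.arg(unit)
  if (n_perm < 1) rlang::abort("n_perm must be >= 1.")
  stopifnot(all(colnames(x) %in% names(immune_score)))
  immune_score <- immune_score[colnames(x)]
  target_genes <- intersect(target_set, rownames(x))
  size <- length(target_genes)
  if (size == 0) rlang::abort("Target set does not intersect the matrix.")
  observed <- spearman_cor(module_score(x, target_genes), immune_score)$rho
  if (is.null(background)) background <- setdiff(rownames(x), exclude)
  if (length(background) < size) {
    rlang::abort("Background universe smaller than the target set.")
  }
  score_rank <- rank(immune_score, ties.method = "average")
  null_rho <- withr::with_seed(seed, {
    if (unit == "genes") {
      # precompute the gene-wise z matrix once; a random set's module score
      # is then just the column mean over its rows
      v <- unclass(x)[background, , drop = FALSE]
      sds <- apply(v, 1, stats::sd)
      v <- v[sds > 0, , drop = FALSE]
      if (nrow(v) < size) rlang::abort("Background universe smaller than the target set.")
      z <- (v - rowMeans(v)) / sds[sds > 0]
      vapply(seq_len(n_perm), function(i) {
        s <- colMeans(z[sample.int(nrow(z), size), , drop = FALSE])
        stats::cor(rank(s, ties.method = "average"), score_rank)
      }, numeric(1))
    } else {
      target_score <- module_score(x, target_genes)
      target_rank <- rank(target_score, ties.method = "average")
      vapply(seq_len(n_perm), function(i) {
        stats::cor(target_rank, sample(score_rank))
      }, numeric(1))
    }
  })
  exceed <- switch(sided,
    greater = sum(null_rho >= observed),
    less = sum(null_rho <= observed),
    two.sided = sum(abs(null_rho) >= abs(observed))
  )
  tibble::tibble(rho = observed, p = (1 + exceed) / (n_perm + 1),
                 n_perm = as.integer(n_perm))
}
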