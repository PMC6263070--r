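#' Gene-wise moderated-t contrast between two arms
#'
#' For each gene the log2 fold-change is the arm-mean difference on the log2
#' scale. Because designs in this setting often carry very few replicates per
#' arm, the per-gene pooled variance is shrunk toward the across-gene mean
#' variance with weight `d0 / (d0 + df)` — a fixed-prior moderated t — and the
#' p-value is taken from a t distribution with `df + d0` degrees of freedom.
#' With `d0 = 0` this reduces exactly to the ordinary pooled-variance
#' two-sample t test.
#'
#' @param x A log2-scale [expression_matrix()].
#' @param annotation Paired annotation tibble (`sample_id`, `arm`).
#' @param arm_a,arm_b Arm labels to contrast; log2FC is mean(A) - mean(B).
#' @param d0 Prior degrees of freedom of the variance shrinkage (default 4).
#' @return A `de_result` tibble: `gene`, `log2fc`, `t`, `p`, `q` (BH), with
#'   the contrast label in attribute `contrast`.
#' @export
gene_stats <- function(x, annotation, arm_a, arm_b, d0 = 4) {
  assert_scale(x, "log2", "gene_stats")
  ann <- pair_annotation(x, annotation)
  ia <- which(ann$arm == arm_a)
  ib <- which(ann$arm == arm_b)
  if (length(ia) < 2 || length(ib) < 2) {
    rlang::abort(sprintf(
      "Both arms need >= 2 samples (got %d for %s, %d for %s); variance is undefined otherwise.",
      length(ia), arm_a, length(ib), arm_b))
  }
  v <- unclass(x)
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(v[, ia, drop = FALSE])
  mb <- rowMeans(v[, ib, drop = FALSE])
  va <- rowSums((v[, ia, drop = FALSE] - ma)^2)
  vb <- rowSums((v[, ib, drop = FALSE] - mb)^2)
  df <- na + nb - 2
  s2 <- (va + vb) / df
  s2_bar <- mean(s2)
  s2_mod <- (d0 * s2_bar + df * s2) / (d0 + df)
  se <- sqrt(s2_mod * (1 / na + 1 / nb))
  log2fc <- ma - mb
  tstat <- log2fc / se
  p <- 2 * stats::pt(abs(tstat), df = df + d0, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  res <- tibble::tibble(gene = rownames(v), log2fc = unname(log2fc),
                        t = unname(tstat), p = unname(p), q = bh_fdr(unname(p)))
  attr(res, "contrast") <- paste0(arm_a, " vs ", arm_b)
  class(res) <- c("de_result", class(res))
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on sorted p-values, `q(i) = min_{j >= i} p(j) m/j`,
#' mapped back to the input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, monotone in `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    rlang::abort("All p-values must lie in (0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Threshold a contrast into an up/down signature
#'
#' @param de A `de_result` from [gene_stats()].
#' @param fc_threshold Fold-change threshold on the natural (not log) scale;
#'   genes need `|log2fc| >= log2(fc_threshold)`.
#' @param fdr_threshold BH q cutoff.
#' @return A `de_signature`: disjoint `up` and `down` gene vectors plus the
#'   thresholds and contrast used.
#' @export
derive_signature <- function(de, fc_threshold = 2, fdr_threshold = 0.05) {
  if (fc_threshold <= 0 || fdr_threshold <= 0) {
    rlang::abort("Thresholds must be > 0.")
  }
  lfc <- log2(fc_threshold)
  up <- de$gene[de$log2fc >= lfc & de$q <= fdr_threshold]
  down <- de$gene[de$log2fc <= -lfc & de$q <= fdr_threshold]
  structure(list(up = up, down = down,
                 contrast = attr(de, "contrast"),
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold),
            class = "de_signature")
}

#' @export
print.de_signature <- function(x, ...) {
  cat(sprintf("<de_signature> %s: %d up, %d down (FC >= %g, FDR <= %g)\n",
              x$contrast %||% "?", length(x$up), length(x$down),
              x$fc_threshold, x$fdr_threshold))
  invisible(x)
}

#' @export
#' @method tidy de_signature
tidy.de_signature <- function(x, ...) {
  tibble::tibble(
    gene = c(x$up, x$down),
    direction = rep(c("up", "down"), c(length(x$up), length(x$down)))
  )
}

#' Combination-synergy gene set
#'
#' A gene belongs to the synergy set of a combination arm when it passes the
#' signature thresholds against BOTH constituent single agents with the same
#' direction in both contrasts. Direction-inconsistent or single-contrast
#' genes are excluded. With `mode = "union"` a gene qualifies if it passes
#' either contrast (direction consistency still required where both pass).
#'
#' @param de_vs_a,de_vs_b `de_result`s of the combination arm against each
#'   single agent, over the same gene universe.
#' @param fc_threshold,fdr_threshold As in [derive_signature()].
#' @param mode `"intersection"` (default, the conservative reading) or
#'   `"union"`.
#' @return A `de_signature` with the shared direction per gene.
#' @export
synergy_set <- function(de_vs_a, de_vs_b, fc_threshold = 2, fdr_threshold = 0.05,
                        mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (!identical(sort(de_vs_a$gene), sort(de_vs_b$gene))) {
    rlang::abort("The two contrasts must share the same gene universe.")
  }
  sig_a <- derive_signature(de_vs_a, fc_threshold, fdr_threshold)
  sig_b <- derive_signature(de_vs_b, fc_threshold, fdr_threshold)
  if (mode == "intersection") {
    up <- intersect(sig_a$up, sig_b$up)
    down <- intersect(sig_a$down, sig_b$down)
  } else {
    inconsistent <- union(intersect(sig_a$up, sig_b$down),
                          intersect(sig_a$down, sig_b$up))
    up <- setdiff(union(sig_a$up, sig_b$up), inconsistent)
    down <- setdiff(union(sig_a$down, sig_b$down), inconsistent)
  }
  structure(list(up = up, down = down,
                 contrast = paste0(attr(de_vs_a, "contrast"), " & ",
                                   attr(de_vs_b, "contrast")),
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold),
            class = "de_signature")
}

#' Most differentially expressed genes across all arms
#'
#' Ranks genes by the one-way across-arm F statistic and returns the top
#' fraction, the ranking used to pick genes for unsupervised heatmap
#' clustering. Ties are broken by gene id so the result is deterministic.
#'
#' @param x A log2 [expression_matrix()].
#' @param annotation Paired annotation tibble.
#' @param fraction Fraction of genes to keep, in (0, 1]; `ceiling(fraction * G)`
#'   genes are returned.
#' @return Character vector of gene ids, in decreasing F order.
#' @export
top_fraction_genes <- function(x, annotation, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) rlang::abort("fraction must be in (0, 1].")
  ann <- pair_annotation(x, annotation)
  arms <- unique(ann$arm)
  if (length(arms) < 2) rlang::abort("Need >= 2 arms for an across-arm F ranking.")
  f <- rowwise_f(unclass(x), ann$arm)$f
  ord <- order(-f, rownames(x))
  n_top <- ceiling(fraction * nrow(x))
  rownames(x)[ord][seq_len(n_top)]
}

# vectorised one-way ANOVA across the rows of a matrix
rowwise_f <- function(v, groups) {
  groups <- as.factor(groups)
  n <- ncol(v)
  k <- nlevels(groups)
  counts <- as.vector(table(groups))
  # group means per row: v %*% indicator / counts
  ind <- stats::model.matrix(~ groups - 1)
  gm <- (v %*% ind) / rep(counts, each = nrow(v))
  grand <- rowMeans(v)
  ss_between <- rowSums(sweep((gm - grand)^2, 2, counts, "*"))
  ss_total <- rowSums((v - grand)^2)
  ss_within <- ss_total - ss_between
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # all-equal rows: 0/0 -> define F = 0, p = 1
  degenerate <- !is.finite(f) & ss_between < 1e-300
  f[degenerate] <- 0
  p[degenerate] <- 1
  list(f = f, p = pmax(p, .Machine$double.xmin), df1 = df1, df2 = df2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` tibble.
#' @param fc_threshold,fdr_threshold Thresholds drawn as guide lines.
#' @param ... Unused.
#' @export
#' @method autoplot de_result
autoplot.de_result <- function(object, fc_threshold = 2, fdr_threshold = 0.05, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    status = dplyr::case_when(
      .data$q <= fdr_threshold & .data$log2fc >= log2(fc_threshold) ~ "up",
      .data$q <= fdr_threshold & .data$log2fc <= -log2(fc_threshold) ~ "down",
      TRUE ~ "ns"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$q),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 FDR",
                  title = attr(object, "contrast")) +
    ggplot2::theme_minimal()
}
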