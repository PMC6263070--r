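#' Per-sample background subtraction
#'
#' Subtracts each sample's `percentile` intensity value from that sample's
#' column and floors the result at a small positive `eps`, mimicking
#' array-style background removal ahead of quantile normalisation.
#'
#' @param x An [expression_matrix()] on the raw intensity scale.
#' @param percentile Background percentile in \[0, 50).
#' @param eps Positive floor applied after subtraction.
#' @return A raw-intensity `expr_matrix` with every value >= `eps`.
#' @export
background_subtract <- function(x, percentile = 5, eps = 1.0) {
  assert_scale(x, "raw_intensity", "background_subtract")
  if (percentile < 0 || percentile >= 50) {
    rlang::abort("percentile must lie in [0, 50).")
  }
  bg <- apply(unclass(x), 2, stats::quantile, probs = percentile / 100,
              names = FALSE, type = 7)
  out <- sweep(unclass(x), 2, bg, "-")
  out[out < eps] <- eps
  as_expr(out, x)
}

#' Quantile normalisation
#'
#' Forces every sample onto the common distribution defined by the
#' across-sample mean of sorted values. Ties within a sample receive the mean
#' of the reference values their ranks span (mid-rank convention). Idempotent
#' to numerical precision.
#'
#' @param x An [expression_matrix()] with >= 2 samples.
#' @return An `expr_matrix` on the same scale whose columns share one sorted
#'   distribution.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) {
    rlang::warn("quantile_normalize with a single sample is a no-op.")
    return(x)
  }
  v <- unclass(x)
  sorted <- apply(v, 2, sort, method = "radix")
  ref <- rowMeans(sorted)
  csum <- c(0, cumsum(ref))
  out <- apply(v, 2, function(col) {
    # a tie spanning reference slots i..j receives mean(ref[i..j])
    rmin <- rank(col, ties.method = "min")
    rmax <- rank(col, ties.method = "max")
    (csum[rmax + 1] - csum[rmin]) / (rmax - rmin + 1)
  })
  dimnames(out) <- dimnames(v)
  as_expr(out, x)
}

#' Log2 transform with offset
#'
#' @param x A raw-intensity [expression_matrix()].
#' @param offset Positive pseudo-intensity added before the log.
#' @return A log2-scale `expr_matrix`.
#' @export
log2_with_offset <- function(x, offset = 1) {
  assert_scale(x, "raw_intensity", "log2_with_offset")
  if (offset <= 0) rlang::abort("offset must be > 0.")
  as_expr(log2(unclass(x) + offset), x, scale = "log2")
}

#' Remove an additive batch effect by per-gene batch mean-centering
#'
#' For every gene, each batch's mean is subtracted and the gene's grand mean
#' added back, removing any purely additive per-gene batch shift exactly
#' while leaving gene-level means untouched. Refuses designs in which a batch
#' coincides 1:1 with a treatment arm, where centering would erase the
#' treatment effect itself.
#'
#' @param x An [expression_matrix()].
#' @param annotation Annotation tibble paired with `x` (columns `sample_id`,
#'   `arm`, `batch`).
#' @return An `expr_matrix` with batch means equalised per gene.
#' @export
batch_center <- function(x, annotation) {
  ann <- pair_annotation(x, annotation)
  batches <- unique(ann$batch)
  if (length(batches) == 1) return(x)
  # confounding check: a batch containing exactly the samples of one arm
  for (b in batches) {
    arms_in_b <- unique(ann$arm[ann$batch == b])
    if (length(arms_in_b) == 1 &&
        all(ann$batch[ann$arm == arms_in_b] == b)) {
      rlang::abort(sprintf(
        "Batch %s is confounded 1:1 with arm %s; batch centering would remove the treatment effect.",
        b, arms_in_b))
    }
  }
  v <- unclass(x)
  grand <- rowMeans(v)
  out <- v
  for (b in batches) {
    cols <- ann$batch == b
    out[, cols] <- v[, cols] - rowMeans(v[, cols, drop = FALSE]) + grand
  }
  as_expr(out, x)
}

#' Principal component analysis of samples
#'
#' SVD of the gene-centered matrix (genes are centered, not scaled, the
#' standard convention for expression PCA). Component signs are fixed by
#' making each loading's largest-magnitude entry positive, so results are
#' fully deterministic.
#'
#' @param x An [expression_matrix()].
#' @param k Number of components, `<= min(genes, samples - 1)`.
#' @return An object of class `expr_pca`: loadings (genes x k), sample
#'   coordinates (samples x k) and explained-variance fractions.
#' @export
expr_pca <- function(x, k = 2) {
  v <- unclass(x)
  kmax <- min(nrow(v), ncol(v) - 1L)
  if (k > kmax) {
    rlang::abort(sprintf("k = %d exceeds min(genes, samples - 1) = %d.", k, kmax))
  }
  centered <- v - rowMeans(v)
  sv <- svd(centered, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    u <- sv$u[, j]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  loadings <- sweep(sv$u, 2, flip, "*")
  coords <- sweep(sv$v, 2, sv$d[seq_len(k)] * flip, "*")
  dimnames(loadings) <- list(rownames(v), paste0("PC", seq_len(k)))
  dimnames(coords) <- list(colnames(v), paste0("PC", seq_len(k)))
  total_var <- sum(centered^2)
  structure(list(loadings = loadings, coordinates = coords,
                 var_explained = sv$d[seq_len(k)]^2 / total_var),
            class = "expr_pca")
}

#' @export
print.expr_pca <- function(x, ...) {
  cat(sprintf("<expr_pca> %d components; variance explained: %s\n",
              ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")))
  invisible(x)
}

#' @rdname expr_pca
#' @param x An `expr_pca` object.
#' @param ... Unused.
#' @export
#' @method tidy expr_pca
tidy.expr_pca <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample")
}

#' @rdname expr_pca
#' @export
#' @method glance expr_pca
glance.expr_pca <- function(x, ...) {
  tibble::tibble(k = ncol(x$loadings),
                 var_explained_total = sum(x$var_explained))
}

#' @rdname expr_pca
#' @param object An `expr_pca` object.
#' @param annotation Optional annotation tibble; if supplied, points are
#'   coloured by arm and shaped by batch.
#' @export
#' @method autoplot expr_pca
autoplot.expr_pca <- function(object, annotation = NULL, ...) {
  df <- tidy(object)
  pct <- 100 * object$var_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(annotation)) {
    df <- dplyr::left_join(df, annotation, by = c(sample = "sample_id"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$arm, shape = .data$batch))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}
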