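#' Construct an expression matrix
#'
#' The central container of the pipeline: a numeric genes x samples matrix
#' carrying a `scale` flag that records whether values are raw (non-negative,
#' intensity-like) or log2. All preprocessing operations check and update the
#' flag so that, for example, background subtraction cannot be applied to
#' already-logged data.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param scale Either `"raw_intensity"` or `"log2"`.
#' @return A matrix of class `expr_matrix` with a `scale` attribute.
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expression_matrix(m, scale = "raw_intensity")
#' @export
expression_matrix <- function(values, scale = c("log2", "raw_intensity")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("`values` must have gene row names and sample column names.")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0) {
    rlang::abort(paste0("Duplicated gene ids: ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    rlang::abort(paste0("Duplicated sample ids: ", paste(dup_s, collapse = ", ")))
  }
  if (any(!is.finite(values))) {
    rlang::abort("All expression values must be finite.")
  }
  if (scale == "raw_intensity" && any(values < 0)) {
    rlang::abort("raw_intensity values must be >= 0.")
  }
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples, scale = %s\n",
    nrow(x), ncol(x), expr_scale(x)
  ))
  utils::str(unclass(x)[seq_len(min(3L, nrow(x))), seq_len(min(3L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Scale flag of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"raw_intensity"` or `"log2"`.
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "log2" else sc
}

# rebuild the class/attr after an operation that returns a bare matrix
as_expr <- function(values, template, scale = expr_scale(template)) {
  expression_matrix(values, scale = scale)
}

assert_scale <- function(x, scale, op) {
  if (expr_scale(x) != scale) {
    rlang::abort(sprintf(
      "%s requires a %s-scale matrix but got scale = %s.", op, scale, expr_scale(x)
    ))
  }
  invisible(x)
}

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `value` and the scale flag
#'   repeated in `scale`.
#' @export
#' @method tidy expr_matrix
tidy.expr_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)),
    scale = expr_scale(x)
  )
}

#' Construct a gene-set collection
#'
#' Named gene sets with GMT semantics: ordered, uniquely named, non-empty, with
#' duplicate members dropped (first occurrence kept).
#'
#' @param sets Named list of character vectors of gene ids.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled from `""`.
#' @return A list of class `gene_sets`.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    rlang::abort("`sets` must be a fully named list of character vectors.")
  }
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup) > 0) {
    rlang::abort(paste0("Duplicated gene-set names: ", paste(dup, collapse = ", ")))
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    rlang::abort(paste0("Empty gene sets: ", paste(empty, collapse = ", ")))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets\n", length(x)))
  n <- min(5L, length(x))
  for (i in seq_len(n)) {
    cat(sprintf("  %s (%d genes)\n", names(x)[i], length(x[[i]])))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' @export
#' @method tidy gene_sets
tidy.gene_sets <- function(x, ...) {
  tibble::tibble(
    set = rep(names(x), lengths(x)),
    gene = unlist(x, use.names = FALSE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
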