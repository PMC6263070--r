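#' Read and write expression matrices
#'
#' Tab-separated text, genes in rows: first column `gene_id`, remaining
#' columns one per sample with sample ids in the header. Decimal points only.
#' Writing then reading reproduces ids exactly and values to full printed
#' precision (17 significant digits).
#'
#' @param path File path.
#' @param scale Scale flag to stamp on the matrix, `"log2"` or
#'   `"raw_intensity"`.
#' @return `read_expression()` returns an [expression_matrix()];
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path, scale = c("log2", "raw_intensity")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) rlang::abort(paste0("No such file: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) rlang::abort("Expression file needs a gene_id column plus >=1 sample.")
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(sprintf(
      "Non-numeric expression value %s at data row %d, sample column %s.",
      vals[bad[1, 1], bad[1, 2]], bad[1, 1], sample_ids[bad[1, 2]]
    ))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  expression_matrix(num, scale = scale)
}

#' @rdname read_expression
#' @param x An `expr_matrix`.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x),
                   format(unclass(x), digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' File order of sets and members is preserved; duplicate members are dropped
#' with a warning.
#'
#' @param path File path.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("No such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) rlang::abort("Empty GMT file.")
  sets <- vector("list", length(lines))
  set_names <- character(length(lines))
  descriptions <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      rlang::abort(sprintf("GMT line %d has %d field(s); need >= 3.", i, length(fields)))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      rlang::warn(sprintf("GMT line %d (%s): duplicate members dropped.", i, fields[1]))
      members <- unique(members)
    }
    if (length(members) == 0) {
      rlang::abort(sprintf("GMT line %d (%s): no members after deduplication.", i, fields[1]))
    }
    sets[[i]] <- members
    set_names[i] <- fields[1]
    descriptions[i] <- fields[2]
  }
  names(sets) <- set_names
  gene_sets(sets, descriptions)
}

#' @rdname read_gmt
#' @param x A `gene_sets` collection.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  desc <- attr(x, "descriptions")
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], desc[[i]], x[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

ENDPOINTS <- c("OS", "RFS", "DMFS")

#' Read sample annotation and survival tables
#'
#' Annotation TSV columns: `sample_id`, `arm`, `batch`, `replicate`; survival
#' TSV columns: `patient_id`, `time`, `event`, `endpoint` (plus optional
#' `group`). Extra columns are preserved untouched. Records are validated:
#' time must be positive, event in {0, 1}, endpoint one of OS / RFS / DMFS.
#'
#' @param path File path.
#' @return A tibble of typed, validated records.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("No such file: ", path))
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE,
                                            colClasses = "character"))
  need <- c("sample_id", "arm", "batch", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) {
    rlang::abort(paste0("Annotation file missing column(s): ", paste(miss, collapse = ", ")))
  }
  df$replicate <- as.integer(df$replicate)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    rlang::abort(paste0("Duplicated sample ids in annotation: ", paste(dup, collapse = ", ")))
  }
  df
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_annotation
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("No such file: ", path))
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE,
                                            colClasses = "character"))
  need <- c("patient_id", "time", "event", "endpoint")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) {
    rlang::abort(paste0("Survival file missing column(s): ", paste(miss, collapse = ", ")))
  }
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  validate_survival(df)
  df
}

#' @rdname read_annotation
#' @param survival_table Survival tibble.
#' @export
write_survival <- function(survival_table, path) {
  utils::write.table(survival_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_survival <- function(df) {
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_t) > 0) {
    rlang::abort(sprintf("Survival row %d: time must be > 0 (got %s).",
                         bad_t[1], df$time[bad_t[1]]))
  }
  bad_e <- which(!df$event %in% c(0L, 1L))
  if (length(bad_e) > 0) {
    rlang::abort(sprintf("Survival row %d: event must be 0 or 1 (got %s).",
                         bad_e[1], df$event[bad_e[1]]))
  }
  bad_ep <- which(!df$endpoint %in% ENDPOINTS)
  if (length(bad_ep) > 0) {
    rlang::abort(sprintf("Survival row %d: unknown endpoint %s (expected %s).",
                         bad_ep[1], df$endpoint[bad_ep[1]],
                         paste(ENDPOINTS, collapse = "/")))
  }
  invisible(df)
}

#' Check that a matrix and its annotation describe the same samples
#'
#' @param x An `expr_matrix`.
#' @param annotation Annotation tibble with a `sample_id` column.
#' @return The annotation reordered to the matrix's column order, invisibly
#'   usable downstream. Errors list the symmetric difference if the sample
#'   sets disagree.
#' @export
pair_annotation <- function(x, annotation) {
  only_m <- setdiff(colnames(x), annotation$sample_id)
  only_a <- setdiff(annotation$sample_id, colnames(x))
  if (length(only_m) > 0 || length(only_a) > 0) {
    rlang::abort(paste0(
      "Sample sets differ. Matrix-only: {", paste(only_m, collapse = ", "),
      "}; annotation-only: {", paste(only_a, collapse = ", "), "}."
    ))
  }
  annotation[match(colnames(x), annotation$sample_id), , drop = FALSE]
}
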