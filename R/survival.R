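#' Median split of a score vector
#'
#' `high` = score strictly above the median; ties at the median go to `low`
#' (the reproducible default when no optimal-cutoff machinery is wanted).
#'
#' @param scores Numeric vector, length >= 2, not all equal.
#' @return Character vector `"high"` / `"low"`, named like `scores`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) rlang::abort("Need >= 2 samples to split.")
  if (length(unique(scores)) == 1) {
    rlang::abort("All scores equal; no split exists.")
  }
  m <- stats::median(scores)
  labels <- ifelse(scores > m, "high", "low")
  names(labels) <- names(scores)
  labels
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' censored-only times adjusting at-risk counts only. Events are processed
#' before censorings at tied times (the standard convention). With no
#' censoring the estimate equals the empirical survival function.
#'
#' @param survival_table Tibble with `time` and `event` columns (see
#'   [read_survival()]).
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` — one row per distinct observed time.
#' @export
km_estimate <- function(survival_table) {
  if (nrow(survival_table) == 0) rlang::abort("Empty survival table.")
  stopifnot(all(c("time", "event") %in% colnames(survival_table)))
  times <- sort(unique(survival_table$time))
  n <- nrow(survival_table)
  surv <- 1
  rows <- purrr::map_dfr(times, function(tt) {
    at_risk <- sum(survival_table$time >= tt)
    d <- sum(survival_table$time == tt & survival_table$event == 1)
    c_ <- sum(survival_table$time == tt & survival_table$event == 0)
    if (d > 0) surv <<- surv * (1 - d / at_risk)
    tibble::tibble(time = tt, n_risk = at_risk, n_event = d, n_censor = c_,
                   surv = surv)
  })
  class(rows) <- c("km_curve", class(rows))
  rows
}

#' @export
#' @method tidy km_curve
tidy.km_curve <- function(x, ...) tibble::as_tibble(x)

#' @rdname km_estimate
#' @param object A `km_curve` (or a named list of them, one per group).
#' @param ... Unused.
#' @export
#' @method autoplot km_curve
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1),
    tibble::as_tibble(object)[, c("time", "surv")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Two-group logrank test with O/E hazard ratio
#'
#' At every distinct event time the observed events in group A are compared
#' with the hypergeometric expectation given the risk sets; the statistic is
#' `(O_A - E_A)^2 / V` on 1 df. The hazard ratio is the ratio of
#' observed/expected ratios, `HR = (O_A/E_A) / (O_B/E_B)`, with
#' `CI = exp(log HR +/- 1.96 sqrt(1/E_A + 1/E_B))`.
#'
#' @param table_a,table_b Survival tibbles for the two groups.
#' @param conf_level Confidence level of the HR interval.
#' @return A `logrank_result` list: `chisq`, `p`, `observed`, `expected`
#'   (length-2 vectors, A then B), `hr`, `ci_low`, `ci_high`.
#' @export
logrank_test <- function(table_a, table_b, conf_level = 0.95) {
  if (nrow(table_a) == 0 || nrow(table_b) == 0) {
    rlang::abort("Both groups must be nonempty.")
  }
  ta <- table_a$time; ea <- table_a$event
  tb <- table_b$time; eb <- table_b$event
  if (sum(ea) + sum(eb) == 0) rlang::abort("Need >= 1 event overall.")
  event_times <- sort(unique(c(ta[ea == 1], tb[eb == 1])))
  O_a <- 0; E_a <- 0; V <- 0; O_b <- 0; E_b <- 0
  for (tt in event_times) {
    n_a <- sum(ta >= tt); n_b <- sum(tb >= tt)
    d_a <- sum(ta == tt & ea == 1); d_b <- sum(tb == tt & eb == 1)
    n <- n_a + n_b; d <- d_a + d_b
    O_a <- O_a + d_a; O_b <- O_b + d_b
    E_a <- E_a + d * n_a / n
    E_b <- E_b + d * n_b / n
    if (n > 1) V <- V + d * (n_a / n) * (n_b / n) * (n - d) / (n - 1)
  }
  if (E_a == 0 || E_b == 0 || O_a == 0 || O_b == 0) {
    rlang::abort("A group has zero observed or expected events; HR undefined.")
  }
  chisq <- (O_a - E_a)^2 / V
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hr <- (O_a / E_a) / (O_b / E_b)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- zcrit * sqrt(1 / E_a + 1 / E_b)
  structure(list(chisq = chisq, p = max(p, .Machine$double.xmin),
                 observed = c(A = O_a, B = O_b),
                 expected = c(A = E_a, B = E_b),
                 hr = hr, ci_low = exp(log(hr) - half),
                 ci_high = exp(log(hr) + half)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chi2 = %.3f, p = %.3g, HR = %.3f [%.3f, %.3f]\n",
              x$chisq, x$p, x$hr, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
#' @method glance logrank_result
glance.logrank_result <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, p = x$p, hr = x$hr,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 observed_a = x$observed[["A"]], observed_b = x$observed[["B"]],
                 expected_a = x$expected[["A"]], expected_b = x$expected[["B"]])
}

#' @export
#' @method tidy logrank_result
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(group = c("A", "B"), observed = unname(x$observed),
                 expected = unname(x$expected))
}

#' Per-gene expression-split prognosis scan
#'
#' For every gene and endpoint, patients are split at the gene's median
#' expression (high = above) and the high group is compared with the low
#' group by logrank, giving a hazard ratio (high vs low) per gene; q is BH
#' within each endpoint. With `combine = TRUE` the genes are first collapsed
#' into one module score and a single split is tested per endpoint.
#'
#' @param x A log2 [expression_matrix()] whose samples are patients.
#' @param survival_tables Named list of survival tibbles (names are ignored;
#'   each table carries its `endpoint` column). Patient ids must match the
#'   matrix samples.
#' @param genes Gene ids to scan.
#' @param combine Collapse `genes` into one [module_score()] first?
#' @return A tibble: `gene`, `endpoint`, `hr`, `ci_low`, `ci_high`, `chisq`,
#'   `p`, `q`.
#' @export
prognosis_scan <- function(x, survival_tables, genes, combine = FALSE) {
  if (!is.list(survival_tables) || length(survival_tables) == 0) {
    rlang::abort("survival_tables must be a nonempty list.")
  }
  genes <- intersect(genes, rownames(x))
  if (length(genes) == 0) rlang::abort("No requested genes in the matrix.")
  scores <- if (combine) {
    list(module_score = module_score(x, genes))
  } else {
    g <- unclass(x)[genes, , drop = FALSE]
    stats::setNames(lapply(genes, function(gg) {
      v <- g[gg, ]
      names(v) <- colnames(x)
      v
    }), genes)
  }
  out <- purrr::map_dfr(survival_tables, function(tab) {
    overlap <- intersect(tab$patient_id, colnames(x))
    if (length(overlap) == 0) {
      rlang::abort("No overlap between survival table patients and matrix samples.")
    }
    tab <- tab[tab$patient_id %in% overlap, , drop = FALSE]
    purrr::map_dfr(names(scores), function(gname) {
      sc <- scores[[gname]][tab$patient_id]
      split <- median_split(sc)
      res <- logrank_test(tab[split == "high", , drop = FALSE],
                          tab[split == "low", , drop = FALSE])
      tibble::tibble(gene = gname, endpoint = tab$endpoint[1], hr = res$hr,
                     ci_low = res$ci_low, ci_high = res$ci_high,
                     chisq = res$chisq, p = res$p)
    })
  })
  dplyr::mutate(dplyr::group_by(out, .data$endpoint), q = bh_fdr(.data$p)) |>
    dplyr::ungroup()
}
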