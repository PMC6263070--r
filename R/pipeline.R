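#' Validate and normalise a pipeline configuration
#'
#' The pipeline is driven by a flat YAML file: a `stages` list naming which
#' stages to run plus per-stage parameters and a mandatory integer `seed`.
#' Unknown keys are rejected, defaults are filled in, and range checks run
#' before any computation starts, so a malformed configuration never leaves
#' partial output behind.
#'
#' @param path Path to a YAML configuration file.
#' @return A normalised configuration list of class `run_config`.
#' @section Configuration keys:
#' \describe{
#'   \item{seed}{integer, required — the single source of randomness; each
#'     stochastic stage derives its own seed as `seed + stage offset`.}
#'   \item{stages}{subset of `simulate`, `preprocess`, `de`, `cluster`,
#'     `enrich`, `immune`, `survival`; default all.}
#'   \item{out_dir}{output directory, required.}
#'   \item{n_genes, replicates_per_arm, noise_sd}{simulator size/noise.}
#'   \item{fc_threshold, fdr_threshold}{signature thresholds (defaults 2, 0.05).}
#'   \item{fraction}{top-gene fraction for clustering input (default 0.1).}
#'   \item{linkage}{hierarchical linkage (default "average").}
#'   \item{k}{infiltration groups (default 3).}
#'   \item{n_perm}{permutations for the gene-wise test (default 10000).}
#'   \item{cohort_n}{cohort size (default 500).}
#'   \item{surv_coef}{log-hazard coefficient of the survival simulator.}
#' }
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("No such config file: ", path))
  raw <- yaml::read_yaml(path)
  defaults <- list(
    seed = NULL, stages = c("simulate", "preprocess", "de", "cluster",
                            "enrich", "immune", "survival"),
    out_dir = NULL,
    n_genes = 2000L, replicates_per_arm = 4L, noise_sd = 0.3,
    fc_threshold = 2, fdr_threshold = 0.05,
    fraction = 0.1, linkage = "average", k = 3L,
    n_perm = 10000L, cohort_n = 500L, surv_coef = 1
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, raw)
  if (is.null(cfg$seed)) rlang::abort("Config must set an integer `seed`.")
  if (cfg$seed != round(cfg$seed)) rlang::abort("`seed` must be an integer.")
  if (is.null(cfg$out_dir)) rlang::abort("Config must set `out_dir`.")
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  if (cfg$fraction <= 0 || cfg$fraction > 1) rlang::abort("`fraction` must be in (0, 1].")
  if (cfg$fdr_threshold <= 0 || cfg$fc_threshold <= 0) rlang::abort("Thresholds must be > 0.")
  if (cfg$noise_sd <= 0) rlang::abort("`noise_sd` must be > 0.")
  if (cfg$n_perm < 1) rlang::abort("`n_perm` must be >= 1.")
  if (cfg$k < 2) rlang::abort("`k` must be >= 2.")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# per-stage seeds derived from the global seed by a fixed offset table,
# so stages can be rerun independently yet reproducibly
stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 1L, preprocess = 2L, de = 3L, cluster = 4L,
               enrich = 5L, immune = 6L, survival = 7L)
  cfg$seed + offsets[[stage]]
}

#' Run the full synthetic pipeline from a configuration
#'
#' Executes the selected stages in order — simulate, preprocess QC, synergy
#' differential expression, clustering, enrichment, immune stratification,
#' survival — writing every artifact as tab-separated text into `out_dir`
#' together with a `manifest.json` recording the configuration, seed and an
#' md5 for each output. Identical configuration and seed give byte-identical
#' outputs. Any stage failure leaves an `INCOMPLETE` marker file.
#'
#' @param config A `run_config` from [validate_config()] (or a path to one).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$out_dir, "INCOMPLETE")
  file.create(marker)
  outputs <- character()
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    design <- treatment_design(replicates_per_arm = config$replicates_per_arm)
    effects <- effect_model(n_genes = config$n_genes, noise_sd = config$noise_sd)

    stage <- "simulate"
    sim <- simulate_treatment_experiment(design, effects, stage_seed(config, "simulate"))
    if ("simulate" %in% config$stages) {
      emit("expression.tsv", function(p) write_expression(sim$expr, p))
      emit("annotation.tsv", function(p) write_annotation(sim$annotation, p))
      emit("truth_effects.tsv", function(p)
        utils::write.table(sim$truth, p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    stage <- "preprocess"
    expr <- batch_center(sim$expr, sim$annotation)
    if ("preprocess" %in% config$stages) {
      pca <- expr_pca(expr, k = 2)
      emit("pca_coordinates.tsv", function(p)
        utils::write.table(tidy(pca), p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    stage <- "de"
    de_ed_e <- gene_stats(expr, sim$annotation, "ED", "E")
    de_ed_d <- gene_stats(expr, sim$annotation, "ED", "D")
    syn <- synergy_set(de_ed_e, de_ed_d, config$fc_threshold, config$fdr_threshold)
    if ("de" %in% config$stages) {
      emit("de_ED_vs_E.tsv", function(p)
        utils::write.table(de_ed_e, p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit("de_ED_vs_D.tsv", function(p)
        utils::write.table(de_ed_d, p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit("synergy_signature.gmt", function(p)
        write_gmt(gene_sets(list(synergy_up = syn$up, synergy_down = syn$down),
                            c("ED synergy up", "ED synergy down")), p))
    }

    stage <- "cluster"
    if ("cluster" %in% config$stages) {
      top <- top_fraction_genes(expr, sim$annotation, config$fraction)
      cl <- cluster_samples_on_set(expr, top, k = length(design$arms),
                                   linkage = config$linkage)
      emit("sample_clusters.tsv", function(p)
        utils::write.table(
          tibble::tibble(sample_id = names(cl$labels), cluster = cl$labels),
          p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit("merge_history.tsv", function(p)
        utils::write.table(
          data.frame(step = seq_len(nrow(cl$tree$merge)),
                     left = cl$tree$merge[, 1], right = cl$tree$merge[, 2],
                     height = cl$tree$height),
          p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    stage <- "enrich"
    if ("enrich" %in% config$stages) {
      sets <- gene_sets(list(
        ifn = gene_ids(config$n_genes)[effects$modules$ifn],
        cell_cycle = gene_ids(config$n_genes)[effects$modules$cell_cycle],
        hdac = gene_ids(config$n_genes)[effects$modules$hdac]
      ))
      prof <- enrichment_matrix(expr, sets)
      stats_tbl <- groupwise_anova(prof, sim$annotation)
      emit("enrichment_scores.tsv", function(p)
        utils::write.table(tidy(prof), p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit("enrichment_anova.tsv", function(p)
        utils::write.table(stats_tbl, p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    stage <- "immune"
    cmodel <- cohort_model(n_samples = config$cohort_n)
    cohort <- simulate_cohort(cmodel, stage_seed(config, "immune"))
    imm_genes <- gene_ids(cmodel$n_genes)[cmodel$immune_genes]
    ifn_genes <- gene_ids(cmodel$n_genes)[cmodel$ifn_genes]
    strat <- stratify_infiltration(cohort$expr, imm_genes, k = config$k,
                                   linkage = config$linkage)
    if ("immune" %in% config$stages) {
      imm_score <- module_score(cohort$expr, imm_genes)
      perm <- genewise_permutation_test(
        cohort$expr, ifn_genes, imm_score, n_perm = config$n_perm,
        seed = stage_seed(config, "immune"), exclude = imm_genes)
      emit("infiltration_groups.tsv", function(p)
        utils::write.table(strat, p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit("immune_association.tsv", function(p)
        utils::write.table(perm, p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    stage <- "survival"
    if ("survival" %in% config$stages) {
      ifn_score <- module_score(cohort$expr, ifn_genes)
      surv <- simulate_survival(ifn_score,
                                survival_model(coef = config$surv_coef),
                                stage_seed(config, "survival"))
      split <- median_split(ifn_score[surv$patient_id])
      lr <- logrank_test(surv[split == "high", ], surv[split == "low", ])
      emit("survival_table.tsv", function(p) write_survival(surv, p))
      emit("logrank.tsv", function(p)
        utils::write.table(glance(lr), p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    manifest <- list(
      config = unclass(config),
      outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p)
        unname(tools::md5sum(p)))
    )
    manifest_path <- file.path(config$out_dir, "manifest.json")
    writeLines(to_json(manifest), manifest_path)
    unlink(marker)
    manifest
  }, error = function(e) {
    rlang::abort(sprintf("Pipeline failed in stage `%s`: %s", stage,
                         conditionMessage(e)), parent = e)
  })
  invisible(result)
}

# minimal JSON writer (names + atomic values only) so the manifest does not
# pull in a serialisation dependency
to_json <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  if (is.list(x)) {
    entries <- vapply(seq_along(x), function(i) {
      sprintf("%s  \"%s\": %s", pad, names(x)[i], to_json(x[[i]], indent + 1))
    }, character(1))
    paste0("{\n", paste(entries, collapse = ",\n"), "\n", pad, "}")
  } else if (length(x) == 1) {
    if (is.character(x)) sprintf("\"%s\"", x) else as.character(x)
  } else {
    paste0("[", paste(vapply(x, to_json, character(1)), collapse = ", "), "]")
  }
}
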