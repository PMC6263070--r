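#' Treatment design for the simulated combination experiment
#'
#' Describes the arm layout of the eight-arm experiment the generator
#' emulates: vehicle, three single agents (entinostat E, all-trans retinoic
#' acid A, doxorubicin D) and their combinations, with replicates spread
#' across batches round-robin so that every arm appears in every batch
#' whenever there are at least as many replicates as batches.
#'
#' @param arms Character vector of unique arm labels; must contain `"Veh"`.
#' @param replicates_per_arm Positive integer.
#' @param batches Character vector of batch labels.
#' @return A list of class `treatment_design`.
#' @export
treatment_design <- function(arms = c("Veh", "E", "A", "D", "EA", "ED", "AD", "EAD"),
                             replicates_per_arm = 4L,
                             batches = c("b1", "b2")) {
  if (anyDuplicated(arms)) rlang::abort("Arm labels must be unique.")
  if (!"Veh" %in% arms) rlang::abort("Design must include a \"Veh\" arm.")
  replicates_per_arm <- as.integer(replicates_per_arm)
  if (replicates_per_arm < 1) rlang::abort("replicates_per_arm must be >= 1.")
  if (length(batches) < 1 || anyDuplicated(batches)) {
    rlang::abort("Need >= 1 uniquely labelled batch.")
  }
  structure(list(arms = arms, replicates_per_arm = replicates_per_arm,
                 batches = batches),
            class = "treatment_design")
}

design_annotation <- function(design) {
  reps <- seq_len(design$replicates_per_arm)
  tibble::tibble(
    arm = rep(design$arms, each = design$replicates_per_arm),
    replicate = rep(reps, times = length(design$arms)),
    batch = design$batches[((rep(reps, times = length(design$arms)) - 1L) %%
                              length(design$batches)) + 1L],
    sample_id = paste0(.data$arm, "_r", .data$replicate)
  )[, c("sample_id", "arm", "batch", "replicate")]
}

#' Planted per-arm effect model for the treatment simulator
#'
#' Genes are partitioned into disjoint named modules (for example `ifn`,
#' `cell_cycle`, `hdac`, with the remainder as background). Each
#' (arm, module) pair carries a log2 effect: `direction = "up"` or `"down"`
#' applies the signed magnitude to every module gene; `"mixed"` splits the
#' module's genes up/down by the arm's `fraction_up` (first `ceil(f * m)`
#' genes up, rest down — deterministic). The default `fraction_up` for the
#' entinostat arm is 0.96, mirroring the strong upward skew HDAC inhibition
#' shows in this system; all other arms default to 0.5.
#'
#' @param n_genes Number of genes in the universe.
#' @param modules Named list of disjoint integer gene-index vectors.
#' @param effects Data frame with columns `arm`, `module`, `log2fc`
#'   (magnitude, > 0) and `direction` (`"up"`, `"down"` or `"mixed"`).
#' @param fraction_up Named numeric vector in \[0, 1\], per arm (unnamed arms
#'   default to 0.5).
#' @param noise_sd Residual Gaussian noise sd on the log2 scale, > 0.
#' @param baseline_range Range of the per-gene baseline mean (log2 units),
#'   drawn uniformly at simulation time.
#' @param batch_sd sd of the additive per-gene batch shift (log2 units),
#'   drawn once per batch.
#' @return A list of class `effect_model`.
#' @export
effect_model <- function(n_genes = 2000L,
                         modules = default_modules(n_genes),
                         effects = default_effects(),
                         fraction_up = c(E = 0.96),
                         noise_sd = 0.3,
                         baseline_range = c(6, 12),
                         batch_sd = 0.3) {
  n_genes <- as.integer(n_genes)
  if (noise_sd <= 0) rlang::abort("noise_sd must be > 0.")
  idx <- unlist(modules, use.names = FALSE)
  if (length(idx) > 0 && (anyDuplicated(idx) || any(idx < 1 | idx > n_genes))) {
    rlang::abort("Modules must be disjoint index sets within 1..n_genes.")
  }
  effects <- tibble::as_tibble(effects)
  stopifnot(all(c("arm", "module", "log2fc", "direction") %in% colnames(effects)))
  if (any(effects$arm == "Veh" & effects$log2fc != 0)) {
    rlang::abort("Effects for arm \"Veh\" must be zero.")
  }
  bad_mod <- setdiff(effects$module, names(modules))
  if (length(bad_mod) > 0) {
    rlang::abort(paste0("Effects reference unknown module(s): ",
                        paste(bad_mod, collapse = ", ")))
  }
  if (any(fraction_up < 0 | fraction_up > 1)) {
    rlang::abort("fraction_up values must lie in [0, 1].")
  }
  structure(list(n_genes = n_genes, modules = modules, effects = effects,
                 fraction_up = fraction_up, noise_sd = noise_sd,
                 baseline_range = baseline_range, batch_sd = batch_sd),
            class = "effect_model")
}

#' @rdname effect_model
#' @export
default_modules <- function(n_genes = 2000L) {
  stopifnot(n_genes >= 400L)
  list(ifn = 1:100, cell_cycle = 101:200, hdac = 201:400)
}

#' @rdname effect_model
#' @export
default_effects <- function() {
  tibble::tribble(
    ~arm,  ~module,      ~log2fc, ~direction,
    "E",   "hdac",       1.2,     "mixed",   # entinostat: mostly up
    "D",   "cell_cycle", 1.0,     "down",    # doxorubicin: MYC/E2F/G2M down
    "EA",  "hdac",       1.2,     "mixed",
    "ED",  "ifn",        1.5,     "up",      # combination-specific IFN induction
    "ED",  "cell_cycle", 1.5,     "down",
    "ED",  "hdac",       1.2,     "mixed",
    "AD",  "cell_cycle", 1.0,     "down",
    "EAD", "ifn",        1.5,     "up",
    "EAD", "cell_cycle", 1.5,     "down",
    "EAD", "hdac",       1.2,     "mixed"
  )
}

# per-gene per-arm planted log2 effects, deterministic given the model
effect_truth <- function(design, effects_model) {
  n_genes <- effects_model$n_genes
  genes <- gene_ids(n_genes)
  mat <- matrix(0, n_genes, length(design$arms),
                dimnames = list(genes, design$arms))
  for (i in seq_len(nrow(effects_model$effects))) {
    row <- effects_model$effects[i, ]
    if (!row$arm %in% design$arms) {
      rlang::abort(paste0("Effects reference unknown arm: ", row$arm))
    }
    idx <- effects_model$modules[[row$module]]
    m <- length(idx)
    fc <- abs(row$log2fc)
    eff <- switch(row$direction,
      up = rep(fc, m),
      down = rep(-fc, m),
      mixed = {
        f <- effects_model$fraction_up[row$arm]
        if (is.na(f)) f <- 0.5
        n_up <- ceiling(f * m)
        c(rep(fc, n_up), rep(-fc, m - n_up))
      },
      rlang::abort(paste0("Unknown effect direction: ", row$direction))
    )
    mat[idx, row$arm] <- mat[idx, row$arm] + eff
  }
  mat
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate the eight-arm combination treatment experiment
#'
#' Log2 expression is baseline + per-gene batch shift + planted arm effect +
#' Gaussian noise. The same seed reproduces the output bit for bit.
#'
#' @param design A [treatment_design()].
#' @param effects An [effect_model()].
#' @param seed Integer seed.
#' @return A list: `expr` (log2 [expression_matrix()]), `annotation`
#'   (sample_id / arm / batch / replicate tibble), and `truth` — a tibble of
#'   the planted per-gene per-arm log2 effects.
#' @export
simulate_treatment_experiment <- function(design, effects, seed) {
  stopifnot(inherits(design, "treatment_design"), inherits(effects, "effect_model"))
  ann <- design_annotation(design)
  truth_mat <- effect_truth(design, effects)
  n_genes <- effects$n_genes
  withr::with_seed(seed, {
    baseline <- stats::runif(n_genes, effects$baseline_range[1], effects$baseline_range[2])
    batch_shift <- matrix(stats::rnorm(n_genes * length(design$batches),
                                       sd = effects$batch_sd),
                          n_genes, length(design$batches),
                          dimnames = list(NULL, design$batches))
    noise <- matrix(stats::rnorm(n_genes * nrow(ann), sd = effects$noise_sd),
                    n_genes, nrow(ann))
    vals <- baseline + truth_mat[, ann$arm, drop = FALSE] +
      batch_shift[, ann$batch, drop = FALSE] + noise
  })
  dimnames(vals) <- list(gene_ids(n_genes), ann$sample_id)
  truth <- tibble::as_tibble(as.data.frame.table(truth_mat, stringsAsFactors = FALSE))
  colnames(truth) <- c("gene", "arm", "effect")
  list(expr = expression_matrix(vals, "log2"), annotation = ann,
       truth = tibble::as_tibble(truth))
}

#' Cohort model with a latent immune-infiltration gradient
#'
#' Emulates a tumor cohort in which a continuous infiltration factor,
#' distributed as a three-component location mixture (latent low / medium /
#' high groups), loads on a core immune gene set and on an IFN gene set, so
#' that module scores over the two sets correlate through the shared factor.
#'
#' @param n_samples Cohort size (>= 3).
#' @param n_genes Genes in the universe.
#' @param immune_genes,ifn_genes Integer index sets.
#' @param mixture_locations Strictly increasing numeric vector of component
#'   means of the latent factor.
#' @param mixture_sd Within-component sd of the latent factor.
#' @param loadings Numeric `c(immune, ifn)` loadings of the factor on each set.
#' @param noise_sd Residual gene-level noise sd (log2 units).
#' @param baseline_range Per-gene baseline mean range.
#' @param allow_overlap If `FALSE` (default), overlapping immune/IFN index
#'   sets are rejected.
#' @return A list of class `cohort_model`.
#' @export
cohort_model <- function(n_samples = 500L, n_genes = 2000L,
                         immune_genes = 1:50, ifn_genes = 51:90,
                         mixture_locations = c(-2, 0, 2), mixture_sd = 0.4,
                         loadings = c(immune = 1.0, ifn = 0.8),
                         noise_sd = 0.5, baseline_range = c(6, 12),
                         allow_overlap = FALSE) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 3) rlang::abort("n_samples must be >= 3.")
  if (length(immune_genes) == 0 || length(ifn_genes) == 0) {
    rlang::abort("immune and IFN gene sets must be nonempty.")
  }
  if (!allow_overlap && length(intersect(immune_genes, ifn_genes)) > 0) {
    rlang::abort("immune and IFN gene sets overlap; set allow_overlap = TRUE to permit.")
  }
  if (any(diff(mixture_locations) <= 0)) {
    rlang::abort("mixture_locations must be strictly increasing.")
  }
  if (any(!is.finite(loadings))) rlang::abort("loadings must be finite.")
  structure(list(n_samples = n_samples, n_genes = as.integer(n_genes),
                 immune_genes = immune_genes, ifn_genes = ifn_genes,
                 mixture_locations = mixture_locations, mixture_sd = mixture_sd,
                 loadings = loadings, noise_sd = noise_sd,
                 baseline_range = baseline_range),
            class = "cohort_model")
}

#' Simulate an infiltration-graded cohort
#'
#' @param model A [cohort_model()].
#' @param seed Integer seed.
#' @return A list: `expr` (log2 [expression_matrix()]) and `truth` — a tibble
#'   with the per-sample latent infiltration value and mixture-component
#'   group label (`"low"`, `"medium"`, `"high"` for three components).
#' @export
simulate_cohort <- function(model, seed) {
  stopifnot(inherits(model, "cohort_model"))
  k <- length(model$mixture_locations)
  group_names <- if (k == 3) c("low", "medium", "high") else paste0("grp", seq_len(k))
  withr::with_seed(seed, {
    comp <- sample.int(k, model$n_samples, replace = TRUE)
    infiltration <- stats::rnorm(model$n_samples,
                                 mean = model$mixture_locations[comp],
                                 sd = model$mixture_sd)
    baseline <- stats::runif(model$n_genes, model$baseline_range[1],
                             model$baseline_range[2])
    vals <- baseline + matrix(stats::rnorm(model$n_genes * model$n_samples,
                                           sd = model$noise_sd),
                              model$n_genes, model$n_samples)
    vals[model$immune_genes, ] <- vals[model$immune_genes, ] +
      rep(model$loadings[["immune"]] * infiltration, each = length(model$immune_genes))
    vals[model$ifn_genes, ] <- vals[model$ifn_genes, ] +
      rep(model$loadings[["ifn"]] * infiltration, each = length(model$ifn_genes))
  })
  samples <- sprintf("t%04d", seq_len(model$n_samples))
  dimnames(vals) <- list(gene_ids(model$n_genes), samples)
  list(
    expr = expression_matrix(vals, "log2"),
    truth = tibble::tibble(sample_id = samples, infiltration = infiltration,
                           group = factor(group_names[comp], levels = group_names))
  )
}

#' Survival model with score-dependent hazard
#'
#' Event times are exponential with rate `baseline_rate * exp(coef * score)`;
#' follow-up ends at the earlier of an independent exponential censoring draw
#' and an administrative horizon.
#'
#' @param baseline_rate Events per unit time at score 0, > 0.
#' @param coef Log-hazard coefficient on the per-sample score.
#' @param admin_time Administrative censoring horizon, > 0.
#' @param censor_rate Rate of the independent censoring process (0 disables).
#' @return A list of class `survival_model`.
#' @export
survival_model <- function(baseline_rate = 0.1, coef = 1,
                           admin_time = 60, censor_rate = 0.02) {
  if (baseline_rate <= 0) rlang::abort("baseline_rate must be > 0.")
  if (admin_time <= 0) rlang::abort("admin_time must be > 0.")
  if (censor_rate < 0) rlang::abort("censor_rate must be >= 0.")
  structure(list(baseline_rate = baseline_rate, coef = coef,
                 admin_time = admin_time, censor_rate = censor_rate),
            class = "survival_model")
}

#' Simulate a survival table from per-sample scores
#'
#' @param scores Named (or unnamed) finite numeric vector, one per patient.
#' @param model A [survival_model()].
#' @param seed Integer seed.
#' @param endpoint Endpoint label (`"OS"`, `"RFS"` or `"DMFS"`).
#' @return A survival tibble: `patient_id`, `time`, `event`, `endpoint`.
#' @export
simulate_survival <- function(scores, model, seed, endpoint = "OS") {
  stopifnot(inherits(model, "survival_model"))
  if (length(scores) == 0) rlang::abort("scores must be nonempty.")
  if (any(!is.finite(scores))) rlang::abort("scores must be finite.")
  endpoint <- match.arg(endpoint, ENDPOINTS)
  n <- length(scores)
  ids <- names(scores)
  if (is.null(ids)) ids <- sprintf("p%04d", seq_len(n))
  withr::with_seed(seed, {
    rate <- model$baseline_rate * exp(model$coef * scores)
    t_event <- stats::rexp(n, rate = rate)
    t_cens <- if (model$censor_rate > 0) stats::rexp(n, rate = model$censor_rate) else rep(Inf, n)
  })
  t_cens <- pmin(t_cens, model$admin_time)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  # observed times must stay strictly positive for downstream validation
  time <- pmax(time, .Machine$double.eps)
  tibble::tibble(patient_id = ids, time = time, event = event, endpoint = endpoint)
}
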