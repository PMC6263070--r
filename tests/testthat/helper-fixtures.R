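# small builders used across test files

toy_matrix <- function(values, genes = NULL, samples = NULL, scale = "log2") {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, scale = scale)
}

# two-arm annotation for a matrix whose columns are already grouped
two_arm_annotation <- function(x, n_a, arm_a = "ED", arm_b = "Veh") {
  n <- ncol(x)
  tibble::tibble(
    sample_id = colnames(x),
    arm = rep(c(arm_a, arm_b), c(n_a, n - n_a)),
    batch = "b1",
    replicate = c(seq_len(n_a), seq_len(n - n_a))
  )
}

# matrix with planted mean differences for a subset of genes
planted_two_arm <- function(n_genes, n_per_arm, planted_idx, delta, sd, seed) {
  withr::with_seed(seed, {
    v <- matrix(stats::rnorm(n_genes * 2 * n_per_arm, mean = 8, sd = sd),
                n_genes, 2 * n_per_arm)
    v[planted_idx, seq_len(n_per_arm)] <- v[planted_idx, seq_len(n_per_arm)] + delta
  })
  x <- toy_matrix(v)
  list(expr = x, annotation = two_arm_annotation(x, n_per_arm))
}

# null experiment: all effects zero
null_experiment <- function(seed, n_genes = 400, reps = 4) {
  design <- treatment_design(arms = c("Veh", "ED"), replicates_per_arm = reps)
  effects <- effect_model(n_genes = n_genes, modules = list(),
                          effects = tibble::tibble(arm = character(),
                                                   module = character(),
                                                   log2fc = numeric(),
                                                   direction = character()),
                          noise_sd = 0.3, batch_sd = 0)
  simulate_treatment_experiment(design, effects, seed)
}

expect_tibble <- function(x, cols) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(cols %in% colnames(x)))
}
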