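test_that("background subtraction shifts by the percentile and floors at eps", {
  x <- toy_matrix(matrix(c(10, 20, 30, 5, 15, 25), 3, 2), scale = "raw_intensity")
  # percentile 0 = column minimum
  out <- background_subtract(x, percentile = 0, eps = 1)
  expect_equal(unclass(out)[, 1], c(1, 10, 20), ignore_attr = TRUE)
  expect_equal(unclass(out)[, 2], c(1, 10, 20), ignore_attr = TRUE)
  # constant column collapses to eps
  xc <- toy_matrix(matrix(c(7, 7, 7, 1, 2, 3), 3, 2), scale = "raw_intensity")
  outc <- background_subtract(xc, percentile = 5)
  expect_true(all(unclass(outc)[, 1] == 1))
  # precondition violations
  expect_error(background_subtract(x, percentile = 50), "50")
  xl <- toy_matrix(matrix(1:6, 3, 2), scale = "log2")
  expect_error(background_subtract(xl), "scale")
})

test_that("quantile normalization matches the sorted-mean oracle", {
  x <- toy_matrix(cbind(c(1, 2, 3), c(4, 5, 6)))
  out <- quantile_normalize(x)
  expect_equal(unclass(out)[, 1], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(unclass(out)[, 2], c(2.5, 3.5, 4.5), ignore_attr = TRUE)

  # order within each column is preserved; sorted columns identical
  set.seed(4)
  y <- toy_matrix(matrix(rnorm(60), 10, 6))
  qn <- quantile_normalize(y)
  for (j in 2:6) {
    expect_equal(unname(sort(unclass(qn)[, j])),
                 unname(sort(unclass(qn)[, 1])))
    expect_equal(order(unclass(qn)[, j]), order(unclass(y)[, j]))
  }

  # identical columns are a fixed point
  z <- toy_matrix(matrix(rep(c(5, 1, 3), 3), 3, 3))
  expect_equal(unclass(quantile_normalize(z)), unclass(z))
})

test_that("quantile normalization averages reference values across ties", {
  # column 1 has a tie at ranks 1-2; reference = mean of sorted columns
  x <- toy_matrix(cbind(c(1, 1, 5), c(2, 4, 6)))
  ref <- rowMeans(cbind(c(1, 1, 5), c(2, 4, 6)))  # 1.5, 2.5, 5.5
  out <- unclass(quantile_normalize(x))
  expect_equal(out[, 1], c(2, 2, 5.5), ignore_attr = TRUE)  # mean(1.5, 2.5) = 2
  expect_equal(out[, 2], ref, ignore_attr = TRUE)
})

test_that("quantile normalization is idempotent", {
  set.seed(9)
  x <- toy_matrix(matrix(rnorm(80), 16, 5))
  once <- quantile_normalize(x)
  twice <- quantile_normalize(once)
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-10)
})

test_that("log2_with_offset transforms, flags, and inverts", {
  x <- toy_matrix(matrix(c(1, 3, 7), 3, 1), scale = "raw_intensity")
  out <- log2_with_offset(x, offset = 1)
  expect_equal(as.vector(unclass(out)), c(1, 2, 3))
  expect_identical(expr_scale(out), "log2")
  expect_error(log2_with_offset(out), "scale")
  expect_error(log2_with_offset(x, offset = 0), "offset")
  back <- 2^unclass(out) - 1
  expect_equal(as.vector(back), c(1, 3, 7), tolerance = 1e-10)
})

test_that("batch centering removes additive shifts exactly, preserves grand means", {
  set.seed(2)
  v <- matrix(rnorm(40, mean = 8), 10, 4)
  v[, 3:4] <- v[, 3:4] + 2  # batch b2 shifted +2 on every gene
  x <- toy_matrix(v)
  ann <- tibble::tibble(sample_id = colnames(x),
                        arm = c("Veh", "ED", "Veh", "ED"),
                        batch = c("b1", "b1", "b2", "b2"), replicate = 1:4)
  out <- batch_center(x, ann)
  m1 <- rowMeans(unclass(out)[, 1:2])
  m2 <- rowMeans(unclass(out)[, 3:4])
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_equal(unname(rowMeans(unclass(out))), rowMeans(v), tolerance = 1e-10)

  # single batch = identity
  ann1 <- ann; ann1$batch <- "b1"
  expect_equal(unclass(batch_center(x, ann1)), unclass(x))

  # batch confounded 1:1 with arm is refused
  ann_conf <- tibble::tibble(sample_id = colnames(x),
                             arm = c("Veh", "Veh", "ED", "ED"),
                             batch = c("b1", "b1", "b2", "b2"), replicate = 1:4)
  expect_error(batch_center(x, ann_conf), "confounded")
})

test_that("PCA matches the two-sample closed form and fixes signs", {
  v <- cbind(c(1, 2, 3, 4), c(2, 4, 1, 8))
  x <- toy_matrix(v)
  p <- expr_pca(x, k = 1)
  # PC1 loading is the normalized difference of the two centered samples
  centered <- v - rowMeans(v)
  diff <- centered[, 1] - centered[, 2]
  expected <- diff / sqrt(sum(diff^2))
  expected <- expected * sign(expected[which.max(abs(expected))])
  expect_equal(as.vector(p$loadings), expected, tolerance = 1e-10)
  expect_equal(p$var_explained, 1, tolerance = 1e-12)
  # coordinates reproduce projections of centered data
  expect_equal(as.vector(p$coordinates),
               as.vector(t(centered) %*% p$loadings), tolerance = 1e-10)
})

test_that("PCA is invariant to duplicated samples and validates k", {
  set.seed(5)
  v <- matrix(rnorm(30, 8), 10, 3)
  x <- toy_matrix(cbind(v, v[, 3]), samples = c("s1", "s2", "s3", "s3dup"))
  p <- expr_pca(x, k = 2)
  expect_equal(p$coordinates["s3", ], p$coordinates["s3dup", ], tolerance = 1e-8)
  expect_error(expr_pca(x, k = 4), "k")
  # explained variance fractions are non-increasing, in [0,1], sum <= 1
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_true(all(p$var_explained >= 0 & p$var_explained <= 1))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("batch centering then PCA removes batch separation on generator data", {
  d <- treatment_design(replicates_per_arm = 4)
  em <- effect_model(n_genes = 600, batch_sd = 1)
  sim <- simulate_treatment_experiment(d, em, 17)
  corrected <- batch_center(sim$expr, sim$annotation)
  p_raw <- expr_pca(sim$expr, k = 2)
  p_cor <- expr_pca(corrected, k = 2)
  batch <- as.integer(factor(sim$annotation$batch))
  cor_raw <- max(abs(cor(p_raw$coordinates, batch)))
  cor_cor <- max(abs(cor(p_cor$coordinates, batch)))
  expect_gt(cor_raw, 0.8)   # planted batch effect dominates a PC before
  expect_lt(cor_cor, 0.2)   # and is gone after
})
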