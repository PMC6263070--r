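test_that("module score is the mean z over members", {
  set.seed(31)
  v <- matrix(rnorm(40, 8), 4, 10)
  x <- toy_matrix(v)
  sc <- module_score(x, c("g1", "g3"))
  z1 <- (v[1, ] - mean(v[1, ])) / sd(v[1, ])
  z3 <- (v[3, ] - mean(v[3, ])) / sd(v[3, ])
  expect_equal(unname(sc), (z1 + z3) / 2, tolerance = 1e-12)
  expect_equal(mean(sc), 0, tolerance = 1e-12)
  # one-gene set is that gene's z-score
  expect_equal(unname(module_score(x, "g2")),
               (v[2, ] - mean(v[2, ])) / sd(v[2, ]), tolerance = 1e-12)
})

test_that("zero-variance members are dropped with warning; all-flat errors", {
  v <- rbind(rnorm(6), rep(5, 6))
  x <- toy_matrix(v)
  expect_warning(sc <- module_score(x, c("g1", "g2")), "g2")
  expect_equal(unname(sc), unname(module_score(x, "g1")))
  xflat <- toy_matrix(matrix(rep(c(3, 7), each = 4), 2, 4, byrow = TRUE))
  expect_error(suppressWarnings(module_score(xflat, c("g1", "g2"))), "variance")
})

test_that("module scores track planted activity on generator data", {
  cm <- cohort_model(n_samples = 500)
  co <- simulate_cohort(cm, 32)
  imm <- sprintf("g%04d", cm$immune_genes)
  sc <- module_score(co$expr, imm)
  expect_gt(cor(sc, co$truth$infiltration, method = "spearman"), 0.9)
})

test_that("stratification recovers planted mixture groups and orders them", {
  aris <- vapply(1:3, function(s) {
    co <- simulate_cohort(cohort_model(n_samples = 300), s)
    st <- stratify_infiltration(co$expr, sprintf("g%04d", 1:50))
    synsig:::adjusted_rand_index(st$group, co$truth$group)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
  # ordering contract: mean immune score strictly increasing low -> high
  co <- simulate_cohort(cohort_model(n_samples = 300), 99)
  st <- stratify_infiltration(co$expr, sprintf("g%04d", 1:50))
  means <- tapply(st$immune_score, st$group, mean)
  expect_true(all(diff(means) > 0))
})

test_that("three exact template profiles are perfectly recovered", {
  templates <- matrix(c(0, 0, 0, 4, 4, 4, 8, 8, 8), 3, 3)
  v <- templates[, rep(1:3, each = 3)] + 0  # exact copies
  # add a trace of noise so genes have variance across samples within groups
  set.seed(33)
  v <- v + matrix(rnorm(27, sd = 1e-6), 3, 9)
  x <- toy_matrix(v)
  st <- stratify_infiltration(x, c("g1", "g2", "g3"), k = 3)
  truth <- rep(1:3, each = 3)
  expect_equal(synsig:::adjusted_rand_index(st$group, truth), 1)
})

test_that("score group tests match direct formulas with Bonferroni capping", {
  scores <- c(1.1, 0.9, 1.3, 2.0, 2.2, 1.9, 3.3, 2.9, 3.1)
  groups <- rep(c("low", "medium", "high"), each = 3)
  res <- score_group_tests(scores, groups)
  fit <- anova(lm(scores ~ groups))
  expect_equal(res$anova$f, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res$anova$p, fit$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)
  for (i in 1:3) {
    a <- scores[groups == res$pairwise$group1[i]]
    b <- scores[groups == res$pairwise$group2[i]]
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$pairwise$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$pairwise$p_adj[i], min(tt$p.value * 3, 1), tolerance = 1e-10)
  }
  # two groups: Bonferroni factor is 1
  res2 <- score_group_tests(scores[1:6], groups[1:6])
  expect_equal(res2$pairwise$p_adj, res2$pairwise$p)
  # identical distributions: adjusted p capped at 1
  res3 <- score_group_tests(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(res3$anova$f, 0, tolerance = 1e-10)
  expect_true(all(res3$pairwise$p_adj == 1))
  expect_error(score_group_tests(1:4, c("a", "a", "a", "b")), "Singleton")
})

test_that("spearman_cor matches mid-rank Pearson and handles monotone pairs", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # tied example vs brute-force oracle
  xt <- c(1, 2, 2, 3, 4)
  yt <- c(5, 5, 7, 8, 8)
  oracle <- cor(rank(xt), rank(yt))
  expect_equal(spearman_cor(xt, yt)$rho, oracle, tolerance = 1e-12)
  # rho agrees with R's spearman on tie-free data
  set.seed(41)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_cor(a, b)$rho,
               unname(cor.test(a, b, method = "spearman")$estimate),
               tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 1:4), "length")
})

test_that("gene-wise permutation p is bounded, calibrated and sample-order invariant", {
  cm <- cohort_model(n_samples = 120)
  co <- simulate_cohort(cm, 51)
  imm <- sprintf("g%04d", cm$immune_genes)
  ifn <- sprintf("g%04d", cm$ifn_genes)
  sc <- module_score(co$expr, imm)
  res <- genewise_permutation_test(co$expr, ifn, sc, n_perm = 200, seed = 5,
                                   exclude = imm)
  expect_gte(res$p, 1 / 201)
  expect_lte(res$p, 1)
  expect_equal(res$p, 1 / 201)  # planted association beats all random sets

  # invariance to sample reordering (same seed)
  perm <- sample(ncol(co$expr))
  xp <- expression_matrix(unclass(co$expr)[, perm], "log2")
  res2 <- genewise_permutation_test(xp, ifn, sc[colnames(xp)], n_perm = 200,
                                    seed = 5, exclude = imm)
  expect_equal(res2$p, res$p)
  expect_equal(res2$rho, res$rho, tolerance = 1e-12)

  # background smaller than target set errors
  expect_error(
    genewise_permutation_test(co$expr, ifn, sc, n_perm = 10, seed = 1,
                              background = sprintf("g%04d", 100:110)),
    "smaller")
})

test_that("sampled gene-wise null matches exhaustive enumeration on a tiny universe", {
  # universe: 2 target genes + 4 background genes -> 6 possible null sets
  set.seed(61)
  v <- matrix(rnorm(6 * 40, 8), 6, 40)
  x <- toy_matrix(v)
  target <- c("g1", "g2")
  bg <- c("g3", "g4", "g5", "g6")
  sc <- setNames(rnorm(40), colnames(x))
  obs <- spearman_cor(module_score(x, target), sc)$rho
  combos <- combn(bg, 2, simplify = FALSE)
  exact_null <- vapply(combos, function(s)
    spearman_cor(module_score(x, s), sc)$rho, numeric(1))
  exact_rate <- mean(exact_null >= obs)
  res <- genewise_permutation_test(x, target, sc, n_perm = 6000, seed = 9,
                                   background = bg)
  se <- sqrt(exact_rate * (1 - exact_rate) / 6000)
  expect_lt(abs(res$p - exact_rate), 4 * se + 2 / 6001)
})

test_that("under a null cohort the permutation test rejects at its nominal rate", {
  # IFN loading zero: target set carries no infiltration signal
  cm <- cohort_model(n_samples = 60, n_genes = 300, immune_genes = 1:30,
                     ifn_genes = 31:60, loadings = c(immune = 1, ifn = 0))
  rejected <- vapply(1:40, function(s) {
    co <- simulate_cohort(cm, s)
    sc <- module_score(co$expr, sprintf("g%04d", 1:30))
    res <- genewise_permutation_test(co$expr, sprintf("g%04d", 31:60), sc,
                                     n_perm = 60, seed = s,
                                     exclude = sprintf("g%04d", 1:30))
    res$p <= 0.05
  }, logical(1))
  # 95% binomial interval around 0.05 with 40 draws
  expect_lte(mean(rejected), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 40))
})
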