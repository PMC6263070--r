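test_that("median split puts strict exceeders high and ties low", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))), c("low", "low", "high", "high"))
  expect_equal(unname(median_split(c(1, 1, 2))), c("low", "low", "high"))
  expect_error(median_split(rep(3, 5)), "equal")
  expect_error(median_split(1), "2 samples")
})

test_that("KM estimate matches the hand product-limit oracle", {
  tab <- tibble::tibble(patient_id = paste0("p", 1:5),
                        time = c(1, 2, 3, 4, 5),
                        event = c(1L, 0L, 1L, 0L, 1L),
                        endpoint = "OS")
  km <- km_estimate(tab)
  # S = 0.8 after t=1; 0.8 * (1 - 1/3) = 0.5333 after t=3; 0 after t=5
  expect_equal(km$surv[km$time == 1], 0.8)
  expect_equal(km$surv[km$time == 3], 0.8 * 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 5], 0)
  expect_equal(km$n_risk, c(5, 4, 3, 2, 1))
  # censored-only times leave S unchanged
  expect_equal(km$surv[km$time == 2], 0.8)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(71)
  times <- round(rexp(40, 0.2), 2) + 0.01
  tab <- tibble::tibble(patient_id = paste0("p", 1:40), time = times,
                        event = 1L, endpoint = "OS")
  km <- km_estimate(tab)
  for (i in seq_len(nrow(km))) {
    expect_equal(km$surv[i], mean(times > km$time[i]), tolerance = 1e-12)
  }
})

test_that("KM handles the no-event and single-time edge cases", {
  tab <- tibble::tibble(patient_id = paste0("p", 1:4), time = 1:4,
                        event = 0L, endpoint = "OS")
  expect_true(all(km_estimate(tab)$surv == 1))
  tab2 <- tibble::tibble(patient_id = paste0("p", 1:4), time = 2,
                         event = 1L, endpoint = "OS")
  km2 <- km_estimate(tab2)
  expect_equal(km2$surv, 0)
  expect_error(km_estimate(tab[0, ]), "Empty")
})

test_that("logrank O/E/V matches a hand-computed toy table", {
  # A: events at 1, 3; censored at 4.  B: events at 2, 5; censored at 6.
  ta <- tibble::tibble(patient_id = c("a1", "a2", "a3"),
                       time = c(1, 3, 4), event = c(1L, 1L, 0L), endpoint = "OS")
  tb <- tibble::tibble(patient_id = c("b1", "b2", "b3"),
                       time = c(2, 5, 6), event = c(1L, 1L, 0L), endpoint = "OS")
  res <- logrank_test(ta, tb)
  # hand computation over event times 1, 2, 3, 5:
  # t=1: nA=3 nB=3 d=1 -> E_A += 1/2,  V += (1*3*3*5)/(36*5) = 1/4
  # t=2: nA=2 nB=3 d=1 -> E_A += 2/5,  V += (2*3*4)/(25*4) = 6/25
  # t=3: nA=2 nB=2 d=1 -> E_A += 1/2,  V += (2*2*3)/(16*3) = 1/4
  # t=5: nA=0 nB=2 d=1 -> E_A += 0,    V += 0
  E_A <- 0.5 + 0.4 + 0.5
  V <- 0.25 + 0.24 + 0.25
  expect_equal(res$expected[["A"]], E_A, tolerance = 1e-10)
  expect_equal(res$observed[["A"]], 2)
  expect_equal(res$chisq, (2 - E_A)^2 / V, tolerance = 1e-10)
  expect_equal(res$hr, (2 / E_A) / (2 / (4 - E_A)), tolerance = 1e-10)
  expect_true(res$ci_low < res$hr && res$hr < res$ci_high)
})

test_that("identical groups give chi-square 0, p 1, HR 1; HR inverts on swap", {
  tab <- tibble::tibble(patient_id = paste0("p", 1:6),
                        time = c(1, 2, 3, 4, 5, 6),
                        event = c(1L, 1L, 0L, 1L, 1L, 0L), endpoint = "OS")
  res_same <- logrank_test(tab, dplyr::mutate(tab, patient_id = paste0("q", 1:6)))
  expect_equal(res_same$chisq, 0, tolerance = 1e-10)
  expect_equal(res_same$p, 1, tolerance = 1e-10)
  expect_equal(res_same$hr, 1, tolerance = 1e-10)

  set.seed(72)
  ta <- tibble::tibble(patient_id = paste0("a", 1:30),
                       time = rexp(30, 0.3) + 0.01,
                       event = rbinom(30, 1, 0.8), endpoint = "OS")
  tb <- tibble::tibble(patient_id = paste0("b", 1:30),
                       time = rexp(30, 0.15) + 0.01,
                       event = rbinom(30, 1, 0.8), endpoint = "OS")
  ab <- logrank_test(ta, tb)
  ba <- logrank_test(tb, ta)
  expect_equal(ab$chisq, ba$chisq, tolerance = 1e-12)
  expect_equal(ab$hr, 1 / ba$hr, tolerance = 1e-12)
})

test_that("KM and logrank agree with the survival package on random tables", {
  skip_if_not_installed("survival")
  set.seed(73)
  for (i in 1:15) {
    n <- 40
    time <- round(rexp(n, 0.2), 3) + 1e-3
    event <- rbinom(n, 1, 0.7)
    grp <- rep(c(1, 2), each = n / 2)
    tab <- tibble::tibble(patient_id = paste0("p", 1:n), time = time,
                          event = as.integer(event), endpoint = "OS")
    # KM vs survfit
    km <- km_estimate(tab)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    at_events <- km[km$n_event > 0, ]
    sf_surv <- summary(sf, times = at_events$time)$surv
    expect_equal(at_events$surv, sf_surv, tolerance = 1e-8)
    # logrank vs survdiff
    if (sum(event[grp == 1]) > 0 && sum(event[grp == 2]) > 0) {
      res <- logrank_test(tab[grp == 1, ], tab[grp == 2, ])
      sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
      expect_equal(res$chisq, sd$chisq, tolerance = 1e-8)
      expect_equal(unname(res$expected), unname(sd$exp), tolerance = 1e-8)
    }
  }
})

test_that("planted hazard is detected with the right HR direction", {
  detected <- vapply(1:10, function(s) {
    scores <- rep(c(0, 1), each = 150)
    tab <- simulate_survival(scores, survival_model(coef = 1), s)
    res <- logrank_test(tab[scores == 1, ], tab[scores == 0, ])
    res$hr > 1 && res$p < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("prognosis scan flags a planted protective gene and is deterministic", {
  set.seed(74)
  n <- 300
  v <- matrix(rnorm(20 * n, 8), 20, n)
  x <- toy_matrix(v, samples = sprintf("p%04d", 1:n))
  protective <- scale(v[7, ])[, 1]
  tab <- simulate_survival(setNames(-protective, colnames(x)),
                           survival_model(coef = 1), 75)
  res <- prognosis_scan(x, list(OS = tab), genes = c("g7", "g1"))
  hit <- res[res$gene == "g7", ]
  expect_lt(hit$hr, 1)
  expect_lt(hit$p, 0.05)
  # duplicate endpoint tables give identical rows
  res2 <- prognosis_scan(x, list(OS = tab, OS2 = tab), genes = "g7")
  expect_equal(res2$hr[1], res2$hr[2])
  expect_equal(res2$p[1], res2$p[2])
  # no overlap errors
  tab_bad <- dplyr::mutate(tab, patient_id = paste0("zz", patient_id))
  expect_error(prognosis_scan(x, list(OS = tab_bad), genes = "g7"), "overlap")
})

test_that("null prognosis scan keeps p roughly uniform", {
  set.seed(76)
  n <- 120
  v <- matrix(rnorm(5 * n, 8), 5, n)
  x <- toy_matrix(v, samples = sprintf("p%04d", 1:n))
  ps <- vapply(1:30, function(s) {
    tab <- simulate_survival(setNames(rep(0, n), colnames(x)),
                             survival_model(coef = 0), s)
    res <- prognosis_scan(x, list(OS = tab), genes = "g1")
    res$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
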