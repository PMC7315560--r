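# Mitotic-clock scores and rate estimators.

test_that("TNSC estimation inverts the first-order model exactly", {
  params <- make_params(40)
  tnscs <- c(0, 150, 700, 1400, 2600)
  m <- first_order_matrix(params, tnscs)
  est <- estimate_tnsc(m, params)
  expect_equal(unname(est), tnscs, tolerance = 1e-9)
  # betas at the ground state give zero divisions
  base <- matrix(params$beta0, ncol = 1,
                 dimnames = list(params$probe_id, "s1"))
  expect_equal(unname(estimate_tnsc(base, params)), 0, tolerance = 1e-12)
})

test_that("with flat kinetics TNSC is proportional to the mean beta", {
  # beta0 = 0 and a common delta reduce the model clock to the averaging one
  params <- data.frame(probe_id = sprintf("cg%02d", 1:20),
                       delta = 5e-5, beta0 = 0)
  withr::with_seed(3, {
    m <- matrix(runif(20 * 4, 0, 0.3), nrow = 20,
                dimnames = list(params$probe_id, sprintf("s%d", 1:4)))
  })
  tnsc <- estimate_tnsc(m, params)
  avg <- pcgt_age_score(m, params$probe_id)
  expect_equal(unname(tnsc), unname((2 / 5e-5) * avg), tolerance = 1e-9)
})

test_that("TNSC coverage and sign policies", {
  params <- make_params(10)
  m <- first_order_matrix(params, c(500, 800))
  # below 80% probe overlap: error names missing probes
  expect_error(estimate_tnsc(m[1:7, ], params), "missing")
  # negative contributions are reported, not clipped
  low <- matrix(pmax(params$beta0 - 0.03, 0), ncol = 1,
                dimnames = list(params$probe_id, "s1"))
  expect_warning(est <- estimate_tnsc(low, params), "negative TNSC")
  expect_lt(est, 0)
})

test_that("lifetime and intrinsic rates follow their definitions", {
  expect_equal(lifetime_rate(350, 10), 35)
  expect_equal(lifetime_rate(0, 50), 0)
  expect_error(lifetime_rate(100, 0), "positive")
  expect_error(lifetime_rate(100, NA), "positive")

  dr <- intrinsic_rate(c(30, 35, 40) * 10, rep(10, 3))
  expect_equal(dr$ir, 35)
  expect_equal(dr$estimator, "median")
  # the median shrugs off an outlier sample
  expect_equal(intrinsic_rate(c(30, 35, 100) * 10, rep(10, 3))$ir, 35)
  expect_equal(intrinsic_rate(c(30, 35, 100) * 10, rep(10, 3),
                              estimator = "mean")$ir, 55)
  expect_error(intrinsic_rate(numeric(0), numeric(0)), "no samples")
})

test_that("simulation round trip: cohort rates centre on the true IR", {
  # clock-like kinetics (the modal blood de novo rate): the regime where
  # the first-order division-count estimator is valid
  sim <- simulate_cohort(simulation_spec(seed = 50, delta_pool = 5e-5))
  cf <- fit_cohort(sim$betas, sim$ages)
  m <- sim$betas[cf$params$probe_id, ]
  tnsc <- estimate_tnsc(m, cf$params)
  dr <- intrinsic_rate(tnsc, sim$ages)
  expect_equal(dr$ir, 35, tolerance = 0.05)
  expect_equal(intrinsic_rate(tnsc, sim$ages, estimator = "mean")$ir, 35,
               tolerance = 0.05)
})

test_that("averaging scores are means with coverage checks", {
  probes <- sprintf("cg%02d", 1:10)
  m <- matrix(0.2, nrow = 10, ncol = 2, dimnames = list(probes, c("a", "b")))
  expect_equal(unname(pcgt_age_score(m, probes)), c(0.2, 0.2))
  m2 <- m; m2[, 2] <- rep(c(0, 1), 5)
  expect_equal(unname(hypo_score(m2, probes))[2], 0.5)
  expect_error(hypo_score(m[1:5, ], probes), "80%")
})

test_that("mitotically older loss cohorts score lower on HypoClock", {
  young <- simulate_cohort(small_spec(seed = 51, direction = "loss"))
  probes <- rownames(young$betas)
  sc <- hypo_score(young$betas, probes)
  # within one cohort, older samples (more divisions) have lower scores
  expect_lt(cor(sc, young$ages), -0.6)
})

test_that("age adjustment and its anti-correlation contract", {
  adj <- hypo_age_adjust(c(0.9, 0.8), c(50, 100))
  expect_equal(adj$adjusted, c(0.002, 0.002))
  expect_equal(adj$median, 0.002)
  expect_equal(hypo_age_adjust(1, 77)$adjusted, 0)
  expect_error(hypo_age_adjust(0.5, -1), "positive")

  # faster-dividing loss cohorts yield larger age-adjusted values
  slow <- simulate_cohort(small_spec(seed = 52, direction = "loss",
                                     true_ir = 10))
  fast <- simulate_cohort(small_spec(seed = 52, direction = "loss",
                                     true_ir = 60))
  probes <- rownames(slow$betas)
  med_slow <- hypo_age_adjust(hypo_score(slow$betas, probes), slow$ages)$median
  med_fast <- hypo_age_adjust(hypo_score(fast$betas, probes), fast$ages)$median
  expect_gt(med_fast, med_slow)
})

test_that("rescaling restores the raw dynamic range", {
  out <- hypo_rescale(c(0.6, 0.8), c(0.005, 0.009))
  expect_equal(out, c(0.2, 0.4))
  withr::with_seed(60, {
    hypo <- runif(50, 0.4, 0.95)
    adj <- (1 - hypo) / runif(50, 20, 90)
    res <- hypo_rescale(hypo, adj)
    expect_equal(diff(range(res)), diff(range(hypo)))  # range preserved
    expect_equal(max(res), max(1 - hypo))              # max anchored
  })
  expect_error(hypo_rescale(c(0.6, 0.8), c(0.005, 0.005)), "distinct")
  expect_error(hypo_rescale(0.6, 0.005), "distinct")
})

test_that("turnover and skin converters reproduce the reference values", {
  expect_equal(turnover_to_ir(10), 36.5)
  expect_equal(turnover_to_ir(5.5), 66.4, tolerance = 1e-3)
  expect_equal(turnover_to_ir(365), 1)
  expect_error(turnover_to_ir(0), "positive")

  expect_equal(skin_lifetime_ir(15), 365 / 21)
  expect_equal(skin_lifetime_ir(20), 365 / 21)
  # independent piecewise arithmetic
  expect_equal(skin_lifetime_ir(35),
               (20 * 365 / 21 + 15 * 365 / 35) / 35)
  expect_equal(skin_lifetime_ir(80),
               (20 * 365 / 21 + 30 * 365 / 35 + 30 * 365 / 90) / 80)
  # cohort averaging differs from point evaluation for dispersed ages
  ages <- c(30, 50, 70)
  expect_equal(skin_cohort_ir(ages), mean(skin_lifetime_ir(ages)))
})

test_that("group AUC is the Mann-Whitney statistic", {
  res <- group_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(res$auc, 1)
  expect_lt(res$p_value, 0.15)
  # identical distributions: exactly 0.5 under full ties
  expect_equal(group_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  # complementary labelings are mirror images
  s <- c(3, 1, 4, 1, 5, 9, 2, 6)
  g <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_equal(group_auc(s, g)$auc + group_auc(s, 1 - g)$auc, 1)
  expect_error(group_auc(1:4, rep(1, 4)), "two groups")
})

test_that("score_cohort assembles the per-sample table", {
  sim <- simulate_cohort(small_spec(seed = 55, n_sites = 20,
                                    delta_pool = c(5e-5, 1e-4)))
  bm <- as_beta_matrix(sim)
  cf <- fit_cohort(bm)
  probes <- rownames(sim$betas)
  sc <- score_cohort(bm, params = cf$params,
                     epitoc_probes = probes, hypo_probes = probes)
  expect_setequal(names(sc), c("sample_id", "age", "tnsc", "rate",
                               "pcgt_age", "hypo_score", "hypo_age_adj",
                               "hypo_rescaled"))
  expect_equal(nrow(sc), 60)
  expect_equal(sc$rate, sc$tnsc / sc$age)
  expect_equal(stats::median(sc$rate), 35, tolerance = 0.1)
  # per-group rescaling covers each group separately
  grp <- rep(c("x", "y"), 30)
  sc2 <- score_cohort(bm, hypo_probes = probes, rescale_by = grp)
  for (g in c("x", "y")) {
    idx <- grp == g
    expect_equal(diff(range(sc2$hypo_rescaled[idx])),
                 diff(range(sc2$hypo_score[idx])))
  }
})

test_that("clock definitions validate probes and parameters", {
  params <- make_params(3)
  cd <- clock_definition("epiTOC2", params$probe_id, params)
  expect_s3_class(cd, "clock_definition")
  expect_error(clock_definition("x", c("a", "a")), "unique")
  expect_error(clock_definition("x", character(0)), "non-empty")
  expect_error(clock_definition("x", c("a", "b"), params), "cover")
})
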