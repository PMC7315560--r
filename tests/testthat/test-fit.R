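# Per-CpG estimation: grid multi-start fit, filtering, consensus, refit.

test_that("noise-free site is recovered from the starting grid", {
  ages <- seq(19, 101, length.out = 200)
  betas <- trajectory_approx(5e-5, 0.05, ages * 35)
  f <- fit_site(betas, ages)
  expect_true(f$converged)
  expect_equal(f$delta_hat * f$ir_hat, 5e-5 * 35, tolerance = 1e-3)
  expect_equal(f$beta0_hat, 0.05, tolerance = 0.005)
  expect_lt(f$rss, 1e-20)
})

test_that("multi-start fit never exceeds the RSS of any single start", {
  sim <- simulate_cohort(small_spec(seed = 40, n_sites = 3))
  grid <- fit_grid()
  for (i in 1:3) {
    f <- fit_site(sim$betas[i, ], sim$ages, grid = grid)
    # manual objective at a handful of starts, beta0 at its grid values
    for (d in c(1e-5, 5e-5, 1e-3)) {
      for (ir in c(1, 35, 100)) {
        for (b0 in c(0, 0.05)) {
          rss <- sum((sim$betas[i, ] -
                        trajectory_approx(d, b0, sim$ages * ir))^2)
          expect_lte(f$rss, rss + 1e-12)
        }
      }
    }
  }
})

test_that("constant betas give a degenerate fit with no accrual signal", {
  ages <- seq(20, 90, length.out = 50)
  f <- fit_site(rep(0.05, 50), ages)
  expect_false(f$converged)
  expect_true(f$degenerate)
  expect_lt(f$delta_hat * f$ir_hat, 1e-6)
})

test_that("input validation: sample floor, age hygiene, beta range", {
  ages <- seq(20, 90, length.out = 50)
  expect_error(fit_site(runif(10), seq(20, 90, length.out = 10)),
               "at least 30")
  expect_error(fit_site(rep(1.5, 50), ages), "\\[0, 1\\]")
  b <- trajectory_approx(5e-5, 0.05, ages * 35)
  a2 <- ages; a2[1:3] <- -1
  expect_warning(f <- fit_site(b, a2), "non-positive age")
  expect_equal(f$n_used, 47)
})

test_that("noisy simulated sites recover the rate product within 30%", {
  sim <- simulate_cohort(small_spec(seed = 41, n_sites = 7))
  fits <- fit_sites(sim$betas, sim$ages)
  strong <- sim$truth$true_delta >= 1e-4  # resolvable accrual at n = 60
  prod_hat <- fits$delta * fits$ir_site
  prod_true <- sim$truth$true_delta * sim$truth$true_ir
  expect_true(all(abs(prod_hat[strong] / prod_true[strong] - 1) < 0.3))
})

test_that("rate-product filter keeps resolvable probes, preserves order", {
  fits <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    delta = c(5e-5, 1e-5, 2e-4, 5e-5),
    beta0 = 0, ir_site = 35, rss = 0.1,
    converged = c(TRUE, TRUE, TRUE, FALSE))
  kept <- filter_sites(fits)
  expect_identical(kept, c("a", "c"))  # b below threshold, d unconverged
  # idempotent on the retained subset
  expect_identical(filter_sites(fits[fits$probe_id %in% kept, ]), kept)
  expect_identical(filter_sites(fits[0, ]), character(0))
})

test_that("consensus vote picks the most represented (delta, IR) cell", {
  unan <- data.frame(probe_id = sprintf("p%d", 1:10),
                     delta = 5e-5, beta0 = 0.05, ir_site = 35,
                     rss = 0.1, converged = TRUE)
  cons <- consensus_rate(unan)
  expect_equal(cons$modal_delta, 5e-5)
  expect_equal(cons$modal_ir, 35)

  plur <- data.frame(
    probe_id = sprintf("p%d", 1:18),
    delta = c(rep(5e-5, 10), rep(1e-4, 5), rep(5e-5, 3)),
    beta0 = 0.05,
    ir_site = c(rep(35, 10), rep(35, 5), rep(30, 3)),
    rss = 0.1, converged = TRUE)
  cons <- consensus_rate(plur)
  expect_equal(cons$modal_delta, 5e-5)
  expect_equal(cons$modal_ir, 35)

  # off-grid estimates snap (delta in log space, IR linearly)
  off <- data.frame(probe_id = "p1", delta = 6e-5, beta0 = 0.05,
                    ir_site = 33.4, rss = 0.1, converged = TRUE)
  cons <- consensus_rate(off)
  expect_equal(cons$modal_delta, 5e-5)
  expect_equal(cons$modal_ir, 35)
  expect_error(consensus_rate(unan[0, ]), "no converged fits")
})

test_that("fixed-rate refit recovers parameters exactly on noise-free data", {
  params <- make_params(6)
  ages <- seq(19, 101, length.out = 80)
  m <- vapply(ages, function(a) {
    vapply(seq_len(nrow(params)), function(i) {
      trajectory_approx(params$delta[i], params$beta0[i], a * 35)
    }, numeric(1))
  }, numeric(nrow(params)))
  rownames(m) <- params$probe_id
  refit <- refit_fixed_rate(m, ages, ir = 35)
  expect_true(all(refit$converged))
  expect_equal(refit$delta, params$delta, tolerance = 1e-6)
  expect_equal(refit$beta0, params$beta0, tolerance = 1e-6)
})

test_that("refit at a doubled rate halves the delta estimates", {
  # in the near-linear regime only the product delta * IR is identified
  ages <- seq(19, 101, length.out = 80)
  m <- matrix(trajectory_approx(5e-5, 0.05, ages * 35), nrow = 1,
              dimnames = list("cg1", NULL))
  at_truth <- refit_fixed_rate(m, ages, ir = 35)
  at_double <- refit_fixed_rate(m, ages, ir = 70)
  expect_equal(at_double$delta / at_truth$delta, 0.5, tolerance = 1e-3)
})

test_that("refit under cohort noise pins the ground state", {
  sim <- simulate_cohort(simulation_spec(n_sites = 7, seed = 44))
  i <- which(sim$truth$true_delta == 5e-5)
  refit <- refit_fixed_rate(sim$betas[i, , drop = FALSE], sim$ages, ir = 35)
  expect_lt(abs(refit$beta0 - 0.05), 0.01)
})

test_that("full pipeline on a reduced site panel finds the generating rate", {
  # consensus needs the full cohort depth; the site panel can be smaller
  sim <- simulate_cohort(simulation_spec(n_sites = 28, seed = 46))
  cf <- fit_cohort(sim$betas, sim$ages)
  expect_equal(cf$modal_ir, 35)
  expect_true(all(cf$params$probe_id %in% cf$retained))
  # dropped probes are the slow ones (delta * IR below assay resolution)
  slow <- sim$truth$probe_id[sim$truth$true_delta * 35 < 0.001]
  expect_true(!any(slow %in% cf$retained))
})

test_that("parameter tables round-trip through text", {
  sim <- simulate_cohort(small_spec(seed = 47, n_sites = 14))
  cf <- fit_cohort(sim$betas, sim$ages)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_parameter_table(cf, path)
  tab <- read_parameter_table(path)
  expect_equal(attr(tab, "modal_ir"), cf$modal_ir)
  expect_setequal(tab$probe_id[tab$retained], cf$retained)
  idx <- match(cf$params$probe_id, tab$probe_id)
  expect_equal(tab$delta[idx], cf$params$delta, tolerance = 1e-12)
  expect_equal(tab$beta0[idx], cf$params$beta0, tolerance = 1e-12)
})
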