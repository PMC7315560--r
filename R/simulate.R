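# Synthetic DNAm cohorts: trajectory-determined means with beta-distributed,
# age-heteroscedastic noise. Used both for testing and for the parameter
# identifiability experiment (simulate -> fit -> consensus).

#' Age-interval variance schedule for simulated cohorts
#'
#' Age bins with per-bin sample counts and DNAm noise variances. The default
#' bins and counts reproduce a Hannum-like whole-blood cohort of 656 samples:
#' age < 40 (n = 35), 40-50 (74), 50-60 (138), 60-70 (167), 70-80 (142),
#' 80+ (100). Per-bin variances increase with age to emulate the
#' age-associated growth of DNAm variance seen in real cohorts; the default
#' schedule (1e-4 to 1e-3) is a declared stand-in chosen to stay feasible
#' near the ground-state methylation level, and is fully overridable.
#'
#' @param lower,upper Bin edges in years; bins are `[lower, upper)` and must
#'   be contiguous and ordered.
#' @param n Per-bin sample counts.
#' @param variance Per-bin DNAm variance (beta-value scale), each in
#'   `(0, 0.25)`.
#' @return A `data.frame` with columns `lower`, `upper`, `n`, `variance`,
#'   of class `age_variance_table`.
#' @examples
#' age_variance_table()
#' @export
age_variance_table <- function(lower = c(19, 40, 50, 60, 70, 80),
                               upper = c(40, 50, 60, 70, 80, 101),
                               n = c(35, 74, 138, 167, 142, 100),
                               variance = c(1e-4, 2e-4, 3e-4, 5e-4, 7e-4, 1e-3)) {
  stopifnot(length(lower) == length(upper),
            length(n) == length(lower),
            length(variance) == length(lower))
  if (any(upper <= lower)) stop("each bin needs `upper` > `lower`")
  if (length(lower) > 1 && any(lower[-1] != upper[-length(upper)])) {
    stop("age bins must be contiguous and ordered")
  }
  if (any(n < 1)) stop("each bin needs at least one sample")
  if (any(variance <= 0 | variance >= 0.25)) {
    stop("`variance` must lie in (0, 0.25)")
  }
  structure(
    data.frame(lower = lower, upper = upper, n = as.integer(n),
               variance = variance),
    class = c("age_variance_table", "data.frame")
  )
}

#' Specification of a synthetic DNAm cohort
#'
#' Describes one simulated cohort completely: number of CpG sites and
#' samples, the shared true intrinsic division rate, the ground-state
#' methylation level, the pool of true de novo probabilities, the age range
#' and age/variance schedule, and a mandatory RNG seed. The defaults are the
#' identifiability study design: 163 gain-direction loci, 656 individuals
#' aged 19-101 with the stated bin counts, `IR = 35`, all `beta0 = 0.05`,
#' and true deltas cycled through the seven-value pool
#' `(1e-3, 7.5e-4, 5e-4, 2.5e-4, 1e-4, 5e-5, 1e-5)`.
#'
#' @param n_sites Number of CpG loci.
#' @param n_samples Cohort size; must equal the variance-table bin total.
#' @param true_ir Shared intrinsic stem-cell division rate
#'   (divisions/stem cell/year).
#' @param beta0 Shared ground-state methylation fraction.
#' @param delta_pool True per-site de novo probabilities to assign.
#' @param age_range Closed interval of admissible ages in years.
#' @param variance_table An [age_variance_table()].
#' @param seed Integer RNG seed (mandatory: cohorts are reproducible).
#' @param direction `"gain"` simulates methylation accrual (epiTOC2-like
#'   loci); `"loss"` mirrors the mean around 1/2 plus ground state, i.e. the
#'   mean is `1 - trajectory_approx(...)`, emulating solo-WCGW decay. The
#'   loss mode is an extension for testing hypomethylation scores, not part
#'   of the identifiability design.
#' @param delta_assignment `"cycle"` assigns deltas round-robin (stable truth
#'   tables); `"sample"` draws them with the seed.
#' @return An object of class `simulation_spec`.
#' @examples
#' simulation_spec(seed = 1)
#' simulation_spec(n_sites = 20, n_samples = 656, seed = 7, direction = "loss")
#' @export
simulation_spec <- function(n_sites = 163,
                            n_samples = 656,
                            true_ir = 35,
                            beta0 = 0.05,
                            delta_pool = c(0.001, 0.00075, 0.0005, 0.00025,
                                           0.0001, 5e-5, 1e-5),
                            age_range = c(19, 101),
                            variance_table = age_variance_table(),
                            seed = NULL,
                            direction = c("gain", "loss"),
                            delta_assignment = c("cycle", "sample")) {
  direction <- match.arg(direction)
  delta_assignment <- match.arg(delta_assignment)
  if (is.null(seed)) stop("`seed` is mandatory: simulated cohorts must be reproducible")
  stopifnot(n_sites >= 1, n_samples >= 1, true_ir > 0,
            beta0 >= 0, beta0 < 1,
            all(delta_pool >= 0), all(delta_pool <= 1),
            length(age_range) == 2, age_range[1] > 0,
            age_range[2] > age_range[1],
            inherits(variance_table, "age_variance_table"))
  if (sum(variance_table$n) != n_samples) {
    stop(sprintf("variance-table bin counts sum to %d but `n_samples` is %d",
                 sum(variance_table$n), n_samples))
  }
  structure(
    list(n_sites = as.integer(n_sites), n_samples = as.integer(n_samples),
         true_ir = true_ir, beta0 = beta0, delta_pool = delta_pool,
         age_range = age_range, variance_table = variance_table,
         seed = as.integer(seed), direction = direction,
         delta_assignment = delta_assignment),
    class = "simulation_spec"
  )
}

#' Convert a (mean, variance) pair to beta-distribution shapes
#'
#' Method-of-moments inversion: `a = (mu * (1 - mu) / sigma2 - 1) * mu` and
#' `b = a / mu - a`, so that `Beta(a, b)` has exactly the requested mean and
#' variance. An infeasible pair (`variance >= mean * (1 - mean)`) is handled
#' by shrinking the variance to 99% of the feasible maximum, with a warning.
#'
#' @param mean Target mean, strictly inside `(0, 1)`. Vectorized.
#' @param variance Target variance, positive. Vectorized (recycled).
#' @return A list with numeric vectors `shape1` and `shape2`.
#' @examples
#' beta_shapes_from_moments(0.5, 0.05)  # Beta(2, 2)
#' @export
beta_shapes_from_moments <- function(mean, variance) {
  if (any(mean <= 0 | mean >= 1)) stop("`mean` must lie strictly in (0, 1)")
  if (any(variance <= 0)) stop("`variance` must be positive")
  vmax <- mean * (1 - mean)
  bad <- variance >= vmax
  if (any(bad)) {
    warning(sprintf(
      "%d infeasible (mean, variance) pair(s): variance shrunk below mean*(1-mean)",
      sum(bad)))
    variance <- ifelse(bad, 0.99 * vmax, variance)
  }
  a <- (vmax / variance - 1) * mean
  list(shape1 = a, shape2 = a / mean - a)
}

# Ages honoring the per-bin counts; assumes the caller controls the RNG.
.draw_ages <- function(spec) {
  vt <- spec$variance_table
  ages <- unlist(lapply(seq_len(nrow(vt)), function(i) {
    stats::runif(vt$n[i], min = vt$lower[i], max = vt$upper[i])
  }))
  pmin(pmax(ages, spec$age_range[1]), spec$age_range[2])
}

#' Draw cohort ages from a simulation spec
#'
#' Samples exactly `n_samples` ages, uniform within each age bin of the
#' spec's variance table with the bin's sample count, clipped to the spec's
#' age range. Deterministic given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return Numeric vector of ages in years, length `spec$n_samples`, ordered
#'   by bin. These are the same ages [simulate_cohort()] uses for the same
#'   spec.
#' @examples
#' ages <- sample_ages(simulation_spec(seed = 1))
#' table(cut(ages, c(19, 40, 50, 60, 70, 80, 101), include.lowest = TRUE))
#' @export
sample_ages <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, .draw_ages(spec))
}

#' Simulate a DNAm cohort with beta-distributed heteroscedastic noise
#'
#' Generates a sites-by-samples beta-value matrix. Each site is assigned a
#' true de novo probability from the spec's pool; each (site, sample) value
#' is drawn from a beta distribution whose mean is the model trajectory
#' `trajectory_approx(delta_i, beta0, age_s * true_ir)` (or one minus it in
#' loss direction) and whose variance is the sample's age-bin variance.
#' Means are clamped to `[1e-4, 1 - 1e-4]` before shape conversion to avoid
#' degenerate shapes, and draws are clamped into the open unit interval.
#'
#' @param spec A [simulation_spec()].
#' @return An object of class `simulated_cohort`: a list with `betas`
#'   (matrix, probes x samples), `ages` (named numeric), and `truth`
#'   (`data.frame` with `probe_id`, `true_delta`, `true_beta0`, `true_ir`),
#'   plus the generating `spec`.
#' @examples
#' sim <- simulate_cohort(simulation_spec(n_sites = 5, seed = 1))
#' dim(sim$betas)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  vt <- spec$variance_table
  withr::with_seed(spec$seed, {
    ages <- .draw_ages(spec)
    deltas <- switch(spec$delta_assignment,
      cycle  = rep_len(spec$delta_pool, spec$n_sites),
      sample = sample(spec$delta_pool, spec$n_sites, replace = TRUE)
    )
    bin <- findInterval(ages, vt$lower)
    sigma2 <- vt$variance[bin]
    betas <- matrix(NA_real_, nrow = spec$n_sites, ncol = spec$n_samples)
    for (i in seq_len(spec$n_sites)) {
      mu <- trajectory_approx(deltas[i], spec$beta0, ages * spec$true_ir)
      if (spec$direction == "loss") mu <- 1 - mu
      mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
      sh <- beta_shapes_from_moments(mu, sigma2)
      betas[i, ] <- stats::rbeta(spec$n_samples, sh$shape1, sh$shape2)
    }
    betas <- pmin(pmax(betas, 1e-6), 1 - 1e-6)
    probe_ids <- sprintf("site_%04d", seq_len(spec$n_sites))
    sample_ids <- sprintf("sample_%04d", seq_len(spec$n_samples))
    dimnames(betas) <- list(probe_ids, sample_ids)
    names(ages) <- sample_ids
    structure(
      list(betas = betas, ages = ages,
           truth = data.frame(probe_id = probe_ids, true_delta = deltas,
                              true_beta0 = spec$beta0, true_ir = spec$true_ir),
           spec = spec),
      class = "simulated_cohort"
    )
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated DNAm cohort: %d sites x %d samples (%s direction)\n",
    nrow(x$betas), ncol(x$betas), x$spec$direction))
  cat(sprintf("  true IR %.3g, beta0 %.3g, ages %.1f-%.1f, seed %d\n",
              x$spec$true_ir, x$spec$beta0, min(x$ages), max(x$ages),
              x$spec$seed))
  invisible(x)
}
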