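# Forward model of replication-coupled DNA methylation gain at a single CpG
# dyad: exact dyad-level recursion, its closed-form strand-frequency solution,
# and the approximations used downstream for fitting and scoring.

#' Per-CpG methylation transmission kinetics
#'
#' Bundles the per-division probabilities governing methylation transmission
#' at one CpG dyad: maintenance probability `mu` (a methylated parent strand
#' keeps its methylation with probability `mu` after replication), and de novo
#' methylation probabilities on the parent (`delta_p`) and daughter
#' (`delta_d`) strands. The total de novo probability `delta = delta_p +
#' delta_d` is what the approximate trajectories depend on; when only `delta`
#' is supplied it is split symmetrically (`delta_p = delta_d = delta / 2`),
#' which leaves every derived quantity unchanged.
#'
#' @param delta Total de novo methylation probability per division. Optional
#'   if `delta_p` and `delta_d` are both given.
#' @param delta_p,delta_d Strand-level de novo probabilities. Optional if
#'   `delta` is given.
#' @param mu Maintenance probability per division, in `[0, 1]`. Default 1,
#'   the regime assumed for fetal-unmethylated clock CpGs.
#' @param beta0 Ground-state (fetal, division time 0) methylation fraction.
#'
#' @return An object of class `site_kinetics`: a list with elements
#'   `delta_p`, `delta_d`, `delta`, `mu`, `beta0`.
#' @examples
#' site_kinetics(delta = 5e-5, beta0 = 0.05)
#' site_kinetics(delta_p = 0.1, delta_d = 0.1, mu = 0.95)
#' @export
site_kinetics <- function(delta = NULL, delta_p = NULL, delta_d = NULL,
                          mu = 1, beta0 = 0) {
  if (is.null(delta_p) != is.null(delta_d)) {
    stop("supply both `delta_p` and `delta_d`, or `delta` alone")
  }
  if (is.null(delta_p)) {
    if (is.null(delta)) stop("supply `delta` or the pair (`delta_p`, `delta_d`)")
    delta_p <- delta_d <- delta / 2
  } else if (!is.null(delta) &&
             abs(delta - (delta_p + delta_d)) > 1e-12) {
    stop("`delta` must equal `delta_p + delta_d`")
  }
  delta <- delta_p + delta_d
  .check_prob(delta_p, "delta_p")
  .check_prob(delta_d, "delta_d")
  .check_prob(mu, "mu")
  .check_prob(beta0, "beta0")
  if (delta > 1) stop("total de novo probability `delta_p + delta_d` exceeds 1")
  structure(
    list(delta_p = delta_p, delta_d = delta_d, delta = delta,
         mu = mu, beta0 = beta0),
    class = "site_kinetics"
  )
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

#' Dyad state of a CpG locus
#'
#' Frequencies of fully methylated (`M`), hemimethylated (`H`) and
#' unmethylated (`U`) CpG dyads in a cell population. The derived strand
#' (gamete) frequency is `m = M + H / 2`, which is what a bisulfite beta
#' value measures.
#'
#' @param M,H,U Dyad-state frequencies; must be in `[0, 1]` and sum to 1
#'   within `1e-12`.
#' @return An object of class `dyad_state` with elements `M`, `H`, `U`.
#' @examples
#' dyad_state(M = 0, H = 0, U = 1)          # fully unmethylated locus
#' strand_frequency(dyad_state(0.2, 0.6, 0.2))
#' @export
dyad_state <- function(M, H, U) {
  for (x in list(M = M, H = H, U = U)) .check_prob(x, "dyad frequency")
  if (abs(M + H + U - 1) > 1e-12) {
    stop("dyad frequencies M + H + U must sum to 1 (within 1e-12)")
  }
  structure(list(M = M, H = H, U = U), class = "dyad_state")
}

#' @rdname dyad_state
#' @param state A `dyad_state`.
#' @export
strand_frequency <- function(state) {
  stopifnot(inherits(state, "dyad_state"))
  state$M + state$H / 2
}

#' Advance a CpG dyad by one cell division
#'
#' One generation of the dyad-level transmission model. With strand
#' frequency `m = M + H/2` and `u = 1 - m`, the next-generation frequencies
#' are `M' = mu * m + delta_p * delta_d * u` and
#' `H' = (1 - mu) * m + delta_d * (1 - delta_p) * u + delta_p * (1 - delta_d) * u`,
#' with `U'` the remainder.
#'
#' @param state A [dyad_state()].
#' @param kin A [site_kinetics()].
#' @return The next-generation `dyad_state`.
#' @examples
#' kin <- site_kinetics(delta_p = 0.1, delta_d = 0.1, mu = 0.95)
#' dyad_step(dyad_state(0, 0, 1), kin)
#' @export
dyad_step <- function(state, kin) {
  stopifnot(inherits(state, "dyad_state"), inherits(kin, "site_kinetics"))
  m <- strand_frequency(state)
  u <- 1 - m
  M1 <- kin$mu * m + kin$delta_p * kin$delta_d * u
  H1 <- (1 - kin$mu) * m +
    kin$delta_d * (1 - kin$delta_p) * u +
    kin$delta_p * (1 - kin$delta_d) * u
  dyad_state(M1, H1, 1 - M1 - H1)
}

#' Linear recursion coefficients of the strand frequency
#'
#' The strand frequency obeys the affine recursion `m_t = a + b * m_{t-1}`
#' with `a = delta / 2` and `b = (1 + mu - delta) / 2`.
#'
#' @param kin A [site_kinetics()].
#' @return Named numeric vector `c(a = , b = )`.
#' @examples
#' strand_coefficients(site_kinetics(delta = 5e-5))  # a = 2.5e-5, b = 0.999975
#' @export
strand_coefficients <- function(kin) {
  stopifnot(inherits(kin, "site_kinetics"))
  c(a = kin$delta / 2, b = (1 + kin$mu - kin$delta) / 2)
}

#' Closed-form methylation trajectory (exact solution)
#'
#' Solves the strand recursion exactly:
#' `m_t = a / (1 - b) + b^t * (m0 - a / (1 - b))` for `b < 1`, and the
#' constant solution `m_t = m0` in the degenerate case `b = 1` (no de novo
#' methylation, perfect maintenance). `t` may be real-valued: in fitting,
#' division time is the continuous product `age * IR`.
#'
#' @param kin A [site_kinetics()].
#' @param m0 Strand methylation frequency at division time 0.
#' @param t Vector of non-negative division counts (real-valued allowed).
#' @return Methylation fractions `m_t`, same length as `t`, in `[0, 1]`.
#' @examples
#' kin <- site_kinetics(delta = 5e-5, mu = 1)
#' trajectory_exact(kin, m0 = 0, t = c(0, 1000))  # 0 and ~0.0247
#' @export
trajectory_exact <- function(kin, m0, t) {
  stopifnot(inherits(kin, "site_kinetics"))
  .check_prob(m0, "m0")
  if (any(t < 0)) stop("`t` must be non-negative")
  ab <- strand_coefficients(kin)
  a <- ab[["a"]]
  b <- ab[["b"]]
  if (b >= 1) return(rep(m0, length(t)))
  mstar <- a / (1 - b)
  bt <- ifelse(t == 0, 1, exp(t * log(b)))
  pmin(1, pmax(0, mstar + bt * (m0 - mstar)))
}

#' Methylation trajectory under perfect maintenance (mu = 1)
#'
#' The working approximation for fetal-unmethylated clock CpGs: with
#' `mu = 1`, `b = 1 - delta / 2` and the trajectory reduces to
#' `beta_t = 1 - (1 - delta/2)^t + beta0 * (1 - delta/2)^t`, which tends to 1
#' as `t` grows. The power is evaluated as `exp(t * log1p(-delta/2))` to keep
#' precision at small `delta` and large `t`. With `delta = 0` the trajectory
#' is constant at `beta0`; the result then carries attribute
#' `degenerate = TRUE`.
#'
#' @param delta Total de novo methylation probability per division, `[0, 1]`.
#' @param beta0 Ground-state methylation fraction.
#' @param t Vector of non-negative division counts (real-valued allowed).
#' @return Methylation fractions, same length as `t`.
#' @examples
#' trajectory_approx(5e-5, 0, 1000)            # ~0.0247
#' trajectory_approx(5e-5, 0.05, 50 * 35)      # an age-50 blood-like value
#' @export
trajectory_approx <- function(delta, beta0, t) {
  .check_prob(delta, "delta")
  .check_prob(beta0, "beta0")
  if (any(t < 0)) stop("`t` must be non-negative")
  if (delta == 0) {
    return(structure(rep(beta0, length(t)), degenerate = TRUE))
  }
  p <- exp(t * log1p(-delta / 2))
  1 - p + beta0 * p
}

#' First-order (linear) methylation accrual
#'
#' Linearization of [trajectory_approx()] around `t = 0`:
#' `beta = beta0 + (delta / 2) * (1 - beta0) * tnsc`, capped at 1. This is
#' the form the TNSC estimator inverts, valid while `delta * tnsc / 2` is
#' small.
#'
#' @param delta Total de novo methylation probability per division.
#' @param beta0 Ground-state methylation fraction.
#' @param tnsc Vector of non-negative cumulative division counts.
#' @return Methylation fractions, same length as `tnsc`.
#' @examples
#' first_order_beta(5e-5, 0.05, 1400)  # 0.08325
#' @export
first_order_beta <- function(delta, beta0, tnsc) {
  .check_prob(delta, "delta")
  .check_prob(beta0, "beta0")
  if (any(tnsc < 0)) stop("`tnsc` must be non-negative")
  pmin(1, beta0 + (delta / 2) * (1 - beta0) * tnsc)
}
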