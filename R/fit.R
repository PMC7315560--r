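# Per-CpG parameter estimation: grid-multi-start bounded non-linear least
# squares on the mu = 1 trajectory, rate-product filtering, (delta, IR) mode
# consensus, and the fixed-IR refit that yields the final clock parameters.

#' Grid of NLS starting values
#'
#' The three-dimensional grid of starting values used for the multi-start
#' fit: seven de novo probabilities (1e-5 to 1e-3), six ground-state levels
#' (0 to 0.05) and twenty-four division rates (1-5 then 10 to 100 in steps
#' of 5). `reduce = TRUE` keeps every other IR start, roughly halving
#' runtime on a full cohort with little effect on the consensus.
#'
#' @param delta_starts,beta0_starts,ir_starts Numeric start sets; stored
#'   sorted ascending.
#' @param reduce Subsample the IR starts (every other value)?
#' @return An object of class `fit_grid` with elements `delta_starts`,
#'   `beta0_starts`, `ir_starts`.
#' @examples
#' fit_grid()
#' fit_grid(reduce = TRUE)
#' @export
fit_grid <- function(delta_starts = c(0.001, 0.00075, 0.0005, 0.00025,
                                      0.0001, 5e-5, 1e-5),
                     beta0_starts = seq(0, 0.05, by = 0.01),
                     ir_starts = c(1, 2, 3, 4, 5, seq(10, 100, by = 5)),
                     reduce = FALSE) {
  stopifnot(length(delta_starts) > 0, length(beta0_starts) > 0,
            length(ir_starts) > 0,
            all(delta_starts > 0), all(beta0_starts >= 0), all(ir_starts > 0))
  ir_starts <- sort(ir_starts)
  if (reduce) ir_starts <- ir_starts[seq(1, length(ir_starts), by = 2)]
  structure(
    list(delta_starts = sort(delta_starts),
         beta0_starts = sort(beta0_starts),
         ir_starts = ir_starts),
    class = "fit_grid"
  )
}

#' @export
print.fit_grid <- function(x, ...) {
  cat(sprintf("NLS starting grid: %d delta x %d beta0 x %d IR = %d starts\n",
              length(x$delta_starts), length(x$beta0_starts),
              length(x$ir_starts),
              length(x$delta_starts) * length(x$beta0_starts) *
                length(x$ir_starts)))
  invisible(x)
}

# Parameter bounds for the bounded least-squares fits. The source model
# states no bounds; these encompass every grid start and every literature
# division rate.
.fit_bounds <- list(delta = c(1e-7, 0.01), beta0 = c(0, 0.1), ir = c(0.01, 150))

# Fixed-IR model (2 parameters: delta, beta0), t = ages * ir fixed.
.traj_resid2 <- function(par, betas, t) {
  p <- exp(t * log1p(-par[1] / 2))
  betas - (1 - (1 - par[2]) * p)
}

.traj_jac2 <- function(par, betas, t) {
  p <- exp(t * log1p(-par[1] / 2))
  cbind(-(1 - par[2]) * t / (2 * (1 - par[1] / 2)) * p, -p)
}

.lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500)
}

#' Fit the accrual model at a single CpG
#'
#' Minimizes the residual sum of squares of the mu = 1 trajectory,
#' `sum_s (beta_s - trajectory_approx(delta, beta0, age_s * ir))^2`, over
#' the multi-start grid. The de novo probability and the division rate
#' enter the trajectory only through the compound rate
#' `c = -ir * log(1 - delta/2)`, so the three-parameter Jacobian is exactly
#' rank-deficient (the `delta` and `ir` columns are collinear with
#' sample-independent ratio) and a continuous joint fit of all three
#' parameters is not identifiable: gradient refinement would drift
#' arbitrarily along the flat `(delta, ir)` ridge. `fit_site()` therefore
#' minimizes exactly over the `(delta, ir)` starting grid, profiling the
#' ground state `beta0` -- which is linear in the model -- in closed form
#' (bounded linear least squares, the variable-projection step; every
#' `beta0` start converges to this same profiled optimum). The reported
#' `delta_hat` and `ir_hat` are grid values; their product estimates the
#' identifiable compound rate. The `(delta, ir)` decomposition is resolved
#' cohort-wise by [consensus_rate()], after which [refit_fixed_rate()]
#' refines `(delta, beta0)` continuously at the consensus IR -- a fit that
#' is well-posed. Missing beta values are dropped pairwise; non-positive or
#' missing ages are excluded with a warning. Fitting is deterministic.
#'
#' @param betas Beta values for one CpG across samples, in `[0, 1]`.
#' @param ages Matching chronological ages in years.
#' @param grid A [fit_grid()].
#' @param probe_id Optional identifier carried into the result.
#' @param min_pairs Minimum number of complete (beta, age) pairs (default 30).
#' @return An object of class `site_fit`: list with `probe_id`, `delta_hat`,
#'   `beta0_hat`, `ir_hat`, `rss`, `converged`, `degenerate`, `n_used`.
#' @examples
#' ages <- seq(20, 90, length.out = 60)
#' betas <- trajectory_approx(5e-5, 0.05, ages * 35)
#' fit_site(betas, ages)
#' @export
fit_site <- function(betas, ages, grid = fit_grid(), probe_id = NA_character_,
                     min_pairs = 30L) {
  stopifnot(length(betas) == length(ages))
  bad_age <- !is.na(betas) & (is.na(ages) | ages <= 0)
  if (any(bad_age)) {
    warning(sprintf("%d sample(s) with missing or non-positive age excluded",
                    sum(bad_age)))
  }
  keep <- !is.na(betas) & !is.na(ages) & ages > 0
  betas <- betas[keep]
  ages <- ages[keep]
  if (any(betas < 0 | betas > 1)) stop("`betas` must lie in [0, 1]")
  if (length(betas) < min_pairs) {
    stop(sprintf("only %d complete (beta, age) pairs; need at least %d",
                 length(betas), min_pairs))
  }
  out <- list(probe_id = probe_id, delta_hat = NA_real_,
              beta0_hat = NA_real_, ir_hat = NA_real_, rss = NA_real_,
              converged = FALSE, degenerate = FALSE,
              n_used = length(betas))
  if (stats::sd(betas) == 0) {
    out$degenerate <- TRUE
    out$delta_hat <- .fit_bounds$delta[1]
    out$beta0_hat <- min(max(betas[1], .fit_bounds$beta0[1]),
                         .fit_bounds$beta0[2])
    out$ir_hat <- .fit_bounds$ir[1]
    out$rss <- sum((betas - betas[1])^2)
    return(structure(out, class = "site_fit"))
  }
  pairs <- expand.grid(d = grid$delta_starts, ir = grid$ir_starts,
                       KEEP.OUT.ATTRS = FALSE)
  best <- list(rss = Inf)
  for (k in seq_len(nrow(pairs))) {
    d <- pairs$d[k]
    ir <- pairs$ir[k]
    p <- exp(ages * ir * log1p(-d / 2))
    # model = 1 - (1 - beta0) * p is linear in beta0: profile it exactly
    y <- betas - (1 - p)
    b0 <- sum(p * y) / sum(p * p)
    b0 <- min(max(b0, .fit_bounds$beta0[1]), .fit_bounds$beta0[2])
    rss <- sum((y - b0 * p)^2)
    if (rss < best$rss) best <- list(d = d, b0 = b0, ir = ir, rss = rss)
  }
  out$delta_hat <- best$d
  out$beta0_hat <- best$b0
  out$ir_hat <- best$ir
  out$rss <- best$rss
  out$converged <- TRUE
  structure(out, class = "site_fit")
}

#' @export
print.site_fit <- function(x, ...) {
  cat(sprintf(
    "site_fit %s: delta %.3g, beta0 %.3g, IR %.3g (rss %.4g, %s, n %d)\n",
    x$probe_id, x$delta_hat, x$beta0_hat, x$ir_hat, x$rss,
    if (x$converged) "converged" else "not converged", x$n_used))
  invisible(x)
}

#' Fit every CpG of a beta matrix
#'
#' Applies [fit_site()] row-wise. Accepts either a [beta_matrix()] or a
#' plain matrix plus ages.
#'
#' @param x A `beta_matrix` or numeric matrix (probes x samples).
#' @param ages Sample ages; taken from the metadata when `x` is a
#'   `beta_matrix`.
#' @param grid A [fit_grid()].
#' @param verbose Emit a progress message every 25 sites?
#' @return `data.frame` with one row per probe: `probe_id`, `delta`,
#'   `beta0`, `ir_site`, `rss`, `converged`, `n_used`.
#' @export
fit_sites <- function(x, ages = NULL, grid = fit_grid(), verbose = FALSE) {
  if (inherits(x, "beta_matrix")) {
    ages <- x$samples$age
    x <- x$betas
  }
  stopifnot(is.matrix(x), !is.null(ages), length(ages) == ncol(x))
  probes <- rownames(x)
  if (is.null(probes)) probes <- sprintf("site_%04d", seq_len(nrow(x)))
  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    f <- fit_site(x[i, ], ages, grid = grid, probe_id = probes[i])
    rows[[i]] <- data.frame(probe_id = f$probe_id, delta = f$delta_hat,
                            beta0 = f$beta0_hat, ir_site = f$ir_hat,
                            rss = f$rss, converged = f$converged,
                            n_used = f$n_used)
    if (verbose && i %% 25 == 0) {
      message(sprintf("fitted %d / %d sites", i, nrow(x)))
    }
  }
  do.call(rbind, rows)
}

#' Retain CpGs whose accrual rate is assay-resolvable
#'
#' Keeps probes whose estimated rate product `delta * IR` is at least
#' `threshold` (default 0.001, i.e. a DNAm gain of at least 1% per decade,
#' the approximate resolution of the Illumina beadarray assay).
#' Non-converged fits never pass. Order-preserving and idempotent.
#'
#' @param fits `data.frame` from [fit_sites()].
#' @param threshold Minimum `delta * ir_site` product.
#' @return Character vector of retained probe ids.
#' @examples
#' fits <- data.frame(probe_id = c("a", "b"), delta = c(5e-5, 1e-5),
#'                    beta0 = 0, ir_site = 35, rss = 0, converged = TRUE)
#' filter_sites(fits)  # "a" only
#' @export
filter_sites <- function(fits, threshold = 0.001) {
  if (nrow(fits) == 0) return(character(0))
  keep <- fits$converged & !is.na(fits$delta) &
    fits$delta * fits$ir_site >= threshold
  fits$probe_id[keep]
}

#' Consensus division rate by (delta, IR) mode
#'
#' The intrinsic rate is shared across CpGs, so per-site IR estimates are
#' reconciled by a vote: each retained site's `(delta, ir)` estimate is
#' snapped to the nearest starting-grid values (delta by nearest neighbour
#' in log10 space, IR linearly), cell occupancies are counted, and the most
#' occupied `(delta, IR)` cell wins. Ties are broken by the lowest summed
#' RSS across the tied cells.
#'
#' @param fits `data.frame` from [fit_sites()], restricted to retained
#'   probes (see [filter_sites()]).
#' @param grid The [fit_grid()] whose values define the snap targets.
#' @return List with `modal_delta`, `modal_ir`, and `cells` (the occupancy
#'   table as a `data.frame` with `delta`, `ir`, `count`, `rss`).
#' @export
consensus_rate <- function(fits, grid = fit_grid()) {
  fits <- fits[fits$converged & !is.na(fits$delta), , drop = FALSE]
  if (nrow(fits) == 0) stop("no converged fits to form a consensus from")
  snap <- function(x, targets, transform = identity) {
    tx <- transform(targets)
    targets[vapply(transform(x), function(v) which.min(abs(v - tx)), 1L)]
  }
  d_snap <- snap(fits$delta, grid$delta_starts, log10)
  ir_snap <- snap(fits$ir_site, grid$ir_starts)
  cells <- stats::aggregate(
    cbind(count = rep(1L, nrow(fits)), rss = fits$rss),
    by = list(delta = d_snap, ir = ir_snap), FUN = sum)
  cells <- cells[order(-cells$count, cells$rss), ]
  list(modal_delta = cells$delta[1], modal_ir = cells$ir[1],
       cells = cells)
}

#' Refit per-CpG parameters at a fixed division rate
#'
#' With the cohort IR fixed, division time per sample is `age * ir` and the
#' model is refit per probe over `(delta, beta0)` only, from the
#' delta-by-beta0 face of the starting grid. This yields the final
#' parameter table the mitotic clocks use.
#'
#' @param x A `beta_matrix` or numeric matrix (probes x samples), usually
#'   restricted to the retained probes.
#' @param ages Sample ages (taken from metadata for a `beta_matrix`).
#' @param ir The fixed intrinsic rate (e.g. `modal_ir` from
#'   [consensus_rate()]).
#' @param grid A [fit_grid()] supplying the delta and beta0 starts.
#' @return `data.frame` with `probe_id`, `delta`, `beta0`, `rss`,
#'   `converged`.
#' @export
refit_fixed_rate <- function(x, ages = NULL, ir, grid = fit_grid()) {
  if (inherits(x, "beta_matrix")) {
    ages <- x$samples$age
    x <- x$betas
  }
  stopifnot(is.matrix(x), !is.null(ages), length(ages) == ncol(x), ir > 0)
  probes <- rownames(x)
  if (is.null(probes)) probes <- sprintf("site_%04d", seq_len(nrow(x)))
  starts <- expand.grid(d = grid$delta_starts, b0 = grid$beta0_starts,
                        KEEP.OUT.ATTRS = FALSE)
  lower <- c(.fit_bounds$delta[1], .fit_bounds$beta0[1])
  upper <- c(.fit_bounds$delta[2], .fit_bounds$beta0[2])
  ctrl <- .lm_control()
  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    keep <- !is.na(x[i, ]) & !is.na(ages) & ages > 0
    b <- x[i, keep]
    t <- ages[keep] * ir
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = as.numeric(starts[k, ]),
                           lower = lower, upper = upper,
                           fn = .traj_resid2, jac = .traj_jac2,
                           betas = b, t = t, control = ctrl),
        error = function(e) NULL
      )
      if (is.null(fit) || !(fit$info %in% 1:3)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    rows[[i]] <- data.frame(
      probe_id = probes[i],
      delta = if (is.null(best)) NA_real_ else best$par[1],
      beta0 = if (is.null(best)) NA_real_ else best$par[2],
      rss = if (is.null(best)) NA_real_ else best$deviance,
      converged = !is.null(best))
  }
  do.call(rbind, rows)
}

#' Full cohort fit: per-site NLS, filter, consensus, fixed-IR refit
#'
#' Runs the complete estimation pipeline on a cohort: [fit_sites()] on every
#' probe, [filter_sites()] at the rate-product threshold, [consensus_rate()]
#' to pick the modal `(delta, IR)` cell, then [refit_fixed_rate()] on the
#' retained probes at the modal IR.
#'
#' @param x A `beta_matrix` or numeric matrix (probes x samples).
#' @param ages Sample ages (taken from metadata for a `beta_matrix`).
#' @param grid A [fit_grid()].
#' @param threshold Rate-product retention threshold (default 0.001).
#' @param verbose Progress messages?
#' @return An object of class `cohort_fit`: list with `site_fits`
#'   (`data.frame`), `retained` (probe ids), `modal_delta`, `modal_ir`,
#'   `params` (final `probe_id`/`delta`/`beta0` table), `cells`.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(simulation_spec(n_sites = 14, seed = 3))
#' cf <- fit_cohort(sim$betas, sim$ages, grid = fit_grid(reduce = TRUE))
#' cf$modal_ir
#' }
#' @export
fit_cohort <- function(x, ages = NULL, grid = fit_grid(), threshold = 0.001,
                       verbose = FALSE) {
  if (inherits(x, "beta_matrix")) {
    ages <- x$samples$age
    x <- x$betas
  }
  fits <- fit_sites(x, ages, grid = grid, verbose = verbose)
  retained <- filter_sites(fits, threshold = threshold)
  if (length(retained) == 0) {
    stop("no probes passed the rate-product filter; no consensus possible")
  }
  cons <- consensus_rate(fits[fits$probe_id %in% retained, , drop = FALSE],
                         grid = grid)
  params <- refit_fixed_rate(x[retained, , drop = FALSE], ages,
                             ir = cons$modal_ir, grid = grid)
  structure(
    list(site_fits = fits, retained = retained,
         modal_delta = cons$modal_delta, modal_ir = cons$modal_ir,
         params = params, cells = cons$cells),
    class = "cohort_fit"
  )
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("Cohort fit: %d sites, %d retained (delta*IR >= threshold)\n",
              nrow(x$site_fits), length(x$retained)))
  cat(sprintf("  modal delta %.3g, modal IR %.4g divisions/stem cell/year\n",
              x$modal_delta, x$modal_ir))
  invisible(x)
}

#' Write / read the per-probe parameter table
#'
#' Serializes a [fit_cohort()] result as a delimited text file with columns
#' `probe_id`, `delta`, `beta0`, `ir_site`, `rss`, `converged`, `retained`.
#' For retained probes `delta` and `beta0` are the final fixed-IR refit
#' values; for dropped probes they are the first-pass estimates. The modal
#' IR is stored in a `# modal_ir=` header comment and restored on read.
#'
#' @param fit A `cohort_fit`.
#' @param path Output file.
#' @param sep Field delimiter.
#' @return `write_parameter_table()` returns `path` invisibly;
#'   `read_parameter_table()` returns a `data.frame` with attribute
#'   `modal_ir`.
#' @export
write_parameter_table <- function(fit, path, sep = "\t") {
  stopifnot(inherits(fit, "cohort_fit"))
  tab <- fit$site_fits[, c("probe_id", "delta", "beta0", "ir_site", "rss",
                           "converged")]
  tab$retained <- tab$probe_id %in% fit$retained
  idx <- match(fit$params$probe_id, tab$probe_id)
  tab$delta[idx] <- fit$params$delta
  tab$beta0[idx] <- fit$params$beta0
  tab$rss[idx] <- fit$params$rss
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modal_ir=%.15g modal_delta=%.15g",
                     fit$modal_ir, fit$modal_delta), con)
  utils::write.table(tab, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path, sep = "\t") {
  header <- readLines(path, n = 1)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE)
  modal_ir <- NA_real_
  if (grepl("^# *modal_ir=", header)) {
    modal_ir <- as.numeric(sub("^# *modal_ir=([0-9.eE+-]+).*$", "\\1", header))
  }
  attr(tab, "modal_ir") <- modal_ir
  tab
}
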