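# Mitotic-age scores: epiTOC2 TNSC and division rates, the earlier epiTOC
# pcgtAge average, and the HypoClock solo-WCGW score with age adjustment and
# dynamic-range rescaling; plus literature turnover-rate converters.

#' Definition of a mitotic clock
#'
#' A clock is a probe list plus, for the model-based epiTOC2 clock, per-probe
#' kinetic parameters. Averaging clocks (epiTOC's pcgtAge, HypoClock) carry
#' only probes and a direction: `"gain"` clocks gain methylation with
#' divisions, `"loss"` clocks (solo-WCGW) lose it.
#'
#' @param name Clock name, e.g. `"epiTOC2"`, `"epiTOC"`, `"HypoClock"`.
#' @param probe_ids Unique, non-empty probe identifiers.
#' @param params Optional `data.frame` with columns `probe_id`, `delta`,
#'   `beta0` covering every probe (required for model-based clocks).
#' @param direction `"gain"` or `"loss"`.
#' @return An object of class `clock_definition`.
#' @examples
#' clock_definition("HypoClock", c("cg01", "cg02"), direction = "loss")
#' @export
clock_definition <- function(name, probe_ids, params = NULL,
                             direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) == 0) stop("`probe_ids` must be non-empty")
  if (anyDuplicated(probe_ids)) stop("`probe_ids` must be unique")
  if (!is.null(params)) {
    if (!all(c("probe_id", "delta", "beta0") %in% names(params))) {
      stop("`params` needs columns probe_id, delta, beta0")
    }
    if (!all(probe_ids %in% params$probe_id)) {
      stop("`params` must cover every clock probe")
    }
    params <- params[match(probe_ids, params$probe_id),
                     c("probe_id", "delta", "beta0")]
    if (any(!is.finite(params$delta)) || any(params$delta <= 0)) {
      stop("`params$delta` must be finite and positive")
    }
  }
  structure(list(name = name, probe_ids = probe_ids, params = params,
                 direction = direction),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("Mitotic clock '%s': %d probes (%s direction, %s)\n",
              x$name, length(x$probe_ids), x$direction,
              if (is.null(x$params)) "averaging" else "model-based"))
  invisible(x)
}

# Per-sample coverage check over a clock's probes; errors below `floor`
# and names (a prefix of) the missing probes.
.check_coverage <- function(betas, probe_ids, floor = 0.8) {
  present <- probe_ids %in% rownames(betas)
  if (mean(present) < floor) {
    miss <- probe_ids[!present]
    stop(sprintf(
      "only %.0f%% of the %d clock probes are in the matrix (need >= %.0f%%); missing e.g. %s",
      100 * mean(present), length(probe_ids), 100 * floor,
      paste(utils::head(miss, 5), collapse = ", ")))
  }
  probe_ids[present]
}

.as_probe_matrix <- function(betas) {
  if (inherits(betas, "beta_matrix")) betas <- betas$betas
  if (is.null(dim(betas))) {
    betas <- matrix(betas, ncol = 1,
                    dimnames = list(names(betas), "sample_1"))
  }
  if (is.null(rownames(betas))) stop("beta values must carry probe ids")
  if (any(betas < 0 | betas > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  betas
}

#' Estimate the total number of stem-cell divisions (TNSC)
#'
#' Inverts the first-order accrual model per sample:
#' `TNSC = (2 / n) * sum_i (beta_i - beta0_i) / (delta_i * (1 - beta0_i))`
#' over the clock probes with non-missing values (`n` = probes used per
#' sample). At least 80% of the clock probes must be present and
#' non-missing. Negative per-probe contributions are not clipped; a sample
#' with overall negative TNSC triggers a warning but is reported as-is
#' (clipping would bias cohort medians).
#'
#' @param betas Named vector (one sample) or probes-x-samples matrix /
#'   `beta_matrix` with probe ids as row names.
#' @param params `data.frame` with `probe_id`, `delta`, `beta0`.
#' @return Named numeric vector of per-sample division counts.
#' @examples
#' params <- data.frame(probe_id = c("cg1", "cg2"),
#'                      delta = c(5e-5, 1e-4), beta0 = c(0.05, 0.02))
#' b <- sapply(1:2, function(i)
#'   first_order_beta(params$delta[i], params$beta0[i], 1400))
#' estimate_tnsc(stats::setNames(b, params$probe_id), params)  # 1400
#' @export
estimate_tnsc <- function(betas, params) {
  betas <- .as_probe_matrix(betas)
  used <- .check_coverage(betas, params$probe_id)
  params <- params[match(used, params$probe_id), ]
  sub <- betas[used, , drop = FALSE]
  contrib <- sweep(sub, 1, params$beta0, "-") /
    (params$delta * (1 - params$beta0))
  nonmiss <- colSums(!is.na(contrib))
  low <- nonmiss < 0.8 * length(params$probe_id)
  if (any(low)) {
    stop(sprintf("%d sample(s) have < 80%% non-missing clock probes",
                 sum(low)))
  }
  tnsc <- 2 * colMeans(contrib, na.rm = TRUE)
  if (any(tnsc < 0)) {
    warning(sprintf("%d sample(s) with negative TNSC (beta below beta0 at many sites); reported unclipped",
                    sum(tnsc < 0)))
  }
  tnsc
}

#' Lifetime stem-cell division rate
#'
#' `R = TNSC / age`: the average number of divisions per stem cell per year
#' over the sample's life. Ages must be supplied (no methylation-based age
#' surrogate is computed).
#'
#' @param tnsc Per-sample division counts.
#' @param age Matching chronological ages in years, all positive.
#' @return Divisions per stem cell per year, same length as `tnsc`.
#' @examples
#' lifetime_rate(350, 10)  # 35
#' @export
lifetime_rate <- function(tnsc, age) {
  stopifnot(length(tnsc) == length(age))
  if (any(is.na(age) | age <= 0)) {
    stop("all ages must be known and positive (supply chronological ages)")
  }
  tnsc / age
}

#' Intrinsic stem-cell division rate of a tissue
#'
#' Summarizes per-sample lifetime rates `TNSC_s / age_s` over a healthy
#' cohort of one tissue by the median (default; robust) or mean.
#'
#' @param tnscs Per-sample division counts.
#' @param ages Matching positive ages in years.
#' @param estimator `"median"` (default) or `"mean"`.
#' @param tissue Optional tissue label carried into the result.
#' @return An object of class `division_rate`: list with `tissue_label`,
#'   `ir`, `estimator`, `n_samples`.
#' @examples
#' intrinsic_rate(c(300, 350, 400), c(10, 10, 10))  # 35 divisions/year
#' @export
intrinsic_rate <- function(tnscs, ages, estimator = c("median", "mean"),
                           tissue = NA_character_) {
  estimator <- match.arg(estimator)
  if (length(tnscs) == 0) stop("no samples supplied")
  rates <- lifetime_rate(tnscs, ages)
  ir <- if (estimator == "median") stats::median(rates) else mean(rates)
  structure(list(tissue_label = tissue, ir = ir, estimator = estimator,
                 n_samples = length(rates)),
            class = "division_rate")
}

#' @export
print.division_rate <- function(x, ...) {
  cat(sprintf("IR(%s) = %.4g divisions/stem cell/year (%s of %d samples)\n",
              if (is.na(x$tissue_label)) "tissue" else x$tissue_label,
              x$ir, x$estimator, x$n_samples))
  invisible(x)
}

.mean_score <- function(betas, probe_ids, floor = 0.8) {
  betas <- .as_probe_matrix(betas)
  used <- .check_coverage(betas, probe_ids, floor)
  sub <- betas[used, , drop = FALSE]
  nonmiss <- colSums(!is.na(sub))
  if (any(nonmiss < floor * length(probe_ids))) {
    stop("some samples have < 80% non-missing clock probes")
  }
  colMeans(sub, na.rm = TRUE)
}

#' epiTOC pcgtAge score
#'
#' The earlier averaging mitotic clock: mean beta value over the
#' PRC2-marked, fetally unmethylated clock CpGs. With site-independent
#' `delta` and `beta0 = 0` it is proportional to the TNSC estimate, so the
#' averaging clock is a special case of the model-based one.
#'
#' @param betas Named vector, matrix, or `beta_matrix` (probe ids as rows).
#' @param probe_ids The epiTOC probe set.
#' @return Named numeric vector of per-sample mean beta values.
#' @export
pcgt_age_score <- function(betas, probe_ids) {
  .mean_score(betas, probe_ids)
}

#' HypoClock score over solo-WCGW probes
#'
#' Mean beta value over constitutively methylated solo-WCGW CpGs; these lose
#' methylation with accumulating divisions, so lower scores indicate greater
#' mitotic age.
#'
#' @inheritParams pcgt_age_score
#' @param probe_ids The solo-WCGW probe set.
#' @return Named numeric vector of per-sample mean beta values.
#' @export
hypo_score <- function(betas, probe_ids) {
  .mean_score(betas, probe_ids)
}

#' Age-adjusted HypoClock score
#'
#' Per sample, `(1 - HypoScore) / age`; the cohort median of these is an
#' anti-correlative measure of the tissue's intrinsic division rate.
#'
#' @param scores Per-sample HypoClock scores in `[0, 1]`.
#' @param ages Matching positive ages in years.
#' @return List with `adjusted` (per-sample values, per year) and `median`.
#' @examples
#' hypo_age_adjust(c(0.9, 0.8), c(50, 100))
#' @export
hypo_age_adjust <- function(scores, ages) {
  stopifnot(length(scores) == length(ages))
  if (any(is.na(ages) | ages <= 0)) stop("all ages must be positive")
  adjusted <- (1 - scores) / ages
  list(adjusted = adjusted, median = stats::median(adjusted))
}

#' Rescale the age-adjusted HypoClock score to the raw dynamic range
#'
#' Age adjustment changes the scale of the HypoClock score; this affine map
#' restores the raw score's dynamic range: with
#' `gamma = (max(hypo) - min(hypo)) / (max(adj) - min(adj))`, returns
#' `max(1 - hypo) - gamma * max(adj) + gamma * adj` per sample. The output
#' range equals the input HypoScore range and the output maximum equals
#' `max(1 - hypo)`. The same transformation must cover every sample being
#' compared: pool all cohorts/tissues first.
#'
#' @param hypo_scores Per-sample raw HypoClock scores.
#' @param adjusted Matching age-adjusted values from [hypo_age_adjust()].
#' @return Rescaled per-sample values (higher = more divisions).
#' @examples
#' hypo_rescale(c(0.6, 0.8), c(0.005, 0.009))  # 0.2, 0.4
#' @export
hypo_rescale <- function(hypo_scores, adjusted) {
  stopifnot(length(hypo_scores) == length(adjusted))
  if (length(adjusted) < 2 || diff(range(adjusted)) == 0) {
    stop("need >= 2 samples with distinct age-adjusted values (gamma undefined)")
  }
  gamma <- diff(range(hypo_scores)) / diff(range(adjusted))
  max(1 - hypo_scores) - gamma * max(adjusted) + gamma * adjusted
}

#' Convert a tissue turnover time to an annual division rate
#'
#' `IR = 365 / turnover_days`: a tissue renewing every `turnover_days` days
#' undergoes that many stem-cell divisions per year.
#'
#' @param turnover_days Days per tissue renewal, positive.
#' @return Divisions per stem cell per year.
#' @examples
#' turnover_to_ir(10)    # blood: 36.5
#' turnover_to_ir(5.5)   # stomach: ~66.4
#' @export
turnover_to_ir <- function(turnover_days) {
  if (any(is.na(turnover_days) | turnover_days <= 0)) {
    stop("`turnover_days` must be positive")
  }
  365 / turnover_days
}

# Skin turnover time (days) for someone over 50: linear from 45 days at 50
# to 90 days at 80.
.skin_rd <- function(age) 1.5 * age - 30

#' Lifetime-averaged skin stem-cell division rate
#'
#' Skin turnover slows with age: renewal every 21 days up to age 20, every
#' 35 days between 20 and 50, then the turnover time grows linearly from 45
#' days at age 50 to 90 days at age 80 (`rd(age) = 1.5 * age - 30`). The
#' lifetime average IR for a person of a given age integrates these phases:
#' \itemize{
#'   \item age <= 20: `365 / 21`
#'   \item 20 < age <= 50: `(20 * 365/21 + (age - 20) * 365/35) / age`
#'   \item age > 50: `(20 * 365/21 + 30 * 365/35 + (age - 50) * 365 / rd(age)) / age`
#' }
#' Point evaluation at one age is the default; for a dispersed cohort, use
#' [skin_cohort_ir()] to average the per-person lifetime values.
#'
#' @param age Age(s) in years, positive. Vectorized.
#' @return Lifetime-average divisions per stem cell per year.
#' @examples
#' skin_lifetime_ir(15)  # 365/21, about 17.4
#' skin_lifetime_ir(50)  # about 13.2
#' @export
skin_lifetime_ir <- function(age) {
  if (any(is.na(age) | age <= 0)) stop("`age` must be positive")
  young <- 20 * 365 / 21
  mid <- 30 * 365 / 35
  ifelse(age <= 20, 365 / 21,
    ifelse(age <= 50, (young + (age - 20) * 365 / 35) / age,
      (young + mid + (age - 50) * 365 / .skin_rd(age)) / age))
}

#' @rdname skin_lifetime_ir
#' @param ages Cohort ages in years.
#' @return `skin_cohort_ir()`: the mean lifetime IR over the cohort.
#' @export
skin_cohort_ir <- function(ages) {
  mean(skin_lifetime_ir(ages))
}

#' Mann-Whitney AUC of a score between two groups
#'
#' Rank-based area under the ROC curve for a score discriminating two
#' groups, with a one-tailed Wilcoxon rank-sum p-value for the alternative
#' that the positive group scores higher. Ties are handled by midranks.
#'
#' @param scores Numeric scores.
#' @param labels Two-level group labels; the higher level (second factor
#'   level, or 1 for 0/1 labels) is the positive class.
#' @return List with `auc`, `p_value`, `n_positive`, `n_negative`.
#' @examples
#' group_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))  # auc = 1
#' @export
group_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  f <- factor(labels[keep])
  if (nlevels(f) != 2) stop("`labels` must contain exactly two groups")
  pos <- f == levels(f)[2]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- stats::wilcox.test(scores[pos], scores[!pos],
                          alternative = "greater", exact = FALSE)$p.value
  list(auc = auc, p_value = p, n_positive = n1, n_negative = n0)
}

#' Score a cohort with every available mitotic clock
#'
#' Convenience wrapper producing the per-sample score table: epiTOC2 TNSC
#' and lifetime rate (when a parameter table is given), epiTOC pcgtAge and
#' HypoClock scores (when probe lists are given), with age adjustment and
#' pooled rescaling of the HypoClock score.
#'
#' @param bm A [beta_matrix()].
#' @param params Optional epiTOC2 parameter `data.frame`
#'   (`probe_id`, `delta`, `beta0`).
#' @param epitoc_probes,hypo_probes Optional probe id vectors.
#' @param rescale_by Optional grouping vector (e.g. tissue) for per-group
#'   rescaling of the HypoClock score; default `NULL` pools all samples, the
#'   appropriate choice for cross-tissue comparison.
#' @return `data.frame` with one row per sample: `sample_id`, `age`, and the
#'   applicable columns among `tnsc`, `rate`, `pcgt_age`, `hypo_score`,
#'   `hypo_age_adj`, `hypo_rescaled`.
#' @export
score_cohort <- function(bm, params = NULL, epitoc_probes = NULL,
                         hypo_probes = NULL, rescale_by = NULL) {
  stopifnot(inherits(bm, "beta_matrix"))
  out <- data.frame(sample_id = bm$samples$sample_id, age = bm$samples$age,
                    stringsAsFactors = FALSE)
  if (!is.null(params)) {
    out$tnsc <- unname(estimate_tnsc(bm, params))
    out$rate <- lifetime_rate(out$tnsc, out$age)
  }
  if (!is.null(epitoc_probes)) {
    out$pcgt_age <- unname(pcgt_age_score(bm, epitoc_probes))
  }
  if (!is.null(hypo_probes)) {
    out$hypo_score <- unname(hypo_score(bm, hypo_probes))
    out$hypo_age_adj <- hypo_age_adjust(out$hypo_score, out$age)$adjusted
    if (is.null(rescale_by)) {
      out$hypo_rescaled <- hypo_rescale(out$hypo_score, out$hypo_age_adj)
    } else {
      stopifnot(length(rescale_by) == nrow(out))
      out$hypo_rescaled <- NA_real_
      for (g in unique(rescale_by)) {
        idx <- rescale_by == g
        out$hypo_rescaled[idx] <- hypo_rescale(out$hypo_score[idx],
                                               out$hypo_age_adj[idx])
      }
    }
  }
  out
}
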