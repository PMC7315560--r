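# Shared fixtures, built in code at test time.

# A scaled-down cohort spec: same six age bins as the full design, smaller
# per-bin counts (sum = 60) so fits stay fast in unit tests.
small_spec <- function(seed, n_sites = 14, direction = "gain", ...) {
  vt <- age_variance_table(n = c(5, 8, 12, 15, 12, 8))
  simulation_spec(n_sites = n_sites, n_samples = 60, variance_table = vt,
                  seed = seed, direction = direction, ...)
}

# Deterministic per-probe parameter table spanning realistic clock kinetics.
make_params <- function(n, seed = 11) {
  withr::with_seed(seed, {
    data.frame(
      probe_id = sprintf("cg%05d", seq_len(n)),
      delta = 10^stats::runif(n, -4.7, -3.7),
      beta0 = stats::runif(n, 0, 0.08),
      stringsAsFactors = FALSE
    )
  })
}

# Beta matrix whose probes follow the first-order accrual model exactly at
# the given per-sample division counts.
first_order_matrix <- function(params, tnscs) {
  m <- vapply(tnscs, function(tt) {
    first_order_beta_vec(params$delta, params$beta0, tt)
  }, numeric(nrow(params)))
  dimnames(m) <- list(params$probe_id,
                      sprintf("s%03d", seq_along(tnscs)))
  m
}

first_order_beta_vec <- function(delta, beta0, tnsc) {
  vapply(seq_along(delta), function(i) {
    first_order_beta(delta[i], beta0[i], tnsc)
  }, numeric(1))
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
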