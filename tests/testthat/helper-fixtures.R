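# Shared fixtures built in code.

# Independent root-finding oracle for the free-hormone binding equation:
# plain bisection on the molar mass-action polynomial.
bisect_ft <- function(tt, shbg, alb, constants = binding_constants()) {
  tt_m <- tt * 1e-9; shbg_m <- shbg * 1e-9
  nfac <- 1 + constants$k_a * alb / constants$albumin_molar_mass
  f <- function(ft) nfac * constants$k_t * ft^2 +
    (nfac + constants$k_t * (shbg_m - tt_m)) * ft - tt_m
  lo <- 0; hi <- tt_m
  if (f(hi) < 0) return(tt)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2 * 1e9
}

# Summary-level instrument simulator used by the MR estimator tests.
# Exposure effects gamma are positive (harmonized orientation); outcome
# effects are beta * gamma plus optional direct (pleiotropic) effects and
# sampling noise at the stated standard errors.
sim_instruments <- function(j = 50, beta = 0.5,
                            gamma_range = c(0.05, 0.15),
                            se_out = 0.02, se_exp = 1e-8,
                            direct_mean = 0, direct_sd = 0,
                            n_outliers = 0, outlier_size = 0,
                            outcome_type = "quantitative", k = NA_real_) {
  g_true <- runif(j, gamma_range[1], gamma_range[2])
  d <- if (direct_sd > 0 || direct_mean != 0)
    rnorm(j, direct_mean, direct_sd) else numeric(j)
  if (n_outliers > 0)
    d[seq_len(n_outliers)] <- d[seq_len(n_outliers)] + outlier_size
  g_hat <- g_true + rnorm(j, 0, se_exp)
  G_hat <- beta * g_true + d + rnorm(j, 0, se_out)
  instrument_set(sprintf("s%03d", seq_len(j)),
                 beta_exp = g_hat, se_exp = rep(se_exp, j),
                 beta_out = G_hat, se_out = rep(se_out, j),
                 outcome_type = outcome_type, k = k)
}

# A moderately sized cohort under the default (full-architecture)
# configuration, simulated once and cached across test files.
.fixture_env <- new.env()
big_cohort <- function() {
  if (is.null(.fixture_env$big))
    .fixture_env$big <- simulate_cohort(sim_config(
      n_individuals = 20000, n_variants = 1000, seed = 2024L))
  .fixture_env$big
}

# A tiny fast cohort for plumbing tests.
small_config <- function(seed = 11L, n_individuals = 600, ...) {
  sim_config(n_individuals = n_individuals, n_variants = 40,
             ld_block_size = 8, ld_rho = 0, n_ft_signals = 8,
             ft_variance_explained = 0.2, n_shbg_signals = 4, n_pcs = 2,
             missing_rate = 0.05, seed = seed, ...)
}
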