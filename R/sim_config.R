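#' Simulation configuration for a synthetic male biobank cohort
#'
#' Collects every knob of the cohort simulator. Defaults describe a
#' UK-Biobank-like male population: free testosterone (FT) with mean
#' 0.210 nmol/L and SD 0.07 nmol/L, a polygenic architecture of 93 signals
#' explaining 3.7% of FT variance, SHBG around 40 nmol/L with its own
#' genetics, albumin around 45 g/L, and total testosterone produced by the
#' forward mass-action binding model (which then averages ~11.9 nmol/L).
#' Assay noise (5% CV) and a small SHBG-coupled assay bias on total
#' testosterone model immunoassay imperfection, so that SHBG genetics can
#' leak into computed free testosterone as it does in real cohorts.
#'
#' @param n_individuals Cohort size.
#' @param n_variants Number of biallelic variants.
#' @param maf_range Range (low, high) of simulated effect-allele frequencies,
#'   within (0, 0.5].
#' @param ld_block_size Number of consecutive variants per LD block.
#' @param ld_rho Target genotype correlation between adjacent variants within
#'   a block, in [0, 1); across blocks variants are independent.
#' @param n_ft_signals Number of variants with direct effects on FT.
#' @param ft_variance_explained Fraction of FT variance explained by the FT
#'   signal variants jointly.
#' @param n_shbg_signals Number of variants with effects on SHBG (disjoint
#'   from the FT signals).
#' @param shbg_variance_explained Fraction of SHBG variance explained by the
#'   SHBG signal variants.
#' @param causal_effect_beta True causal effect of FT on each outcome, in
#'   outcome units (quantitative) or log-odds / liability units (binary) per
#'   nmol/L of FT.
#' @param pleiotropy_mode One of "none", "balanced", "directional", "outlier":
#'   how FT-signal variants receive direct (non-FT-mediated) outcome effects.
#' @param pleiotropy_fraction In outlier mode, the fraction of FT-signal
#'   variants given large direct effects.
#' @param pleiotropy_scale Magnitude of direct effects (SD in balanced mode,
#'   mean in directional mode, per-allele size in outlier mode), outcome
#'   units per allele.
#' @param confounder_strength Loading in [0, 1] of a shared standard-normal
#'   confounder on FT (as a fraction of non-genetic FT SD) and on outcomes.
#' @param binary_outcome_prevalences Named vector of prevalences in (0,1);
#'   names become binary outcome columns.
#' @param quantitative_outcomes Character vector of quantitative outcome
#'   column names.
#' @param binary_link "liability" (threshold model, near-exact prevalence) or
#'   "logistic".
#' @param ft_mean,ft_sd Mean and SD of latent FT, nmol/L.
#' @param shbg_mean,shbg_sd Mean and SD of SHBG, nmol/L.
#' @param alb_mean,alb_sd Mean and SD of albumin, g/L.
#' @param assay_cv_tt,assay_cv_shbg Multiplicative assay CV on measured total
#'   testosterone and SHBG.
#' @param shbg_assay_coupling Fractional bias of the total-testosterone assay
#'   per SD of SHBG (models assay interference).
#' @param androgen_rate Fraction self-reporting androgen medication.
#' @param missing_rate Fraction with a missing serum biomarker measurement.
#' @param med_bp_rate,med_chol_rate Fractions on blood-pressure and
#'   cholesterol medication (independent of genotype).
#' @param signal_effects Distribution of FT-signal per-allele effects before
#'   variance scaling: "normal" (a realistic spread of effect sizes) or
#'   "equal" (equal magnitudes, random sign — every signal equally
#'   discoverable, used by the demonstration configuration).
#' @param n_pcs Number of genetic principal-component covariates.
#' @param n_centers Number of assessment centres.
#' @param outcome_noise_sd Residual SD of quantitative outcomes.
#' @param seed Integer seed; a fixed seed makes the cohort bit-reproducible.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 1000,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_rho = 0.3,
                       n_ft_signals = 93,
                       ft_variance_explained = 0.037,
                       n_shbg_signals = 20,
                       shbg_variance_explained = 0.15,
                       causal_effect_beta = 0,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "outlier"),
                       pleiotropy_fraction = 0.1,
                       pleiotropy_scale = 0.1,
                       confounder_strength = 0.3,
                       binary_outcome_prevalences = c(disease = 0.2),
                       quantitative_outcomes = "quant_trait",
                       binary_link = c("liability", "logistic"),
                       ft_mean = 0.210, ft_sd = 0.07,
                       shbg_mean = 40, shbg_sd = 15,
                       alb_mean = 45, alb_sd = 2.5,
                       assay_cv_tt = 0.05, assay_cv_shbg = 0.05,
                       shbg_assay_coupling = 0.02,
                       androgen_rate = 0.011,
                       missing_rate = 0.13,
                       med_bp_rate = 0.246,
                       med_chol_rate = 0.227,
                       signal_effects = c("normal", "equal"),
                       n_pcs = 10,
                       n_centers = 5,
                       outcome_noise_sd = 1,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size),
              ld_rho = ld_rho,
              n_ft_signals = as.integer(n_ft_signals),
              ft_variance_explained = ft_variance_explained,
              n_shbg_signals = as.integer(n_shbg_signals),
              shbg_variance_explained = shbg_variance_explained,
              causal_effect_beta = causal_effect_beta,
              pleiotropy_mode = match.arg(pleiotropy_mode),
              pleiotropy_fraction = pleiotropy_fraction,
              pleiotropy_scale = pleiotropy_scale,
              confounder_strength = confounder_strength,
              binary_outcome_prevalences = binary_outcome_prevalences,
              quantitative_outcomes = quantitative_outcomes,
              binary_link = match.arg(binary_link),
              ft_mean = ft_mean, ft_sd = ft_sd,
              shbg_mean = shbg_mean, shbg_sd = shbg_sd,
              alb_mean = alb_mean, alb_sd = alb_sd,
              assay_cv_tt = assay_cv_tt, assay_cv_shbg = assay_cv_shbg,
              shbg_assay_coupling = shbg_assay_coupling,
              androgen_rate = androgen_rate,
              missing_rate = missing_rate,
              med_bp_rate = med_bp_rate,
              med_chol_rate = med_chol_rate,
              signal_effects = match.arg(signal_effects),
              n_pcs = as.integer(n_pcs),
              n_centers = as.integer(n_centers),
              outcome_noise_sd = outcome_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals > 1, cfg$n_variants >= 1,
            length(cfg$maf_range) == 2,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$ld_block_size >= 1,
            cfg$ld_rho >= 0, cfg$ld_rho < 1,
            cfg$n_ft_signals >= 0, cfg$n_shbg_signals >= 0,
            cfg$n_ft_signals + cfg$n_shbg_signals <= cfg$n_variants,
            cfg$ft_variance_explained >= 0, cfg$ft_variance_explained <= 1,
            cfg$shbg_variance_explained >= 0,
            cfg$shbg_variance_explained <= 1,
            cfg$pleiotropy_fraction >= 0, cfg$pleiotropy_fraction <= 1,
            cfg$confounder_strength >= 0, cfg$confounder_strength <= 1,
            cfg$ft_sd > 0, cfg$ft_mean > 0,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$androgen_rate >= 0, cfg$androgen_rate < 1)
  if (length(cfg$binary_outcome_prevalences)) {
    if (any(cfg$binary_outcome_prevalences <= 0 |
            cfg$binary_outcome_prevalences >= 1))
      stop("binary outcome prevalences must lie in (0,1)")
    if (is.null(names(cfg$binary_outcome_prevalences)))
      stop("binary_outcome_prevalences must be named")
  }
  invisible(cfg)
}

#' Desk-scale demonstration configuration
#'
#' A small cohort used by the worked examples and the end-to-end recovery
#' experiments: 5,000 individuals, 500 variants, 5 FT signals jointly
#' explaining 5% of FT variance (so each instrument is individually strong
#' at this sample size), and a binary outcome with a configurable causal
#' odds ratio per 0.1 nmol/L of FT generated through a logistic link.
#'
#' @param seed Integer seed.
#' @param causal_or_per_0.1 True odds ratio of the binary outcome per
#'   0.1 nmol/L of FT.
#' @param ... Overrides passed on to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
demo_config <- function(seed = 1L, causal_or_per_0.1 = 1.5, ...) {
  sim_config(n_individuals = 5000,
             n_variants = 500,
             n_ft_signals = 5,
             ft_variance_explained = 0.05,
             n_shbg_signals = 5,
             causal_effect_beta = log(causal_or_per_0.1) / 0.1,
             binary_outcome_prevalences = c(disease = 0.25),
             binary_link = "logistic",
             signal_effects = "equal",
             seed = seed,
             ...)
}
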