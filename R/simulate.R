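# Synthetic male-cohort simulator: genotypes with block LD, hormone
# biomarkers generated through the forward binding model, outcomes with
# configurable causal effect, confounding and pleiotropy.

.ftmr_env <- new.env(parent = emptyenv())

# 64-point Gauss-Legendre nodes/weights on [-1, 1], computed once
# (Golub-Welsch: eigen-decomposition of the Jacobi matrix).
gl_rule <- function() {
  if (is.null(.ftmr_env$gl)) {
    k <- 64L
    i <- seq_len(k - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, k, k)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    .ftmr_env$gl <- list(x = rev(e$values),
                         w = rev(2 * e$vectors[1, ]^2))
  }
  .ftmr_env$gl
}

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho.
bvn_upper_tail <- function(a, b, rho) {
  if (abs(rho) < 1e-12)
    return(stats::pnorm(a, lower.tail = FALSE) *
           stats::pnorm(b, lower.tail = FALSE))
  hi <- max(a + 9, 9)
  gl <- gl_rule()
  x <- (hi - a) / 2 * gl$x + (hi + a) / 2
  f <- stats::dnorm(x) *
    stats::pnorm((rho * x - b) / sqrt(1 - rho^2))
  sum(gl$w * f) * (hi - a) / 2
}

# Latent-normal correlation that yields allele-indicator correlation
# `target` after thresholding at frequencies p and q (Gaussian copula
# calibration). Capped just below the feasible maximum.
latent_rho_for <- function(target, p, q) {
  if (target <= 0) return(0)
  a <- stats::qnorm(1 - p)
  b <- stats::qnorm(1 - q)
  denom <- sqrt(p * (1 - p) * q * (1 - q))
  r_of <- function(rho) (bvn_upper_tail(a, b, rho) - p * q) / denom
  hi <- 0.9995
  if (r_of(hi) <= target) return(hi)
  stats::uniroot(function(rho) r_of(rho) - target,
                 lower = 0, upper = hi, tol = 1e-4)$root
}

#' Simulate biallelic genotype dosages with block linkage disequilibrium
#'
#' Draws two haplotypes per individual from a Gaussian copula with an AR(1)
#' latent correlation inside each LD block, thresholded at the effect-allele
#' frequency; dosage is the allele sum. The latent correlation of each
#' adjacent pair is calibrated so the realized genotype correlation matches
#' \code{ld_rho}; blocks are mutually independent. The last block is
#' truncated when \code{n_variants} is not a multiple of the block size.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{dosages} (individuals x variants matrix of
#'   0/1/2) and \code{variant_info} (id, chromosome, position, effect and
#'   other allele, empirical EAF).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  m <- config$n_variants
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  block <- (seq_len(m) - 1) %/% config$ld_block_size + 1
  rho_lat <- numeric(m)  # latent correlation with previous variant
  if (config$ld_rho > 0) {
    for (j in 2:max(2, m)) {
      if (m >= 2 && block[j] == block[j - 1])
        rho_lat[j] <- latent_rho_for(config$ld_rho, maf[j - 1], maf[j])
    }
  }
  thr <- stats::qnorm(1 - maf)  # allele present when latent > threshold
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (config$ld_rho > 0 && m >= 2) {
      for (j in 2:m) {
        if (rho_lat[j] > 0)
          z[, j] <- rho_lat[j] * z[, j - 1] +
            sqrt(1 - rho_lat[j]^2) * z[, j]
      }
    }
    dos <- dos + (z > rep(thr, each = n))
  }
  ids <- sprintf("v%04d", seq_len(m))
  chrom <- (block - 1L) %% 22L + 1L
  pos <- integer(m)
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    pos[sel] <- seq_len(sum(sel)) * 50000L +
      2000000L * (block[sel] - min(block[sel]))
  }
  colnames(dos) <- ids
  list(dosages = dos,
       variant_info = data.frame(id = ids, chromosome = chrom, position = pos,
                                 effect_allele = "A", other_allele = "G",
                                 eaf = colMeans(dos) / 2,
                                 stringsAsFactors = FALSE))
}

# polygenic component over `idx` columns scaled to explain `ve` of total
# variance `total_var`; returns list(score, effects)
polygenic_score <- function(dosages, idx, ve, total_var,
                            dist = c("normal", "equal")) {
  dist <- match.arg(dist)
  if (length(idx) == 0 || ve <= 0)
    return(list(score = rep(0, nrow(dosages)), effects = numeric(0)))
  b <- if (dist == "equal")
    sample(c(-1, 1), length(idx), replace = TRUE)
  else stats::rnorm(length(idx))
  g <- as.vector(dosages[, idx, drop = FALSE] %*% b)
  v <- stats::var(g)
  s <- if (v > 0) sqrt(ve * total_var / v) else 0
  list(score = g * s, effects = b * s)
}

# centered right-skewed noise: scaled centered lognormal(0, sdlog)
skewed_noise <- function(n, target_var, sdlog = 0.5) {
  if (target_var <= 0) return(rep(0, n))
  l <- stats::rlnorm(n, 0, sdlog)
  v <- exp(sdlog^2) * (exp(sdlog^2) - 1)
  (l - exp(sdlog^2 / 2)) * sqrt(target_var / v)
}

#' Simulate hormone biomarkers from genotypes
#'
#' Latent free testosterone is a polygenic score over the designated FT
#' signal variants (scaled to the configured variance explained) plus a
#' shared confounder and right-skewed residual noise; SHBG has its own
#' disjoint genetics; albumin is narrowly distributed. True total
#' testosterone follows the forward mass-action binding equation; measured
#' total testosterone and SHBG add multiplicative assay noise, and the
#' total-testosterone assay carries a small SHBG-coupled bias.
#'
#' @param dosages Genotype dosage matrix from
#'   \code{\link{simulate_genotypes}}.
#' @param config A \code{\link{sim_config}}.
#' @param age Optional age vector (years) for a small negative age trend in
#'   FT.
#' @return List with \code{biomarkers} (measured values: total_testosterone,
#'   shbg, albumin, red_cell_count, mean_corpuscular_volume),
#'   \code{latent} (ft, shbg_true, tt_true, confounder), and \code{log}
#'   (signal indices, per-allele effects, floored-draw counts).
#' @export
simulate_hormones <- function(dosages, config, age = NULL) {
  set.seed(config$seed + 2L)
  n <- nrow(dosages)
  m <- ncol(dosages)
  idx <- sample.int(m, config$n_ft_signals + config$n_shbg_signals)
  ft_idx <- idx[seq_len(config$n_ft_signals)]
  shbg_idx <- idx[setdiff(seq_along(idx), seq_len(config$n_ft_signals))]

  g_ft <- polygenic_score(dosages, ft_idx, config$ft_variance_explained,
                          config$ft_sd^2, dist = config$signal_effects)
  u <- stats::rnorm(n)
  c_u <- config$confounder_strength *
    sqrt(1 - config$ft_variance_explained) * config$ft_sd
  var_eps <- config$ft_sd^2 * (1 - config$ft_variance_explained) - c_u^2
  age_eff <- if (is.null(age)) 0 else -0.0004 * (age - mean(age))
  ft <- config$ft_mean + g_ft$score - mean(g_ft$score) + c_u * u + age_eff +
    skewed_noise(n, var_eps)
  n_ft_floored <- sum(ft < 0.001)
  ft <- pmax(ft, 0.001)

  g_sh <- polygenic_score(dosages, shbg_idx, config$shbg_variance_explained,
                          config$shbg_sd^2)
  shbg <- config$shbg_mean + g_sh$score - mean(g_sh$score) +
    skewed_noise(n, config$shbg_sd^2 * (1 - config$shbg_variance_explained))
  shbg <- pmax(shbg, 1)

  alb <- pmax(stats::rnorm(n, config$alb_mean, config$alb_sd), 30)
  tt_true <- tt_forward(ft, shbg, alb)
  shbg_z <- (shbg - mean(shbg)) / stats::sd(shbg)
  tt_meas <- pmax(tt_true * (1 + config$assay_cv_tt * stats::rnorm(n)) *
                    (1 + config$shbg_assay_coupling * shbg_z), 0.01)
  shbg_meas <- pmax(shbg * (1 + config$assay_cv_shbg * stats::rnorm(n)), 0.5)

  biomarkers <- data.frame(
    total_testosterone = tt_meas,
    shbg = shbg_meas,
    albumin = alb,
    red_cell_count = pmax(stats::rnorm(n, 5.0, 0.35), 2),
    mean_corpuscular_volume = pmax(stats::rnorm(n, 90, 4), 60))
  latent <- data.frame(ft = ft, shbg_true = shbg, tt_true = tt_true,
                       confounder = u)
  log <- list(ft_signal_idx = ft_idx,
              ft_signal_ids = colnames(dosages)[ft_idx],
              ft_effects = g_ft$effects,
              shbg_signal_idx = shbg_idx,
              shbg_signal_ids = colnames(dosages)[shbg_idx],
              shbg_effects = g_sh$effects,
              n_ft_floored = n_ft_floored)
  list(biomarkers = biomarkers, latent = latent, log = log)
}

#' Simulate outcomes with configurable causal effect and pleiotropy
#'
#' Each outcome is built from the latent free testosterone (causal path),
#' the shared confounder, direct per-variant effects on the FT-signal
#' variants according to the pleiotropy mode, and noise. Binary outcomes use
#' a liability-threshold link (near-exact prevalence control) or a logistic
#' link whose intercept is solved to hit the configured prevalence.
#'
#' @param dosages Genotype dosage matrix.
#' @param latent Latent data frame from \code{\link{simulate_hormones}}.
#' @param config A \code{\link{sim_config}}.
#' @param hormone_log Log from \code{\link{simulate_hormones}} (provides the
#'   FT-signal variant indices).
#' @return List with \code{outcomes} (data frame) and \code{log}
#'   (per-outcome direct effects and flagged pleiotropic variants).
#' @export
simulate_outcomes <- function(dosages, latent, config, hormone_log) {
  set.seed(config$seed + 3L)
  n <- nrow(dosages)
  ft_c <- latent$ft - mean(latent$ft)
  c_out <- config$confounder_strength * config$outcome_noise_sd
  ft_idx <- hormone_log$ft_signal_idx
  nsig <- length(ft_idx)

  draw_direct <- function() {
    d <- numeric(nsig)
    flagged <- integer(0)
    if (nsig > 0) {
      sc <- config$pleiotropy_scale
      if (config$pleiotropy_mode == "balanced") {
        d <- stats::rnorm(nsig, 0, sc); flagged <- seq_len(nsig)
      } else if (config$pleiotropy_mode == "directional") {
        d <- stats::rnorm(nsig, sc, sc / 2); flagged <- seq_len(nsig)
      } else if (config$pleiotropy_mode == "outlier") {
        k <- round(config$pleiotropy_fraction * nsig)
        flagged <- sort(sample.int(nsig, k))
        d[flagged] <- sc * sample(c(-1, 1), k, replace = TRUE)
      }
    }
    list(d = d, flagged = flagged)
  }
  linpred <- function(d) {
    out <- config$causal_effect_beta * ft_c + c_out * latent$confounder
    if (nsig > 0 && any(d != 0))
      out <- out + as.vector(dosages[, ft_idx, drop = FALSE] %*% d)
    out
  }

  outcomes <- data.frame(row.names = seq_len(n))
  olog <- list()
  for (nm in config$quantitative_outcomes) {
    dd <- draw_direct()
    outcomes[[nm]] <- linpred(dd$d) +
      stats::rnorm(n, 0, config$outcome_noise_sd)
    olog[[nm]] <- list(type = "quantitative", direct = dd$d,
                       flagged_ids = hormone_log$ft_signal_ids[dd$flagged])
  }
  for (nm in names(config$binary_outcome_prevalences)) {
    prev <- config$binary_outcome_prevalences[[nm]]
    dd <- draw_direct()
    lin <- linpred(dd$d)
    if (config$binary_link == "liability") {
      liab <- lin + stats::rnorm(n)
      z <- (liab - mean(liab)) / stats::sd(liab)
      outcomes[[nm]] <- as.integer(z > stats::qnorm(1 - prev))
    } else {
      alpha <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) - prev,
                              lower = -30, upper = 30)$root
      outcomes[[nm]] <- stats::rbinom(n, 1, stats::plogis(alpha + lin))
    }
    olog[[nm]] <- list(type = "binary", prevalence = prev, direct = dd$d,
                       flagged_ids = hormone_log$ft_signal_ids[dd$flagged])
  }
  list(outcomes = outcomes, log = olog)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the genotype, covariate, hormone and outcome generators under a
#' single seed (expanded internally per stage) and assembles the cohort:
#' dosages, variant metadata, a phenotype table (covariates, measured
#' biomarkers with injected missingness, outcomes, medication flags), the
#' latent truth, and a simulation log holding every true parameter for
#' recovery tests.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{ft_cohort}.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  geno <- simulate_genotypes(config)
  n <- config$n_individuals

  set.seed(config$seed + 4L)
  covar <- data.frame(
    age = round(stats::runif(n, 38, 73)),
    chip = sample(c("chip_a", "chip_b"), n, replace = TRUE),
    center = sample(sprintf("center_%d", seq_len(config$n_centers)), n,
                    replace = TRUE))
  covar$age2 <- covar$age^2
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  colnames(pcs) <- sprintf("pc%d", seq_len(config$n_pcs))
  covar <- cbind(covar, as.data.frame(pcs))

  horm <- simulate_hormones(geno$dosages, config, age = covar$age)
  outc <- simulate_outcomes(geno$dosages, horm$latent, config, horm$log)

  set.seed(config$seed + 5L)
  miss <- stats::rbinom(n, 1, config$missing_rate) == 1
  bio <- horm$biomarkers
  bio$total_testosterone[miss] <- NA
  bio$shbg[miss] <- NA
  bio$albumin[miss] <- NA
  meds <- data.frame(
    med_androgen = stats::rbinom(n, 1, config$androgen_rate),
    med_bp = stats::rbinom(n, 1, config$med_bp_rate),
    med_chol = stats::rbinom(n, 1, config$med_chol_rate))

  phenotypes <- cbind(data.frame(id = seq_len(n)), covar, bio,
                      outc$outcomes, meds)
  sim_log <- c(horm$log,
               list(outcomes = outc$log,
                    causal_effect_beta = config$causal_effect_beta,
                    pleiotropy_mode = config$pleiotropy_mode,
                    seed = config$seed))
  structure(list(dosages = geno$dosages,
                 variant_info = geno$variant_info,
                 phenotypes = phenotypes,
                 latent = horm$latent,
                 sim_log = sim_log,
                 config = config),
            class = "ft_cohort")
}

#' @export
print.ft_cohort <- function(x, ...) {
  cat(sprintf("<ft_cohort> %d individuals x %d variants (seed %d)\n",
              nrow(x$dosages), ncol(x$dosages), x$config$seed))
  cat(sprintf("  FT signals: %d; SHBG signals: %d; outcomes: %s\n",
              length(x$sim_log$ft_signal_idx),
              length(x$sim_log$shbg_signal_idx),
              paste(names(x$sim_log$outcomes), collapse = ", ")))
  invisible(x)
}

#' Default GWAS covariate columns for a cohort phenotype table
#'
#' Age, age squared, genotyping chip, assessment centre, and the genetic
#' principal components present in the table.
#'
#' @param phenotypes Phenotype data frame.
#' @return Character vector of column names.
#' @export
default_covariates <- function(phenotypes) {
  c("age", "age2", "chip", "center",
    grep("^pc[0-9]+$", names(phenotypes), value = TRUE))
}
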