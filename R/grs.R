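# Weighted genetic risk score, calibration to exposure units, phenome-wide
# scan, power-based outcome filter, and family-wise error control.

#' Build a weighted genetic risk score and calibrate it to exposure units
#'
#' The score is the weighted allele count
#' \eqn{score_i = \sum_j \gamma_j \, dosage_{ij}} over the (positively
#' oriented) instruments. The calibration slope — nmol/L of exposure per
#' score unit — is the covariate-adjusted regression coefficient of the
#' exposure on the score, and is what converts per-score-unit outcome
#' effects to the per-0.1 nmol/L reporting scale. Missing dosages are
#' mean-imputed per variant.
#'
#' @param dosages Dosage matrix; rows indexed by \code{phenotypes$id}.
#' @param weights Data frame with columns \code{id} and \code{beta_exp}
#'   (per-allele exposure effects from harmonized instruments).
#' @param phenotypes Phenotype data frame with the exposure column.
#' @param exposure Exposure column name (default "cft").
#' @param covariates Covariate column names.
#' @return List of class \code{grs_profile}: \code{score} (named by
#'   individual id, full dosage-matrix rows), \code{calibration_slope},
#'   \code{r2} (variance of exposure explained by the score),
#'   \code{n_imputed}, \code{weights}.
#' @export
build_grs <- function(dosages, weights, phenotypes, exposure = "cft",
                      covariates = default_covariates(phenotypes)) {
  stopifnot(all(c("id", "beta_exp") %in% names(weights)),
            all(weights$id %in% colnames(dosages)))
  g <- dosages[, weights$id, drop = FALSE]
  n_imputed <- sum(is.na(g))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(g))) {
      nas <- is.na(g[, j])
      if (any(nas)) g[nas, j] <- mean(g[, j], na.rm = TRUE)
    }
  }
  score <- as.vector(g %*% weights$beta_exp)
  use <- stats::complete.cases(phenotypes[, c(exposure, covariates),
                                          drop = FALSE])
  ph <- phenotypes[use, , drop = FALSE]
  design <- covariate_design(ph, covariates)
  y_r <- residualize(ph[[exposure]], design)
  s_r <- residualize(score[ph$id], design)
  if (sum(s_r^2) < 1e-12) {
    warning("GRS has no variance; calibration undefined")
    slope <- NA_real_; r2 <- 0
  } else {
    slope <- sum(s_r * y_r) / sum(s_r^2)
    r2 <- slope^2 * sum(s_r^2) / sum((y_r - mean(y_r))^2)
    if (slope <= 0)
      warning("GRS calibration slope is not positive; check orientation")
  }
  structure(list(score = score, calibration_slope = slope, r2 = r2,
                 n_imputed = n_imputed, weights = weights),
            class = "grs_profile")
}

#' Phenome-wide association scan of a genetic risk score
#'
#' Regresses each outcome on the score with covariate adjustment — linear
#' regression for quantitative outcomes, logistic for binary — and rescales
#' effects to per 0.1 nmol/L of the exposure by dividing by the GRS
#' calibration slope and multiplying by 0.1. Binary outcomes with fewer
#' than 2 cases (or 2 controls) among complete cases are skipped with a
#' reason.
#'
#' @param phenotypes Phenotype data frame.
#' @param grs A \code{\link{build_grs}} profile.
#' @param outcome_spec Data frame with columns \code{name},
#'   \code{type} ("quantitative"/"binary"), optional \code{category}.
#' @param covariates Covariate column names.
#' @param alpha_family Family-wise threshold for the significance flag.
#' @param scale Reporting scale in exposure units (default 0.1 nmol/L).
#' @return Data frame of PheWAS records: outcome, category, type, n,
#'   cases, beta (per scale units; log-odds for binary), se, or with CI,
#'   p, significant, skipped_reason.
#' @export
phewas_scan <- function(phenotypes, grs, outcome_spec,
                        covariates = default_covariates(phenotypes),
                        alpha_family = 0.05, scale = 0.1) {
  stopifnot(all(c("name", "type") %in% names(outcome_spec)))
  factor_rescale <- scale / grs$calibration_slope
  rows <- lapply(seq_len(nrow(outcome_spec)), function(i) {
    nm <- outcome_spec$name[i]
    ty <- outcome_spec$type[i]
    cat <- if ("category" %in% names(outcome_spec))
      outcome_spec$category[i] else NA_character_
    rec <- data.frame(outcome = nm, category = cat, type = ty,
                      n = NA_integer_, cases = NA_integer_,
                      beta = NA_real_, se = NA_real_, or = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      p = NA_real_, significant = NA,
                      skipped_reason = NA_character_,
                      stringsAsFactors = FALSE)
    use <- stats::complete.cases(phenotypes[, c(nm, covariates),
                                            drop = FALSE])
    ph <- phenotypes[use, , drop = FALSE]
    ph$grs_score <- grs$score[ph$id]
    rec$n <- nrow(ph)
    f <- stats::as.formula(paste(nm, "~ grs_score +",
                                 paste(covariates, collapse = " + ")))
    if (ty == "binary") {
      rec$cases <- sum(ph[[nm]] == 1)
      if (rec$cases < 2 || rec$n - rec$cases < 2) {
        rec$skipped_reason <- "fewer than 2 cases or controls"
        return(rec)
      }
      fit <- stats::glm(f, data = ph, family = stats::binomial())
      co <- summary(fit)$coefficients["grs_score", ]
    } else {
      fit <- stats::lm(f, data = ph)
      co <- summary(fit)$coefficients["grs_score", ]
    }
    rec$beta <- co[["Estimate"]] * factor_rescale
    rec$se <- co[["Std. Error"]] * factor_rescale
    rec$p <- co[[4]]
    rec$ci_lower <- rec$beta - stats::qnorm(0.975) * rec$se
    rec$ci_upper <- rec$beta + stats::qnorm(0.975) * rec$se
    if (ty == "binary") rec$or <- exp(rec$beta)
    rec$significant <- rec$p < alpha_family
    rec
  })
  do.call(rbind, rows)
}

#' Per-test Bonferroni threshold
#'
#' @param m Number of tests in the family (at least 1).
#' @param alpha_total Family-wise error rate (default 0.05).
#' @return \code{alpha_total / m}.
#' @export
bonferroni_threshold <- function(m, alpha_total = 0.05) {
  stopifnot(m >= 1)
  alpha_total / m
}

#' Minimum detectable odds ratio for a GRS-on-outcome test
#'
#' Normal-approximation power calculation for a score test of a binary
#' outcome on a genetic score explaining \code{grs_r2} of the exposure
#' variance: the standard error of the log-odds effect per SD of exposure
#' is \eqn{1/\sqrt{n\,k(1-k)\,R^2}}, so the minimal detectable log-OR per
#' \code{per} exposure units at the given power and two-sided alpha is
#' \eqn{(z_{1-\alpha/2} + z_{power}) \cdot se \cdot per/\sigma_{exposure}}.
#'
#' @param n_cases,n_total Case count and total sample size.
#' @param grs_r2 Exposure variance explained by the score, in (0, 1).
#' @param power Target power (default 0.8).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param exposure_sd SD of the exposure (nmol/L; default 0.07).
#' @param per Reporting scale in exposure units (default 0.1 nmol/L).
#' @return Minimum detectable OR (> 1) per \code{per} exposure units.
#' @export
detectable_or <- function(n_cases, n_total, grs_r2, power = 0.8,
                          alpha = 0.05, exposure_sd = 0.07, per = 0.1) {
  stopifnot(grs_r2 > 0, grs_r2 < 1, all(n_cases >= 0), n_total > 0)
  k <- n_cases / n_total
  se_per_sd <- 1 / sqrt(n_total * k * (1 - k) * grs_r2)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  exp(z * se_per_sd * per / exposure_sd)
}

#' Power-based outcome filter
#'
#' Retains binary outcomes whose detectable-OR interval
#' \eqn{[1/OR_{det}, OR_{det}]} lies inside the stated bounds — i.e. the
#' study has at least the target power against odds ratios at the bounds.
#' Also reports the induced minimum case count: the smallest case count at
#' which the upper bound is detectable.
#'
#' @param case_counts Named vector of case counts per outcome.
#' @param n_total Total sample size.
#' @param grs_r2 Exposure variance explained by the score.
#' @param bounds Odds-ratio bounds, default \code{c(0.5, 2)} per 0.1
#'   nmol/L.
#' @param power,alpha,exposure_sd,per Passed to
#'   \code{\link{detectable_or}}.
#' @return List: \code{retained} (outcome names), \code{detectable}
#'   (per-outcome detectable OR), \code{case_cutoff} (induced minimum case
#'   count).
#' @export
power_filter <- function(case_counts, n_total, grs_r2,
                         bounds = c(0.5, 2), power = 0.8, alpha = 0.05,
                         exposure_sd = 0.07, per = 0.1) {
  det <- detectable_or(case_counts, n_total, grs_r2, power, alpha,
                       exposure_sd, per)
  keep <- det <= bounds[2] & 1 / det >= bounds[1]
  cutoff <- tryCatch(ceiling(stats::uniroot(function(nc)
    detectable_or(nc, n_total, grs_r2, power, alpha, exposure_sd, per) -
      bounds[2], lower = 1, upper = n_total / 2)$root),
    error = function(e) NA_integer_)
  list(retained = names(case_counts)[keep], detectable = det,
       case_cutoff = cutoff)
}

#' Re-run a PheWAS scan on a medication-free subset
#'
#' Repeats the scan on individuals with the exclusion flag unset and
#' reports directional consistency (sign agreement of the effect) with the
#' full-cohort estimates.
#'
#' @param phenotypes Phenotype data frame.
#' @param grs A \code{\link{build_grs}} profile.
#' @param outcome_spec Outcome specification (see
#'   \code{\link{phewas_scan}}).
#' @param exclusion_flag Name of a 0/1 column; rows with 1 are excluded.
#' @param full_results Results of the full-cohort scan for comparison.
#' @param ... Passed to \code{\link{phewas_scan}}.
#' @return The subset scan with columns \code{subset}, \code{n_excluded},
#'   \code{sign_consistent}.
#' @export
subset_rerun <- function(phenotypes, grs, outcome_spec, exclusion_flag,
                         full_results, ...) {
  stopifnot(exclusion_flag %in% names(phenotypes))
  keep <- !(phenotypes[[exclusion_flag]] %in% 1)
  if (!any(keep)) stop("exclusion flag removes every individual")
  sub <- phewas_scan(phenotypes[keep, , drop = FALSE], grs, outcome_spec,
                     ...)
  sub$subset <- paste0("excluding ", exclusion_flag)
  sub$n_excluded <- sum(!keep)
  idx <- match(sub$outcome, full_results$outcome)
  sub$sign_consistent <- sign(sub$beta) == sign(full_results$beta[idx])
  sub
}
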