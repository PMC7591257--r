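# One-sample Mendelian randomization estimators and sensitivity suite,
# implemented from the estimators' definitions: IVW, MR-Egger, MR-RAPS,
# MR-PRESSO, Wald ratios, leave-one-out, and the reporting decision rules.

#' Build an instrument set from harmonized effect pairs
#'
#' @param id Variant ids.
#' @param beta_exp,se_exp Per-allele effect and SE on the exposure
#'   (nmol/L CFT per allele).
#' @param beta_out,se_out Per-allele effect and SE on the outcome (outcome
#'   units, linear-probability units, or log-odds per allele).
#' @param outcome Outcome name.
#' @param outcome_type "quantitative" or "binary".
#' @param k Case fraction (binary outcomes only).
#' @return Data frame of class \code{instrument_set}.
#' @export
instrument_set <- function(id, beta_exp, se_exp, beta_out, se_out,
                           outcome = "outcome",
                           outcome_type = c("quantitative", "binary"),
                           k = NA_real_) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(all(se_exp > 0), all(se_out > 0), length(id) >= 1)
  if (outcome_type == "binary") stopifnot(k > 0, k < 1)
  structure(data.frame(id = id, beta_exp = beta_exp, se_exp = se_exp,
                       beta_out = beta_out, se_out = se_out,
                       stringsAsFactors = FALSE),
            outcome = outcome, outcome_type = outcome_type, k = k,
            class = c("instrument_set", "data.frame"))
}

keep_inst_attrs <- function(x, template) {
  attr(x, "outcome") <- attr(template, "outcome")
  attr(x, "outcome_type") <- attr(template, "outcome_type")
  attr(x, "k") <- attr(template, "k")
  class(x) <- c("instrument_set", "data.frame")
  x
}

#' Harmonize exposure and outcome association records
#'
#' In a one-sample design both scans share the allele coding, so
#' harmonization checks that variants and alleles match, then orients every
#' instrument so its exposure effect is positive (flipping the outcome
#' effect sign with it). Wald ratios are invariant to this orientation.
#'
#' @param exposure_assoc,outcome_assoc Association records sharing ids and
#'   alleles.
#' @param outcome Outcome name.
#' @param outcome_type "quantitative" or "binary".
#' @param k Case fraction for binary outcomes.
#' @return An \code{\link{instrument_set}}.
#' @export
harmonize <- function(exposure_assoc, outcome_assoc, outcome = "outcome",
                      outcome_type = "quantitative", k = NA_real_) {
  idx <- match(exposure_assoc$id, outcome_assoc$id)
  if (anyNA(idx))
    stop("variants missing from outcome scan: ",
         paste(exposure_assoc$id[is.na(idx)], collapse = ", "))
  oa <- outcome_assoc[idx, , drop = FALSE]
  if (!is.null(exposure_assoc$effect_allele) &&
      !all(is.na(exposure_assoc$effect_allele))) {
    bad <- exposure_assoc$effect_allele != oa$effect_allele |
      exposure_assoc$other_allele != oa$other_allele
    if (any(bad, na.rm = TRUE))
      stop("allele mismatch for: ",
           paste(exposure_assoc$id[which(bad)], collapse = ", "))
  }
  flip <- ifelse(exposure_assoc$beta < 0, -1, 1)
  instrument_set(id = exposure_assoc$id,
                 beta_exp = exposure_assoc$beta * flip,
                 se_exp = exposure_assoc$se,
                 beta_out = oa$beta * flip,
                 se_out = oa$se,
                 outcome = outcome, outcome_type = outcome_type, k = k)
}

mr_estimate <- function(method, beta, se, j, scale = 1,
                        diagnostics = list(), df = Inf) {
  beta <- beta * scale
  se <- se * scale
  p <- if (is.finite(df)) 2 * stats::pt(-abs(beta / se), df)
       else 2 * stats::pnorm(-abs(beta / se))
  structure(list(method = method, beta = beta, se = se,
                 ci_lower = beta - stats::qnorm(0.975) * se,
                 ci_upper = beta + stats::qnorm(0.975) * se,
                 p = p, n_snp = j, scale = scale,
                 diagnostics = diagnostics),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (95%% CI %.4g to %.4g), p = %.3g, J = %d%s\n",
              x$method, x$beta, x$ci_lower, x$ci_upper, x$p, x$n_snp,
              if (x$scale != 1)
                sprintf(" [per %g exposure units]", x$scale) else ""))
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' \eqn{\beta = \Gamma/\gamma} with first-order delta-method standard error
#' \eqn{\sigma_\Gamma/|\gamma|}.
#'
#' @param beta_exp,se_exp Exposure effect and SE.
#' @param beta_out,se_out Outcome effect and SE.
#' @param scale Reporting scale in exposure units (default 1; use 0.1 for
#'   per-0.1 nmol/L).
#' @return An \code{mr_estimate}.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, scale = 1) {
  if (beta_exp == 0) stop("wald_ratio undefined for a null exposure effect")
  mr_estimate("Wald ratio", beta_out / beta_exp, se_out / abs(beta_exp),
              1L, scale)
}

#' Inverse-variance-weighted MR estimate
#'
#' \eqn{\hat\beta = \sum_j \gamma_j \Gamma_j/\sigma^2_{\Gamma j} \big/
#' \sum_j \gamma_j^2/\sigma^2_{\Gamma j}}. The variance
#' \eqn{1/\sum_j \gamma_j^2/\sigma^2_{\Gamma j}} is inflated by
#' \eqn{\max(1, RSS/(J-1))} under the multiplicative random-effects
#' convention (J of at least 2); with a single instrument the estimate
#' reduces exactly to the Wald ratio. Two-sided p from the normal
#' reference.
#'
#' @param inst An \code{\link{instrument_set}}.
#' @param scale Reporting scale in exposure units.
#' @return An \code{mr_estimate} with heterogeneity diagnostics (Cochran
#'   RSS and its inflation factor).
#' @export
mr_ivw <- function(inst, scale = 1) {
  j <- nrow(inst)
  stopifnot(j >= 1)
  w <- 1 / inst$se_out^2
  denom <- sum(inst$beta_exp^2 * w)
  beta <- sum(inst$beta_exp * inst$beta_out * w) / denom
  rss <- sum(w * (inst$beta_out - beta * inst$beta_exp)^2)
  infl <- if (j >= 2) max(1, rss / (j - 1)) else 1
  se <- sqrt(infl / denom)
  mr_estimate("IVW", beta, se, j, scale,
              diagnostics = list(rss = rss, dispersion = infl))
}

#' Convert a linear-probability effect to the log-odds scale
#'
#' For a binary outcome analyzed with a linear model on 0/1,
#' \eqn{\log OR = \beta/(k(1-k))} where k is the case fraction; the SE
#' scales by the same factor.
#'
#' @param beta,se Linear-probability effect and SE.
#' @param k Case fraction in (0, 1).
#' @return List with \code{log_or}, \code{se}, \code{or}.
#' @export
logodds_convert <- function(beta, se, k) {
  if (any(k <= 0) || any(k >= 1)) stop("case fraction k must lie in (0,1)")
  f <- 1 / (k * (1 - k))
  list(log_or = beta * f, se = se * f, or = exp(beta * f))
}

#' Convert an instrument set's outcome side to log-odds
#'
#' @param inst A binary-outcome \code{\link{instrument_set}} whose outcome
#'   effects are on the linear-probability scale.
#' @return The instrument set with \code{beta_out}/\code{se_out} on the
#'   log-odds scale.
#' @export
inst_to_logodds <- function(inst) {
  stopifnot(attr(inst, "outcome_type") == "binary")
  k <- attr(inst, "k")
  conv <- logodds_convert(inst$beta_out, inst$se_out, k)
  inst$beta_out <- conv$log_or
  inst$se_out <- conv$se
  inst
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the (positively
#' oriented) exposure effects with weights \eqn{1/\sigma^2_{\Gamma j}} and a
#' free intercept. The slope is the pleiotropy-adjusted causal estimate;
#' the intercept estimates average directional pleiotropy, with a two-sided
#' t test on J - 2 degrees of freedom. Residual dispersion is floored at 1
#' (multiplicative random effects).
#'
#' @param inst An \code{\link{instrument_set}} with at least 3 instruments.
#' @param scale Reporting scale in exposure units.
#' @return An \code{mr_estimate}; diagnostics carry
#'   \code{egger_intercept}, \code{egger_intercept_se},
#'   \code{egger_intercept_p}.
#' @export
mr_egger <- function(inst, scale = 1) {
  j <- nrow(inst)
  if (j < 3) stop("MR-Egger needs at least 3 instruments")
  if (any(inst$beta_exp < 0))
    stop("MR-Egger requires positively oriented exposure effects; harmonize first")
  w <- 1 / inst$se_out^2
  x <- cbind(1, inst$beta_exp)
  xtwx <- crossprod(x, w * x)
  est <- solve(xtwx, crossprod(x, w * inst$beta_out))
  resid <- inst$beta_out - x %*% est
  sigma2 <- sum(w * resid^2) / (j - 2)
  disp2 <- max(1, sigma2)                  # never deflate below 1
  ses <- sqrt(diag(solve(xtwx)) * disp2)
  slope <- est[2]; slope_se <- ses[2]
  int <- est[1]; int_se <- ses[1]
  int_p <- 2 * stats::pt(-abs(int / int_se), df = j - 2)
  mr_estimate("MR-Egger", slope, slope_se, j, scale,
              diagnostics = list(egger_intercept = int,
                                 egger_intercept_se = int_se,
                                 egger_intercept_p = int_p),
              df = j - 2)
}

# loss psi functions and the Fisher-consistency constant E[psi(Z) Z]
raps_psi <- function(loss) {
  switch(loss,
    l2 = list(psi = function(t) t,
              dpsi = function(t) rep(1, length(t)),
              rho = function(t) t^2 / 2,
              delta = 1),
    huber = {
      k <- 1.345
      list(psi = function(t) pmin(pmax(t, -k), k),
           dpsi = function(t) as.numeric(abs(t) <= k),
           rho = function(t) ifelse(abs(t) <= k, t^2 / 2,
                                    k * abs(t) - k^2 / 2),
           delta = stats::integrate(function(z)
             pmin(pmax(z, -k), k) * z * stats::dnorm(z),
             -Inf, Inf)$value)
    },
    tukey = {
      cc <- 4.685
      list(psi = function(t) ifelse(abs(t) <= cc,
                                    t * (1 - (t / cc)^2)^2, 0),
           dpsi = function(t) ifelse(abs(t) <= cc,
             (1 - (t / cc)^2) * (1 - 5 * (t / cc)^2), 0),
           rho = function(t) ifelse(abs(t) <= cc,
             cc^2 / 6 * (1 - (1 - (t / cc)^2)^3), cc^2 / 6),
           delta = stats::integrate(function(z)
             ifelse(abs(z) <= cc, z * (1 - (z / cc)^2)^2, 0) * z *
               stats::dnorm(z), -Inf, Inf)$value)
    },
    stop("unknown loss: ", loss))
}

#' MR-RAPS: robust adjusted profile score estimation
#'
#' Solves the robustified profile-score estimating equation
#' \eqn{\sum_j \psi(t_j)\,\partial t_j/\partial\beta = 0} with standardized
#' residuals
#' \eqn{t_j = (\Gamma_j - \beta\gamma_j)/\sqrt{\sigma^2_{\Gamma j} +
#' \beta^2\sigma^2_{\gamma j} + \tau^2}}, where \eqn{\psi} is the derivative
#' of the chosen loss (Tukey biweight c = 4.685 by default, Huber k = 1.345,
#' or plain l2). The overdispersion \eqn{\tau^2 \ge 0} is solved jointly
#' from the Fisher-consistent second-moment condition
#' \eqn{\sum_j [\psi(t_j) t_j - E_\Phi \psi(Z)Z] = 0} and pinned at 0 when
#' the condition is negative there. Roots are located by a deterministic
#' multi-start grid followed by bisection, keeping the root minimizing the
#' robust objective; the standard error is the M-estimation sandwich.
#' In the l2 / no-overdispersion / error-free-exposure limit the estimate
#' equals IVW.
#'
#' @param inst An \code{\link{instrument_set}} with at least 3 instruments.
#' @param overdispersion Estimate tau-squared (default TRUE).
#' @param loss "tukey" (default), "huber", or "l2".
#' @param scale Reporting scale in exposure units.
#' @param max_iter,tol Convergence controls for the beta/tau iteration.
#' @return An \code{mr_estimate}; diagnostics carry \code{tau2} and the
#'   convergence flag.
#' @export
mr_raps <- function(inst, overdispersion = TRUE,
                    loss = c("tukey", "huber", "l2"), scale = 1,
                    max_iter = 100, tol = 1e-10) {
  loss <- match.arg(loss)
  j <- nrow(inst)
  if (j < 3) stop("MR-RAPS needs at least 3 instruments")
  L <- raps_psi(loss)
  g <- inst$beta_exp; sg2 <- inst$se_exp^2
  G <- inst$beta_out; sG2 <- inst$se_out^2

  score <- function(beta, tau2) {
    s2 <- sG2 + beta^2 * sg2 + tau2
    s <- sqrt(s2)
    t <- (G - beta * g) / s
    dt <- -(g + t * beta * sg2 / s) / s
    sum(L$psi(t) * dt)
  }
  objective <- function(beta, tau2) {
    s2 <- sG2 + beta^2 * sg2 + tau2
    sum(L$rho((G - beta * g) / sqrt(s2)) + 0.5 * log(s2))
  }
  moment <- function(tau2, beta) {
    t <- (G - beta * g) / sqrt(sG2 + beta^2 * sg2 + tau2)
    sum(L$psi(t) * t - L$delta)
  }
  solve_beta <- function(tau2, span) {
    grid <- seq(span[1], span[2], length.out = 201)
    f <- vapply(grid, score, numeric(1), tau2 = tau2)
    sc <- which(diff(sign(f)) != 0)
    if (length(sc) == 0) return(grid[which.min(
      vapply(grid, objective, numeric(1), tau2 = tau2))])
    roots <- vapply(sc, function(i)
      stats::uniroot(score, c(grid[i], grid[i + 1]), tau2 = tau2,
                     tol = 1e-12)$root, numeric(1))
    roots[which.min(vapply(roots, objective, numeric(1), tau2 = tau2))]
  }

  b0 <- mr_ivw(inst)$beta
  width <- max(10 * abs(b0), 10 * stats::mad(G / g), 1)
  span <- c(b0 - width, b0 + width)
  beta <- b0; tau2 <- 0; converged <- FALSE
  for (it in seq_len(max_iter)) {
    beta_new <- solve_beta(tau2, span)
    tau2_new <- 0
    if (overdispersion && moment(0, beta_new) > 0) {
      up <- stats::var(G - beta_new * g) + max(sG2)
      while (moment(up, beta_new) > 0) up <- up * 4
      tau2_new <- stats::uniroot(moment, c(0, up), beta = beta_new,
                                 tol = 1e-12)$root
    }
    if (abs(beta_new - beta) < tol && abs(tau2_new - tau2) < tol) {
      beta <- beta_new; tau2 <- tau2_new; converged <- TRUE; break
    }
    beta <- beta_new; tau2 <- tau2_new
  }
  if (!converged && it == max_iter)
    warning("mr_raps: beta/tau iteration did not fully converge")
  s2 <- sG2 + beta^2 * sg2 + tau2
  s <- sqrt(s2)
  t <- (G - beta * g) / s
  dt <- -(g + t * beta * sg2 / s) / s
  A <- sum(L$dpsi(t) * dt^2)
  B <- sum((L$psi(t) * dt)^2)
  se <- sqrt(B) / abs(A)
  mr_estimate("MR-RAPS", beta, se, j, scale,
              diagnostics = list(tau2 = tau2, loss = loss,
                                 converged = converged))
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' The observed residual sum of squares uses the leave-one-out IVW estimate
#' per variant, \eqn{RSS = \sum_j w_j (\Gamma_j -
#' \hat\beta_{(-j)}\gamma_j)^2} with \eqn{w_j = 1/\sigma^2_{\Gamma j}}; its
#' null distribution is simulated parametrically,
#' \eqn{\Gamma^*_j \sim N(\gamma_j\hat\beta_{(-j)}, \sigma^2_{\Gamma j})},
#' recomputing the leave-one-out estimates on each simulated draw. The
#' global p is the empirical tail proportion with add-one correction.
#' Per-variant outlier p-values compare each observed weighted residual to
#' its simulated distribution, Bonferroni-adjusted over J. When the global
#' test rejects at \code{alpha}, outliers are removed, IVW repeated on the
#' survivors, and the distortion test compares the observed displacement to
#' removals of random subsets of the same cardinality.
#'
#' @param inst An \code{\link{instrument_set}} with at least 4 instruments.
#' @param n_sim Number of parametric simulations (at least 100; the
#'   full-scale analysis uses 10,000).
#' @param alpha Threshold for the global test and (after Bonferroni) for
#'   outlier flags.
#' @param n_distortion Random subsets for the distortion null (default
#'   1000).
#' @param seed Seed for the Monte-Carlo draws (recorded in the output).
#' @param scale Reporting scale in exposure units.
#' @return List: \code{global_p}, \code{rss_obs}, \code{outlier_ids},
#'   \code{outlier_p} (Bonferroni-adjusted, per variant),
#'   \code{corrected} (IVW on survivors, NULL when no correction was
#'   triggered), \code{distortion_p} (NULL without correction),
#'   \code{n_sim}, \code{seed}.
#' @export
mr_presso <- function(inst, n_sim = 1000, alpha = 0.05,
                      n_distortion = 1000, seed = 42L, scale = 1) {
  j <- nrow(inst)
  if (j < 4) stop("MR-PRESSO needs at least 4 instruments")
  stopifnot(n_sim >= 100)
  set.seed(seed)
  g <- inst$beta_exp; G <- inst$beta_out
  w <- 1 / inst$se_out^2
  s1 <- sum(g^2 * w)
  s2 <- sum(g * G * w)
  beta_loo <- (s2 - g * G * w) / (s1 - g^2 * w)
  res_obs <- w * (G - beta_loo * g)^2
  rss_obs <- sum(res_obs)

  gs <- matrix(stats::rnorm(n_sim * j,
                            mean = rep(g * beta_loo, each = n_sim),
                            sd = rep(inst$se_out, each = n_sim)),
               n_sim, j)
  s2_sim <- gs %*% (g * w)
  beta_loo_sim <- (as.vector(s2_sim) - t(t(gs) * (g * w))) /
    rep(s1 - g^2 * w, each = n_sim)
  res_sim <- t(t(gs - t(t(beta_loo_sim) * g))^2 * w)
  rss_sim <- rowSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)

  outlier_p_raw <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) /
    (1 + n_sim)
  outlier_p <- pmin(outlier_p_raw * j, 1)
  outliers <- which(outlier_p < alpha)

  corrected <- NULL
  distortion_p <- NULL
  outlier_ids <- character(0)
  if (global_p < alpha && length(outliers) > 0) {
    if (length(outliers) == j) stop("no instruments survive outlier removal")
    outlier_ids <- inst$id[outliers]
    survivors <- keep_inst_attrs(inst[-outliers, , drop = FALSE], inst)
    corrected <- mr_ivw(survivors, scale = scale)
    beta_full <- mr_ivw(inst, scale = scale)$beta
    d_obs <- corrected$beta - beta_full
    d_null <- vapply(seq_len(n_distortion), function(b) {
      drop <- sample.int(j, length(outliers))
      sub <- keep_inst_attrs(inst[-drop, , drop = FALSE], inst)
      mr_ivw(sub, scale = scale)$beta - beta_full
    }, numeric(1))
    distortion_p <- mean(abs(d_null) >= abs(d_obs))
  }
  list(global_p = global_p, rss_obs = rss_obs,
       outlier_ids = outlier_ids, outlier_p = outlier_p,
       corrected = corrected, distortion_p = distortion_p,
       n_sim = n_sim, seed = seed)
}

#' Leave-one-out IVW analysis
#'
#' Repeats the IVW estimate excluding each instrument in turn, flagging
#' exclusions whose estimate leaves the full-set 95 percent confidence
#' interval (a single variant driving the result).
#'
#' @param inst An \code{\link{instrument_set}} with at least 2 instruments.
#' @param scale Reporting scale in exposure units.
#' @return Data frame: excluded id, beta, se, ci, p, outside_full_ci.
#' @export
leave_one_out <- function(inst, scale = 1) {
  j <- nrow(inst)
  stopifnot(j >= 2)
  full <- mr_ivw(inst, scale = scale)
  rows <- lapply(seq_len(j), function(i) {
    e <- mr_ivw(keep_inst_attrs(inst[-i, , drop = FALSE], inst),
                scale = scale)
    data.frame(excluded = inst$id[i], beta = e$beta, se = e$se,
               ci_lower = e$ci_lower, ci_upper = e$ci_upper, p = e$p,
               outside_full_ci = e$beta < full$ci_lower |
                 e$beta > full$ci_upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full MR analysis of one outcome with reporting decision rules
#'
#' Runs IVW (the primary estimator) plus the sensitivity suite and applies
#' the reporting rules: when the Egger intercept differs from zero at
#' p < 0.05 the MR-Egger estimate is reported in place of IVW; when the
#' PRESSO global test rejects at p < 0.05 the outlier-corrected instrument
#' set replaces the full set (and Egger, if triggered, is refit on it).
#' Binary outcomes on the linear-probability scale are converted to
#' log-odds before estimation.
#'
#' @param inst An \code{\link{instrument_set}} (linear-probability outcome
#'   scale for binary outcomes).
#' @param alpha_family Family-wise significance threshold for the outcome's
#'   analysis family (e.g. \code{bonferroni_threshold(22)}).
#' @param scale Reporting scale in exposure units (default 0.1 nmol/L).
#' @param n_sim PRESSO simulations.
#' @param seed Seed for PRESSO Monte-Carlo.
#' @param run_presso,run_raps,run_egger Toggles for the sensitivity suite
#'   (each needs enough instruments).
#' @return List of class \code{mr_report}: outcome, estimates (all
#'   methods), \code{reported} (the decision-rule estimate), diagnostics,
#'   \code{significant} flag at \code{alpha_family}.
#' @export
mr_report <- function(inst, alpha_family = 0.05, scale = 0.1,
                      n_sim = 1000, seed = 42L,
                      run_presso = nrow(inst) >= 4,
                      run_raps = nrow(inst) >= 3,
                      run_egger = nrow(inst) >= 3) {
  binary <- identical(attr(inst, "outcome_type"), "binary")
  work <- if (binary) inst_to_logodds(inst) else inst
  ivw <- mr_ivw(work, scale = scale)
  egger <- if (run_egger) mr_egger(work, scale = scale) else NULL
  raps <- if (run_raps) mr_raps(work, scale = scale) else NULL
  presso <- if (run_presso) mr_presso(work, n_sim = n_sim, seed = seed,
                                      scale = scale) else NULL
  loo <- if (nrow(work) >= 2) leave_one_out(work, scale = scale) else NULL

  analysis_set <- work
  corrected <- FALSE
  if (!is.null(presso) && presso$global_p < 0.05 &&
      length(presso$outlier_ids) > 0) {
    analysis_set <- keep_inst_attrs(
      work[!work$id %in% presso$outlier_ids, , drop = FALSE], work)
    corrected <- TRUE
  }
  ivw_final <- if (corrected) mr_ivw(analysis_set, scale = scale) else ivw
  reported <- ivw_final
  method_note <- if (corrected) "IVW (outlier-corrected)" else "IVW"
  # the Egger decision rule is applied to the analysis set in use: after
  # outlier correction the sensitivity analysis is repeated on the
  # corrected set
  egger_final <- if (corrected && run_egger && nrow(analysis_set) >= 3)
    mr_egger(analysis_set, scale = scale) else egger
  if (!is.null(egger_final) &&
      egger_final$diagnostics$egger_intercept_p < 0.05) {
    reported <- egger_final
    method_note <- if (corrected) "MR-Egger (outlier-corrected)"
                   else "MR-Egger"
  }
  reported$method <- method_note
  structure(list(outcome = attr(inst, "outcome"),
                 outcome_type = attr(inst, "outcome_type"),
                 estimates = list(ivw = ivw, egger = egger, raps = raps,
                                  presso = presso, loo = loo),
                 reported = reported,
                 significant = reported$p < alpha_family,
                 alpha_family = alpha_family,
                 seed = seed),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR report for '%s' (%s outcome)\n", x$outcome,
              x$outcome_type))
  print(x$reported)
  if (!is.null(x$estimates$egger))
    cat(sprintf("  Egger intercept p = %.3g\n",
                x$estimates$egger$diagnostics$egger_intercept_p))
  if (!is.null(x$estimates$presso))
    cat(sprintf("  PRESSO global p = %.3g (%d outlier(s))\n",
                x$estimates$presso$global_p,
                length(x$estimates$presso$outlier_ids)))
  cat(sprintf("  significant at alpha = %.3g: %s\n", x$alpha_family,
              x$significant))
  invisible(x)
}

#' Forest-plot-ready table from MR reports
#'
#' @param reports List of \code{mr_report} objects.
#' @return Data frame: outcome, type, method, beta, ci bounds, p,
#'   significant.
#' @export
mr_results_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    e <- r$reported
    data.frame(outcome = r$outcome, type = r$outcome_type,
               method = e$method, beta = e$beta,
               ci_lower = e$ci_lower, ci_upper = e$ci_upper, p = e$p,
               n_snp = e$n_snp, significant = r$significant,
               stringsAsFactors = FALSE)
  }))
}
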