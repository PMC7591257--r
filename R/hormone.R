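#' Binding constants for the free-testosterone mass-action model
#'
#' Association constants of testosterone for SHBG and albumin used by the
#' Vermeulen free-hormone calculation. Defaults are the canonical Vermeulen
#' (1999) parameterization.
#'
#' @param k_t SHBG-testosterone association constant, L/mol.
#' @param k_a Albumin-testosterone association constant, L/mol.
#' @param albumin_molar_mass Molar mass of albumin, g/mol.
#' @return A list of class \code{binding_constants}.
#' @export
binding_constants <- function(k_t = 1.0e9, k_a = 3.6e4,
                              albumin_molar_mass = 69000) {
  stopifnot(k_t > 0, k_a > 0, albumin_molar_mass > 0)
  structure(list(k_t = k_t, k_a = k_a,
                 albumin_molar_mass = albumin_molar_mass),
            class = "binding_constants")
}

#' Calculated free testosterone (Vermeulen equation)
#'
#' Computes free testosterone from total testosterone, SHBG and albumin by
#' solving the mass-action binding equilibrium. Free testosterone FT (mol/L)
#' is the positive root of
#' \deqn{N K_t FT^2 + (N + K_t(SHBG - TT)) FT - TT = 0,}
#' where \eqn{N = 1 + K_a [Alb]} accounts for the low-affinity, high-capacity
#' albumin pool. All concentrations are converted to mol/L internally; the
#' result is returned in nmol/L. Vectorized over its first three arguments.
#'
#' @param tt Total testosterone, nmol/L (>= 0).
#' @param shbg SHBG, nmol/L (>= 0).
#' @param alb Albumin, g/L (> 0).
#' @param constants A \code{\link{binding_constants}} object.
#' @return Free testosterone in nmol/L, satisfying \code{0 <= ft <= tt}.
#' @export
cft_vermeulen <- function(tt, shbg, alb, constants = binding_constants()) {
  n <- max(length(tt), length(shbg), length(alb))
  tt <- rep_len(tt, n); shbg <- rep_len(shbg, n); alb <- rep_len(alb, n)
  if (any(!is.finite(tt)) || any(!is.finite(shbg)) || any(!is.finite(alb)))
    stop("non-finite input to cft_vermeulen")
  if (any(tt < 0) || any(shbg < 0) || any(alb <= 0))
    stop("cft_vermeulen requires tt >= 0, shbg >= 0, alb > 0")
  tt_m <- tt * 1e-9
  shbg_m <- shbg * 1e-9
  alb_m <- alb / constants$albumin_molar_mass
  nfac <- 1 + constants$k_a * alb_m
  a <- nfac * constants$k_t
  b <- nfac + constants$k_t * (shbg_m - tt_m)
  disc <- b^2 + 4 * a * tt_m
  stopifnot(all(disc >= 0))
  ft_m <- (-b + sqrt(disc)) / (2 * a)
  ft <- pmin(pmax(ft_m * 1e9, 0), tt)
  ft
}

#' Forward mass-action binding: total testosterone from free testosterone
#'
#' The forward counterpart of \code{\link{cft_vermeulen}}:
#' \eqn{TT = FT \cdot N + K_t FT \cdot SHBG / (1 + K_t FT)} with concentrations
#' in mol/L. Used by the cohort simulator to generate total testosterone from
#' latent free testosterone, so that the downstream inversion is exact.
#'
#' @param ft Free testosterone, nmol/L.
#' @param shbg SHBG, nmol/L.
#' @param alb Albumin, g/L.
#' @param constants A \code{\link{binding_constants}} object.
#' @return Total testosterone, nmol/L.
#' @export
tt_forward <- function(ft, shbg, alb, constants = binding_constants()) {
  stopifnot(all(ft >= 0), all(shbg >= 0), all(alb > 0))
  ft_m <- ft * 1e-9
  shbg_m <- shbg * 1e-9
  alb_m <- alb / constants$albumin_molar_mass
  nfac <- 1 + constants$k_a * alb_m
  tt_m <- ft_m * nfac + constants$k_t * ft_m * shbg_m / (1 + constants$k_t * ft_m)
  tt_m * 1e9
}

#' Winsorize at mean +/- 4 SD
#'
#' Clips values lying beyond four standard deviations from the mean to
#' exactly mean +/- 4 SD, with mean and SD computed on the input (pre-clip)
#' distribution. If the SD is zero the input is returned unchanged.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param n_sd Number of SDs at which to clip (default 4).
#' @return Clipped vector of the same length.
#' @export
winsorize_4sd <- function(values, n_sd = 4) {
  finite <- is.finite(values)
  if (sum(finite) < 2) stop("winsorize_4sd needs >= 2 finite values")
  m <- mean(values[finite])
  s <- stats::sd(values[finite])
  if (s == 0) return(values)
  pmin(pmax(values, m - n_sd * s), m + n_sd * s)
}

#' Hematocrit from red-cell count and mean corpuscular volume
#'
#' Relative volume of packed erythrocytes in whole blood, in percent:
#' \code{rbc * mcv / 10}.
#'
#' @param rbc Red blood cell count, 10^12/L (> 0).
#' @param mcv Mean corpuscular volume, fL (> 0).
#' @return Hematocrit, percent.
#' @export
hematocrit_from_counts <- function(rbc, mcv) {
  if (any(rbc <= 0) || any(mcv <= 0))
    stop("hematocrit_from_counts requires positive rbc and mcv")
  rbc * mcv / 10
}

#' Phenotype construction: exclusions and derived biomarkers
#'
#' Applies the analysis exclusions (androgen medication use; missing total
#' testosterone, SHBG or albumin) and then derives the analysis phenotypes on
#' the retained subset: calculated free testosterone (winsorized at 4 SD on
#' the post-exclusion male distribution), natural-log SHBG, and hematocrit
#' from red-cell indices. Exclusion first, winsorization second.
#'
#' @param phenotypes Data frame with columns \code{total_testosterone},
#'   \code{shbg}, \code{albumin}, \code{med_androgen}, and optionally
#'   \code{red_cell_count}, \code{mean_corpuscular_volume}.
#' @param constants A \code{\link{binding_constants}} object.
#' @return The retained rows with added columns \code{cft}, \code{log_shbg}
#'   and (when red-cell indices are present) \code{hematocrit}; attribute
#'   \code{exclusions} records counts per reason.
#' @export
prepare_phenotypes <- function(phenotypes, constants = binding_constants()) {
  stopifnot(all(c("total_testosterone", "shbg", "albumin", "med_androgen")
                %in% names(phenotypes)))
  miss <- !stats::complete.cases(
    phenotypes[, c("total_testosterone", "shbg", "albumin")])
  androgen <- phenotypes$med_androgen %in% 1
  keep <- !miss & !androgen
  out <- phenotypes[keep, , drop = FALSE]
  out$cft <- winsorize_4sd(
    cft_vermeulen(out$total_testosterone, out$shbg, out$albumin, constants))
  out$log_shbg <- log(out$shbg)
  if (all(c("red_cell_count", "mean_corpuscular_volume") %in% names(out)))
    out$hematocrit <- hematocrit_from_counts(out$red_cell_count,
                                             out$mean_corpuscular_volume)
  attr(out, "exclusions") <- c(n_input = nrow(phenotypes),
                               n_missing_biomarker = sum(miss),
                               n_androgen_medication = sum(androgen & !miss),
                               n_retained = nrow(out))
  out
}
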