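# Per-variant association scan, variant QC, instrument discovery.

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact two-sided test of HWE by full enumeration of the conditional
#' distribution of heterozygote counts given the allele counts
#' (Wigginton-Cutler-Abecasis construction): the p-value is the summed
#' probability of all heterozygote counts no more likely than the observed
#' one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom. reference, het., hom. alt.).
#' @return Two-sided exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab          # minor-agnostic: use rarer allele
  rare <- min(n_a, 2 * n - n_a)
  het_obs <- n_ab
  # possible heterozygote counts share parity with the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized log-probabilities of each het count (hypergeometric-like)
  hom_r <- (rare - hets) / 2
  hom_c <- n - hets - hom_r
  logp <- hets * log(2) - lfactorial(hets) - lfactorial(hom_r) -
    lfactorial(hom_c)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[match(het_obs, hets)] * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Retains variants with minor allele frequency at or above
#' \code{maf_min}, HWE exact-test p at or above \code{hwe_p_min},
#' imputation info at or above \code{info_min} (skipped when no info scores
#' are supplied), and position outside every blacklisted region. Each
#' excluded variant gets exactly one primary reason, in priority order
#' region > MAF > HWE > info. Dosages are rounded to hard genotype calls for
#' the HWE test.
#'
#' @param dosages Dosage matrix (individuals x variants).
#' @param variant_info Data frame with id, chromosome, position.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param hwe_p_min Minimum HWE exact p (default 1e-10).
#' @param info_min Minimum imputation info (default 0.7).
#' @param info Optional named vector of per-variant info scores.
#' @param blacklist Data frame (chromosome, start, end) of excluded regions;
#'   default is the extended HLA region chr6:25,000,000-34,000,000 (GRCh37
#'   convention, closed 1-based interval).
#' @return List with \code{keep} (retained variant ids) and \code{report}
#'   (per-variant maf, hwe_p, info, pass flag, reason).
#' @export
variant_qc <- function(dosages, variant_info,
                       maf_min = 0.01, hwe_p_min = 1e-10, info_min = 0.7,
                       info = NULL,
                       blacklist = data.frame(chromosome = 6,
                                              start = 25e6, end = 34e6)) {
  stopifnot(ncol(dosages) == nrow(variant_info))
  eaf <- colMeans(dosages) / 2
  maf <- pmin(eaf, 1 - eaf)
  g <- round(dosages)
  hwe <- vapply(seq_len(ncol(g)), function(j) {
    tb <- tabulate(g[, j] + 1L, nbins = 3L)
    hwe_exact_p(tb[1], tb[2], tb[3])
  }, numeric(1))
  in_region <- rep(FALSE, nrow(variant_info))
  for (r in seq_len(nrow(blacklist))) {
    in_region <- in_region |
      (variant_info$chromosome == blacklist$chromosome[r] &
       variant_info$position >= blacklist$start[r] &
       variant_info$position <= blacklist$end[r])
  }
  info_v <- if (is.null(info)) rep(NA_real_, ncol(dosages))
            else info[variant_info$id]
  reason <- rep(NA_character_, ncol(dosages))
  reason[!is.na(info_v) & info_v < info_min] <- "info"
  reason[hwe < hwe_p_min] <- "HWE"
  reason[maf < maf_min] <- "MAF"
  reason[in_region] <- "region"
  report <- data.frame(id = variant_info$id, maf = maf, hwe_p = hwe,
                       info = info_v, pass = is.na(reason), reason = reason,
                       stringsAsFactors = FALSE)
  list(keep = variant_info$id[is.na(reason)], report = report)
}

# residualize columns of x against the covariate design (QR, rank-aware)
residualize <- function(x, design) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    warning("collinear covariates dropped (rank ",
            qr_d$rank, " < ", ncol(design), ")")
  qr.resid(qr_d, x)
}

covariate_design <- function(phenotypes, covariates) {
  if (length(covariates) == 0)
    return(matrix(1, nrow(phenotypes), 1))
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  stats::model.matrix(f, data = phenotypes)
}

#' Genome-wide association scan by covariate-adjusted least squares
#'
#' Per-variant slope of the trait on effect-allele dosage adjusted for
#' covariates (Frisch-Waugh partialled regression: trait and dosages are
#' residualized against the covariate design, then regressed per variant).
#' Two-sided p-values come from the t distribution with n - p - 1 degrees
#' of freedom. Binary traits are fitted with the same linear model on 0/1;
#' downstream log-odds conversion handles the scale.
#'
#' @param dosages Dosage matrix; rows indexed by \code{phenotypes$id}.
#' @param phenotypes Phenotype data frame (complete cases are used).
#' @param trait Name of the trait column.
#' @param covariates Covariate column names (categorical columns are
#'   expanded to indicators); default \code{\link{default_covariates}}.
#' @param variant_info Variant metadata aligned to \code{dosages} columns.
#' @return Data frame of association records: id, chromosome, position,
#'   effect_allele, other_allele, eaf, beta, se, p, n. Zero-variance
#'   dosages are skipped.
#' @export
gwas_scan <- function(dosages, phenotypes, trait,
                      covariates = default_covariates(phenotypes),
                      variant_info = NULL) {
  stopifnot(trait %in% names(phenotypes))
  use <- stats::complete.cases(phenotypes[, c(trait, covariates),
                                          drop = FALSE])
  ph <- phenotypes[use, , drop = FALSE]
  g <- dosages[ph$id, , drop = FALSE]
  y <- ph[[trait]]
  design <- covariate_design(ph, covariates)
  n <- length(y)
  p_cov <- qr(design)$rank
  y_r <- residualize(y, design)
  g_r <- residualize(g, design)
  sxx <- colSums(g_r^2)
  ok <- sxx > 1e-10
  sxy <- colSums(g_r * y_r)
  beta <- sxy[ok] / sxx[ok]
  syy <- sum(y_r^2)
  df <- n - p_cov - 1
  rss <- pmax(syy - beta * sxy[ok], 0)
  se <- sqrt(rss / df / sxx[ok])
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  vi <- if (is.null(variant_info))
    data.frame(id = colnames(dosages), chromosome = NA, position = NA,
               effect_allele = NA, other_allele = NA,
               stringsAsFactors = FALSE)
  else variant_info
  out <- data.frame(id = vi$id[ok],
                    chromosome = vi$chromosome[ok],
                    position = vi$position[ok],
                    effect_allele = vi$effect_allele[ok],
                    other_allele = vi$other_allele[ok],
                    eaf = colMeans(g)[ok] / 2,
                    beta = beta, se = se, p = pmax(pval, .Machine$double.xmin),
                    n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median of the per-variant chi-square statistics
#' \eqn{(\beta/se)^2} divided by the null median 0.4549364. Values near 1
#' indicate a well-calibrated scan; polygenic traits inflate the median.
#'
#' @param assoc Association records from \code{\link{gwas_scan}}.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(assoc) {
  if (nrow(assoc) < 100)
    warning("fewer than 100 variants; lambda is unstable")
  chisq <- (assoc$beta / assoc$se)^2
  stats::median(chisq) / 0.4549364
}

#' Filter exposure hits by SHBG association
#'
#' Drops exposure-associated variants that are also associated with natural
#' log-transformed SHBG at \code{p_threshold}, removing variants whose
#' apparent free-testosterone signal may act through binding-protein
#' biology rather than testosterone production.
#'
#' @param hits Exposure association records (the genome-wide hits).
#' @param shbg_assoc SHBG association records on the same variant set and
#'   allele orientation.
#' @param p_threshold Exclusion threshold (default 0.05): hits with SHBG
#'   p below it are removed.
#' @return The retained subset of \code{hits}, with column \code{shbg_p}.
#' @export
shbg_filter <- function(hits, shbg_assoc, p_threshold = 0.05) {
  idx <- match(hits$id, shbg_assoc$id)
  if (anyNA(idx))
    stop("variants missing from the SHBG scan: ",
         paste(hits$id[is.na(idx)], collapse = ", "))
  hits$shbg_p <- shbg_assoc$p[idx]
  hits[hits$shbg_p >= p_threshold, , drop = FALSE]
}

#' LD pruning by greedy clumping
#'
#' Sorts hits by ascending p (ties: chromosome, then position), keeps the
#' best, discards every remaining variant whose squared dosage correlation
#' with any kept variant is at or above \code{r2_threshold}, and repeats.
#' All retained pairs satisfy r-squared below the threshold.
#'
#' @param hits Association records of candidate instruments.
#' @param dosages Dosage matrix containing a column per hit.
#' @param r2_threshold Squared-correlation threshold (default 0.01).
#' @return The retained (independent) subset of \code{hits}, in selection
#'   order.
#' @export
ld_prune <- function(hits, dosages, r2_threshold = 0.01) {
  if (nrow(hits) == 0) return(hits)
  stopifnot(all(hits$id %in% colnames(dosages)))
  ord <- order(hits$p, hits$chromosome, hits$position)
  cand <- hits[ord, , drop = FALSE]
  g <- dosages[, cand$id, drop = FALSE]
  kept <- integer(0)
  for (j in seq_len(nrow(cand))) {
    if (length(kept) == 0) { kept <- j; next }
    r2 <- stats::cor(g[, kept, drop = FALSE], g[, j])^2
    if (all(r2 < r2_threshold)) kept <- c(kept, j)
  }
  cand[kept, , drop = FALSE]
}

#' Instrument-strength F statistic from summary quantities
#'
#' \eqn{F = \frac{n - J - 1}{J} \cdot \frac{R^2}{1 - R^2}} for J instruments
#' jointly explaining \eqn{R^2} of the exposure in n individuals. F above
#' 10 is the conventional threshold for strong instruments.
#'
#' @param r2 Variance explained, in (0, 1).
#' @param j Number of instruments.
#' @param n Sample size (must exceed j + 1).
#' @return Scalar F.
#' @export
f_statistic <- function(r2, j, n) {
  stopifnot(j >= 1, n > j + 1, r2 >= 0, r2 < 1)
  (n - j - 1) / j * r2 / (1 - r2)
}

#' Joint instrument strength on individual-level data
#'
#' Covariate-adjusted R-squared of the exposure on all instrument dosages
#' jointly, and the corresponding F statistic.
#'
#' @param dosages Dosage matrix; rows indexed by \code{phenotypes$id}.
#' @param phenotypes Phenotype data frame with the exposure column.
#' @param exposure Exposure column name.
#' @param instrument_ids Variant ids of the instruments.
#' @param covariates Covariate column names.
#' @return List with \code{r2}, \code{f}, \code{j}, \code{n}.
#' @export
instrument_strength <- function(dosages, phenotypes, exposure,
                                instrument_ids,
                                covariates = default_covariates(phenotypes)) {
  j <- length(instrument_ids)
  stopifnot(j >= 1)
  use <- stats::complete.cases(phenotypes[, c(exposure, covariates),
                                          drop = FALSE])
  ph <- phenotypes[use, , drop = FALSE]
  n <- nrow(ph)
  if (n <= j + 1) stop("more instruments than informative observations")
  design <- covariate_design(ph, covariates)
  y_r <- residualize(ph[[exposure]], design)
  g_r <- residualize(dosages[ph$id, instrument_ids, drop = FALSE], design)
  fit <- stats::lm.fit(cbind(1, g_r), y_r)
  r2 <- 1 - sum(fit$residuals^2) / sum((y_r - mean(y_r))^2)
  list(r2 = r2, f = f_statistic(r2, j, n), j = j, n = n)
}
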