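# End-to-end pipeline: exclusions -> CFT -> GWAS -> QC -> instrument
# selection -> MR sensitivity suite -> GRS -> PheWAS -> subset reruns.

#' Pipeline configuration
#'
#' Bundles the simulation block with every analysis threshold. Thresholds
#' default to the full-scale analysis values (genome-wide significance
#' 5e-8, SHBG filter 0.05, LD r-squared 0.01, F floor 10); desk-scale runs
#' override the significance threshold because synthetic cohorts are
#' small.
#'
#' @param sim A \code{\link{sim_config}}.
#' @param gws_p Genome-wide significance threshold for exposure hits.
#' @param shbg_p SHBG-association exclusion threshold.
#' @param r2_prune LD pruning r-squared threshold.
#' @param f_floor Instrument-strength F warning floor.
#' @param alpha_total Family-wise error rate before Bonferroni division.
#' @param scale Reporting scale in exposure units (0.1 nmol/L).
#' @param presso_nsim MR-PRESSO simulation count.
#' @param maf_min,hwe_p_min,info_min Variant QC thresholds.
#' @param run_phewas Run the GRS phenome scan stage.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(),
                            gws_p = 5e-8, shbg_p = 0.05, r2_prune = 0.01,
                            f_floor = 10, alpha_total = 0.05, scale = 0.1,
                            presso_nsim = 1000,
                            maf_min = 0.01, hwe_p_min = 1e-10,
                            info_min = 0.7,
                            run_phewas = TRUE) {
  stopifnot(gws_p > 0, gws_p < 1, shbg_p > 0, shbg_p < 1,
            r2_prune > 0, r2_prune <= 1, f_floor >= 0,
            alpha_total > 0, alpha_total < 1, scale > 0)
  structure(list(sim = sim, gws_p = gws_p, shbg_p = shbg_p,
                 r2_prune = r2_prune, f_floor = f_floor,
                 alpha_total = alpha_total, scale = scale,
                 presso_nsim = presso_nsim, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, info_min = info_min,
                 run_phewas = run_phewas),
            class = "pipeline_config")
}

#' Desk-scale demonstration pipeline configuration
#'
#' @param seed Cohort seed.
#' @param causal_or_per_0.1 True causal OR of the binary outcome per
#'   0.1 nmol/L FT.
#' @param ... Overrides for \code{\link{demo_config}}.
#' @return A \code{pipeline_config} with the significance threshold
#'   relaxed to 1e-4 for the small synthetic cohort.
#' @export
demo_pipeline_config <- function(seed = 1L, causal_or_per_0.1 = 1.5, ...) {
  pipeline_config(sim = demo_config(seed = seed,
                                    causal_or_per_0.1 = causal_or_per_0.1,
                                    ...),
                  gws_p = 1e-4)
}

#' Run the full one-sample MR pipeline on a synthetic cohort
#'
#' Executes every stage in order: cohort simulation; phenotype exclusions
#' and derived biomarkers (CFT winsorized at 4 SD, log SHBG); variant QC;
#' GWAS of CFT and of log SHBG; genome-wide hit selection; SHBG filtering;
#' LD pruning; instrument-strength check (F below the floor logs a
#' prominent weak-instrument warning but the run continues); per-outcome
#' MR with the full sensitivity suite and reporting rules; GRS
#' construction and calibration; phenome scan; and medication-exclusion
#' reruns. A manifest records seeds, counts at every stage, and the filter
#' partial order.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List of class \code{ft_pipeline}: cohort, phenotypes,
#'   qc, assoc (cft, log_shbg), hits, instruments, strength, mr_reports,
#'   mr_table, grs, phewas, subset_scans, manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config$sim)
  pheno <- prepare_phenotypes(cohort$phenotypes)
  covars <- default_covariates(pheno)

  qc <- variant_qc(cohort$dosages, cohort$variant_info,
                   maf_min = config$maf_min, hwe_p_min = config$hwe_p_min,
                   info_min = config$info_min)
  dos <- cohort$dosages[, qc$keep, drop = FALSE]
  vi <- cohort$variant_info[match(qc$keep, cohort$variant_info$id), ]

  cft_assoc <- gwas_scan(dos, pheno, "cft", covars, vi)
  shbg_assoc <- gwas_scan(dos, pheno, "log_shbg", covars, vi)
  lambda <- genomic_inflation(cft_assoc)

  hits <- cft_assoc[cft_assoc$p < config$gws_p, , drop = FALSE]
  clean <- shbg_filter(hits, shbg_assoc, config$shbg_p)
  instruments <- ld_prune(clean, dos, config$r2_prune)

  strength <- if (nrow(instruments) > 0)
    instrument_strength(dos, pheno, "cft", instruments$id, covars)
  else list(r2 = NA, f = NA, j = 0, n = nrow(pheno))
  if (!is.na(strength$f) && strength$f < config$f_floor)
    warning(sprintf(
      "WEAK INSTRUMENTS: joint F = %.2f is below the floor of %g; causal estimates may be biased",
      strength$f, config$f_floor))

  outcome_spec <- rbind(
    data.frame(name = config$sim$quantitative_outcomes,
               type = "quantitative", stringsAsFactors = FALSE),
    if (length(config$sim$binary_outcome_prevalences))
      data.frame(name = names(config$sim$binary_outcome_prevalences),
                 type = "binary", stringsAsFactors = FALSE))
  alpha_mr <- bonferroni_threshold(nrow(outcome_spec), config$alpha_total)

  mr_reports <- list()
  if (nrow(instruments) >= 1) {
    for (i in seq_len(nrow(outcome_spec))) {
      nm <- outcome_spec$name[i]
      oa <- gwas_scan(dos[, instruments$id, drop = FALSE], pheno, nm,
                      covars, vi[match(instruments$id, vi$id), ])
      ktype <- outcome_spec$type[i]
      kfrac <- if (ktype == "binary") mean(pheno[[nm]] == 1) else NA
      inst <- harmonize(instruments, oa, outcome = nm,
                        outcome_type = ktype, k = kfrac)
      mr_reports[[nm]] <- mr_report(inst, alpha_family = alpha_mr,
                                    scale = config$scale,
                                    n_sim = config$presso_nsim,
                                    seed = config$sim$seed + 100L)
    }
  }
  mr_table <- if (length(mr_reports)) mr_results_table(mr_reports) else NULL

  grs <- NULL; phewas <- NULL; subset_scans <- NULL
  if (config$run_phewas && nrow(instruments) >= 1) {
    # signed per-allele weights: equivalent to flipping each variant to
    # its exposure-increasing allele and using positive weights
    oriented <- instruments
    oriented$beta_exp <- oriented$beta
    grs <- build_grs(dos, oriented[, c("id", "beta_exp")], pheno,
                     exposure = "cft", covariates = covars)
    alpha_phewas <- bonferroni_threshold(nrow(outcome_spec),
                                         config$alpha_total)
    phewas <- phewas_scan(pheno, grs, outcome_spec, covars,
                          alpha_family = alpha_phewas,
                          scale = config$scale)
    subset_scans <- list(
      med_bp = subset_rerun(pheno, grs, outcome_spec, "med_bp", phewas,
                            covariates = covars,
                            alpha_family = alpha_phewas,
                            scale = config$scale),
      med_chol = subset_rerun(pheno, grs, outcome_spec, "med_chol",
                              phewas, covariates = covars,
                              alpha_family = alpha_phewas,
                              scale = config$scale))
  }

  manifest <- list(
    seed = config$sim$seed,
    package_version = as.character(utils::packageVersion("ftmr")),
    counts = c(n_simulated = config$sim$n_individuals,
               n_analyzed = nrow(pheno),
               n_variants = config$sim$n_variants,
               n_qc_pass = length(qc$keep),
               n_gws_hits = nrow(hits),
               n_shbg_clean = nrow(clean),
               n_instruments = nrow(instruments)),
    lambda = lambda,
    instrument_f = strength$f,
    instrument_r2 = strength$r2,
    thresholds = config[c("gws_p", "shbg_p", "r2_prune", "f_floor",
                          "alpha_total")],
    exclusions = attr(pheno, "exclusions"))
  structure(list(cohort = cohort, phenotypes = pheno, qc = qc,
                 assoc = list(cft = cft_assoc, log_shbg = shbg_assoc),
                 hits = hits, shbg_clean = clean,
                 instruments = instruments, strength = strength,
                 mr_reports = mr_reports, mr_table = mr_table,
                 grs = grs, phewas = phewas, subset_scans = subset_scans,
                 manifest = manifest),
            class = "ft_pipeline")
}

#' @export
print.ft_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<ft_pipeline>\n")
  cat(sprintf("  %s\n", paste(names(m$counts), m$counts, sep = " = ",
                              collapse = ", ")))
  cat(sprintf("  lambda = %.3f, instrument F = %.1f (R2 = %.4f)\n",
              m$lambda, m$instrument_f, m$instrument_r2))
  if (!is.null(x$mr_table)) {
    cat("  MR results (reported estimates):\n")
    print(x$mr_table, row.names = FALSE)
  }
  invisible(x)
}

#' Write the pipeline result bundle to a directory
#'
#' Emits per-stage artifacts: GWAS summary TSVs (columns CHR, POS, ID, EA,
#' OA, EAF, BETA, SE, P, N), the QC report, the instrument table, the MR
#' forest table, PheWAS results, and the JSON manifest.
#'
#' @param result An \code{ft_pipeline}.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_summary <- function(a) data.frame(
    CHR = a$chromosome, POS = a$position, ID = a$id,
    EA = a$effect_allele, OA = a$other_allele, EAF = a$eaf,
    BETA = a$beta, SE = a$se, P = a$p, N = a$n)
  paths <- character(0)
  wt <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(as_summary(result$assoc$cft), "gwas_cft.tsv")
  wt(as_summary(result$assoc$log_shbg), "gwas_log_shbg.tsv")
  wt(result$qc$report, "qc_report.tsv")
  wt(result$instruments, "instruments.tsv")
  if (!is.null(result$mr_table)) wt(result$mr_table, "mr_results.tsv")
  if (!is.null(result$phewas)) wt(result$phewas, "phewas_results.tsv")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
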