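#!/usr/bin/env Rscript
# Stage 3 — one-sample Mendelian randomization with the sensitivity suite.
#
# For each outcome: per-instrument outcome associations, harmonization,
# IVW estimation (binary outcomes converted from the linear-probability to
# the log-odds scale), MR-Egger with the intercept decision rule, MR-RAPS
# (Tukey loss, overdispersion), MR-PRESSO (global / outlier / distortion)
# and leave-one-out. Effects reported per 0.1 nmol/L of CFT; the true
# simulated OR for 'disease' is 1.5 per 0.1 nmol/L.

library(ftmr)

cohort <- readRDS("scratch/study_cohort.rds")
pheno <- prepare_phenotypes(cohort$phenotypes)
covars <- default_covariates(pheno)
instruments <- read.delim("results/02_instruments.tsv")

outcomes <- data.frame(name = c("quant_trait", "disease"),
                       type = c("quantitative", "binary"))
alpha <- bonferroni_threshold(nrow(outcomes))

reports <- list()
for (i in seq_len(nrow(outcomes))) {
  nm <- outcomes$name[i]
  oa <- gwas_scan(cohort$dosages[, instruments$id, drop = FALSE], pheno,
                  nm, covars)
  k <- if (outcomes$type[i] == "binary") mean(pheno[[nm]] == 1) else NA
  inst <- harmonize(instruments, oa, outcome = nm,
                    outcome_type = outcomes$type[i], k = k)
  reports[[nm]] <- mr_report(inst, alpha_family = alpha, scale = 0.1,
                             n_sim = 10000, seed = 20260927L)
}

tab <- mr_results_table(reports)
tab$or <- ifelse(tab$type == "binary", exp(tab$beta), NA)
tab$or_lo <- ifelse(tab$type == "binary", exp(tab$ci_lower), NA)
tab$or_hi <- ifelse(tab$type == "binary", exp(tab$ci_upper), NA)
write.table(tab, "results/03_mr_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

diag <- do.call(rbind, lapply(reports, function(r) data.frame(
  outcome = r$outcome,
  egger_intercept_p = r$estimates$egger$diagnostics$egger_intercept_p,
  raps_tau2 = r$estimates$raps$diagnostics$tau2,
  presso_global_p = r$estimates$presso$global_p,
  presso_outliers = length(r$estimates$presso$outlier_ids),
  loo_flagged = sum(r$estimates$loo$outside_full_ci))))
write.table(diag, "results/03_mr_diagnostics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (nm in names(reports)) print(reports[[nm]])
dis <- reports$disease$reported
cat(sprintf(
  "Disease: reported OR %.2f (%.2f to %.2f) per 0.1 nmol/L; truth 1.50.\n",
  exp(dis$beta), exp(dis$ci_lower), exp(dis$ci_upper)))
cat("Wrote results/03_mr_results.tsv, 03_mr_diagnostics.tsv\n")
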