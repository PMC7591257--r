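# Variant QC, GWAS scan, inflation, SHBG filter, LD pruning, instrument
# strength.

# Independent HWE oracle: direct counting of genotype configurations at
# tiny n using plain factorials.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  configs <- list()
  for (ab in 0:n) {
    aa <- (n_a - ab) / 2
    bb <- n - ab - aa
    if (aa >= 0 && bb >= 0 && aa == round(aa))
      configs[[length(configs) + 1]] <- c(aa, ab, bb)
  }
  probs <- vapply(configs, function(cfg)
    factorial(n) / (factorial(cfg[1]) * factorial(cfg[2]) *
                      factorial(cfg[3])) * 2^cfg[2], numeric(1))
  probs <- probs / sum(probs)
  obs <- which(vapply(configs, function(cfg) cfg[2] == n_ab, logical(1)))
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}

test_that("HWE exact test matches the enumeration oracle", {
  cases <- list(c(25, 50, 25), c(10, 5, 10), c(0, 20, 0), c(17, 3, 1),
                c(5, 0, 5), c(30, 10, 2))
  for (cs in cases)
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  # equilibrium counts are comfortably retained at the QC threshold
  expect_gt(hwe_exact_p(25, 50, 25), 1e-10)
})

test_that("variant QC assigns one primary reason per exclusion, by priority", {
  set.seed(40)
  n <- 400
  good <- rbinom(n, 2, 0.3)
  rare <- rbinom(n, 2, 0.004)          # MAF below 1%
  mono <- rep(0L, n)                   # monomorphic
  allhet <- rep(1L, n)                 # extreme HWE violation
  region_lowmaf <- rbinom(n, 2, 0.004) # in blacklist AND low MAF
  dos <- cbind(good = good, rare = rare, mono = mono, allhet = allhet,
               region = region_lowmaf)
  vi <- data.frame(id = colnames(dos),
                   chromosome = c(1, 1, 2, 2, 6),
                   position = c(1e6, 2e6, 1e6, 2e6, 30e6))
  qc <- variant_qc(dos, vi)
  rep <- qc$report
  expect_equal(qc$keep, "good")
  expect_equal(rep$reason[rep$id == "rare"], "MAF")
  expect_equal(rep$reason[rep$id == "mono"], "MAF")
  expect_equal(rep$reason[rep$id == "allhet"], "HWE")
  expect_equal(rep$reason[rep$id == "region"], "region")  # region > MAF
  expect_true(all(is.na(rep$reason) == rep$pass))
  # info filter applies when scores are provided
  qc2 <- variant_qc(dos[, "good", drop = FALSE], vi[1, ],
                    info = c(good = 0.5))
  expect_equal(qc2$report$reason, "info")
})

test_that("gwas_scan equals per-variant lm on small instances", {
  set.seed(41)
  n <- 200
  ph <- data.frame(id = 1:n, age = runif(n, 40, 70),
                   sexless_cov = rnorm(n))
  dos <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.4),
               v3 = rbinom(n, 2, 0.2))
  ph$y <- 0.3 * dos[, "v1"] + 0.1 * ph$age + rnorm(n)
  res <- gwas_scan(dos, ph, "y", covariates = c("age", "sexless_cov"))
  for (v in colnames(dos)) {
    fit <- summary(lm(ph$y ~ dos[, v] + ph$age + ph$sexless_cov))
    co <- fit$coefficients[2, ]
    row <- res[res$id == v, ]
    expect_equal(row$beta, unname(co["Estimate"]), tolerance = 1e-10)
    expect_equal(row$se, unname(co["Std. Error"]), tolerance = 1e-10)
    expect_equal(row$p, unname(co[4]), tolerance = 1e-8)
  }
})

test_that("noise-free trait proportional to dosage is fit exactly", {
  set.seed(42)
  n <- 100
  dos <- cbind(v1 = rbinom(n, 2, 0.4))
  ph <- data.frame(id = 1:n, y = 2 * dos[, 1])
  res <- gwas_scan(dos, ph, "y", covariates = character(0))
  expect_equal(res$beta, 2, tolerance = 1e-12)
  expect_lt(res$p, 1e-200)
})

test_that("null scan is calibrated and zero-variance dosages are skipped", {
  set.seed(43)
  n <- 2000; m <- 200
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m,
                dimnames = list(NULL, sprintf("v%03d", 1:m)))
  dos[, 1] <- 1L   # zero variance
  ph <- data.frame(id = 1:n, y = rnorm(n), age = runif(n, 40, 70))
  res <- gwas_scan(dos, ph, "y", covariates = "age")
  expect_equal(nrow(res), m - 1)   # constant column skipped
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / (m - 1)))
  # injected effect is recovered within 3 SE
  b <- 0.25
  ph$y2 <- ph$y + b * dos[, 5]
  res2 <- gwas_scan(dos, ph, "y2", covariates = "age")
  row <- res2[res2$id == "v005", ]
  expect_lt(abs(row$beta - b), 3 * row$se)
})

test_that("genomic inflation matches its definition and null behaviour", {
  # chi-square exactly at the null median in every variant -> lambda = 1
  a <- data.frame(beta = rep(sqrt(0.4549364), 150), se = 1)
  expect_equal(genomic_inflation(a), 1.0, tolerance = 1e-12)
  # null simulation: lambda near 1 (median MC error ~0.03 at m = 10000)
  set.seed(44)
  n <- 500; m <- 10000
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m,
                dimnames = list(NULL, sprintf("v%04d", 1:m)))
  ph <- data.frame(id = 1:n, y = rnorm(n))
  res <- gwas_scan(dos, ph, "y", covariates = character(0))
  lam <- genomic_inflation(res)
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
  # strongly polygenic trait inflates the median test statistic
  beta_poly <- rnorm(m, 0, 0.05)
  ph$yp <- as.vector(dos %*% beta_poly) + rnorm(n)
  resp <- gwas_scan(dos, ph, "yp", covariates = character(0))
  expect_gt(genomic_inflation(resp), 1)
})

test_that("SHBG filter applies the threshold and demands matching scans", {
  hits <- data.frame(id = c("a", "b", "c"), p = c(1e-9, 1e-10, 1e-8))
  shbg <- data.frame(id = c("a", "b", "c"), p = c(0.04, 0.5, 0.06))
  out <- shbg_filter(hits, shbg, 0.05)
  expect_equal(out$id, c("b", "c"))   # p = 0.04 excluded, 0.5 and 0.06 kept
  expect_error(shbg_filter(data.frame(id = "zz", p = 1e-9), shbg),
               "missing")
})

test_that("SHBG-leaking variants are removed while FT signals survive", {
  # strong assay coupling makes SHBG genetics reach significance on
  # computed CFT; the filter must remove those variants and keep the
  # genuine FT-production signals
  cfg <- sim_config(n_individuals = 8000, n_variants = 120, ld_rho = 0,
                    n_ft_signals = 30, ft_variance_explained = 0.15,
                    n_shbg_signals = 15, shbg_variance_explained = 0.3,
                    shbg_assay_coupling = 0.25, missing_rate = 0,
                    n_pcs = 2, seed = 45)
  co <- simulate_cohort(cfg)
  ph <- prepare_phenotypes(co$phenotypes)
  covs <- default_covariates(ph)
  cft_a <- gwas_scan(co$dosages, ph, "cft", covs, co$variant_info)
  shbg_a <- gwas_scan(co$dosages, ph, "log_shbg", covs, co$variant_info)
  hits <- cft_a[cft_a$p < 1e-4, ]
  shbg_sig_hit <- intersect(hits$id, co$sim_log$shbg_signal_ids)
  expect_gt(length(shbg_sig_hit), 0)  # leakage did produce CFT hits
  clean <- shbg_filter(hits, shbg_a, 0.05)
  expect_equal(intersect(clean$id, co$sim_log$shbg_signal_ids),
               character(0))
  ft_hits <- intersect(hits$id, co$sim_log$ft_signal_ids)
  retained <- intersect(clean$id, co$sim_log$ft_signal_ids)
  expect_gte(length(retained) / length(ft_hits), 0.85)
})

test_that("LD pruning is greedy on p and verified by exhaustive pairwise check", {
  set.seed(46)
  n <- 500
  base <- rbinom(n, 2, 0.3)
  dos <- cbind(lead = base, proxy = base,   # r2 = 1 pair
               free = rbinom(n, 2, 0.3))
  hits <- data.frame(id = c("lead", "proxy", "free"),
                     chromosome = c(1, 1, 2), position = c(1, 2, 1),
                     p = c(1e-10, 1e-8, 1e-6))
  pruned <- ld_prune(hits, dos, 0.01)
  expect_equal(sort(pruned$id), c("free", "lead"))
  # mutually independent variants are all kept
  cfg <- sim_config(n_individuals = 2000, n_variants = 20, ld_rho = 0,
                    n_ft_signals = 2, n_shbg_signals = 0, seed = 47)
  g <- simulate_genotypes(cfg)
  hh <- data.frame(id = g$variant_info$id,
                   chromosome = g$variant_info$chromosome,
                   position = g$variant_info$position,
                   p = runif(20))
  kept <- ld_prune(hh, g$dosages, 0.05)
  expect_equal(nrow(kept), 20)
  # structured LD: every retained pair satisfies the invariant
  cfg2 <- sim_config(n_individuals = 2000, n_variants = 20,
                     ld_block_size = 5, ld_rho = 0.6,
                     n_ft_signals = 2, n_shbg_signals = 0, seed = 48)
  g2 <- simulate_genotypes(cfg2)
  hh2 <- data.frame(id = g2$variant_info$id,
                    chromosome = g2$variant_info$chromosome,
                    position = g2$variant_info$position,
                    p = runif(20))
  kept2 <- ld_prune(hh2, g2$dosages, 0.1)
  r2 <- cor(g2$dosages[, kept2$id])^2
  expect_true(all(r2[upper.tri(r2)] < 0.1))
  # and every discarded variant is correlated with some kept one
  dropped <- setdiff(hh2$id, kept2$id)
  for (d in dropped)
    expect_true(any(cor(g2$dosages[, d], g2$dosages[, kept2$id])^2 >= 0.1))
})

test_that("instrument-strength arithmetic and joint regression", {
  expect_equal(f_statistic(0.5, 1, 102), 100)
  expect_equal(f_statistic(0, 5, 1000), 0)
  co <- simulate_cohort(small_config(seed = 49))
  ph <- prepare_phenotypes(co$phenotypes)
  s <- instrument_strength(co$dosages, ph, "cft",
                           co$sim_log$ft_signal_ids)
  # 8 signals explaining ~20% of latent FT variance, diluted by assay
  # noise on measured CFT
  expect_gt(s$r2, 0.08); expect_lt(s$r2, 0.35)
  expect_equal(s$f, f_statistic(s$r2, s$j, s$n))
})
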