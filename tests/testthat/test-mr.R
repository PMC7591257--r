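# MR estimators and sensitivity suite.

test_that("harmonization orients exposure effects positive and flags mismatches", {
  ea <- data.frame(id = c("a", "b"), effect_allele = c("A", "C"),
                   other_allele = c("G", "T"),
                   beta = c(-0.2, 0.3), se = c(0.02, 0.02))
  oa <- data.frame(id = c("b", "a"), effect_allele = c("C", "A"),
                   other_allele = c("T", "G"),
                   beta = c(0.5, 0.1), se = c(0.05, 0.05))
  inst <- harmonize(ea, oa)
  expect_equal(inst$beta_exp, c(0.2, 0.3))
  expect_equal(inst$beta_out, c(-0.1, 0.5))   # sign flipped with exposure
  # already-positive effects pass through unchanged
  ea2 <- ea; ea2$beta <- abs(ea2$beta)
  inst2 <- harmonize(ea2, oa)
  expect_equal(inst2$beta_out, c(0.1, 0.5))
  # Wald ratio is invariant under the orientation flip
  expect_equal(inst$beta_out[1] / inst$beta_exp[1],
               0.1 / -0.2)
  oa_bad <- oa; oa_bad$effect_allele <- c("T", "A")
  expect_error(harmonize(ea, oa_bad), "allele mismatch")
  expect_error(harmonize(ea, oa[1, ]), "missing")
})

test_that("Wald ratio arithmetic and its delta-method standard error", {
  w <- wald_ratio(0.2, 0.01, 0.4, 0.05)
  expect_equal(w$beta, 2.0)
  expect_equal(w$se, 0.05 / 0.2)
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.05)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.4, 0.05))
  # Monte-Carlo check of the first-order se at small relative error
  set.seed(50)
  g <- 0.2; G <- 0.4; sg <- 0.02; sG <- 0.02
  ratios <- (G + rnorm(5e4, 0, sG)) / (g + rnorm(5e4, 0, sg))
  # delta-method se including the exposure term, vs sd of simulated ratios
  se_delta <- sqrt(sG^2 / g^2 + G^2 * sg^2 / g^4)
  expect_lt(abs(sd(ratios) - se_delta) / se_delta, 0.1)
})

test_that("IVW reduces to the Wald ratio at J = 1 and matches the hand-computed J = 2 case", {
  one <- instrument_set("a", 0.2, 0.01, 0.4, 0.05)
  expect_equal(mr_ivw(one)$beta, wald_ratio(0.2, 0.01, 0.4, 0.05)$beta)
  expect_equal(mr_ivw(one)$se, wald_ratio(0.2, 0.01, 0.4, 0.05)$se)
  # (gamma, se_out, Gamma) = (1,1,2) and (1,1,4): equal weights -> beta = 3
  two <- instrument_set(c("a", "b"), c(1, 1), c(0.01, 0.01),
                        c(2, 4), c(1, 1))
  expect_equal(mr_ivw(two)$beta, 3.0)
  # per-0.1 reporting scale multiplies the estimate
  expect_equal(mr_ivw(two, scale = 0.1)$beta, 0.3)
})

test_that("IVW estimates are scale- and orientation-invariant as required", {
  set.seed(51)
  inst <- sim_instruments(j = 30, beta = 0.4, se_exp = 0.01)
  base_ivw <- mr_ivw(inst)$beta
  base_egger <- mr_egger(inst)$beta
  base_raps <- mr_raps(inst)$beta
  # multiplying all outcome effects and ses by c scales every estimate by c
  sc <- inst; sc$beta_out <- sc$beta_out * 3; sc$se_out <- sc$se_out * 3
  expect_equal(mr_ivw(sc)$beta, 3 * base_ivw, tolerance = 1e-10)
  expect_equal(mr_egger(sc)$beta, 3 * base_egger, tolerance = 1e-10)
  expect_equal(mr_raps(sc)$beta, 3 * base_raps, tolerance = 1e-6)
  # flipping an instrument's alleles (both signs) changes nothing after
  # re-orientation through harmonize
  ea <- data.frame(id = inst$id, effect_allele = "A", other_allele = "G",
                   beta = inst$beta_exp, se = inst$se_exp)
  oa <- data.frame(id = inst$id, effect_allele = "A", other_allele = "G",
                   beta = inst$beta_out, se = inst$se_out)
  ea_f <- ea; oa_f <- oa
  ea_f$beta[4] <- -ea_f$beta[4]; oa_f$beta[4] <- -oa_f$beta[4]
  h1 <- harmonize(ea, oa); h2 <- harmonize(ea_f, oa_f)
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h1)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$beta, mr_egger(h1)$beta, tolerance = 1e-12)
})

test_that("log-odds conversion formula and identity cases", {
  conv <- logodds_convert(0.1, 0.02, 0.5)
  expect_equal(conv$log_or, 0.4)
  expect_equal(conv$se, 0.08)
  expect_equal(logodds_convert(0, 0.02, 0.3)$or, 1)
  expect_error(logodds_convert(0.1, 0.02, 1))
  expect_error(logodds_convert(0.1, 0.02, 0))
})

test_that("Egger regression interpolates exact linear data and reports the intercept", {
  # three points exactly on Gamma = 0.05 + 0.7 * gamma
  g <- c(0.1, 0.2, 0.3)
  inst <- instrument_set(c("a", "b", "c"), g, rep(0.01, 3),
                        0.05 + 0.7 * g, rep(0.02, 3))
  e <- mr_egger(inst)
  expect_equal(e$beta, 0.7, tolerance = 1e-10)
  expect_equal(e$diagnostics$egger_intercept, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(inst[1:2, ]))
  neg <- inst; neg$beta_exp[1] <- -0.1
  expect_error(mr_egger(neg), "oriented")
})

test_that("RAPS equals IVW in the l2 / no-overdispersion / error-free-exposure limit", {
  set.seed(52)
  for (r in 1:5) {
    inst <- sim_instruments(j = 25, beta = runif(1, -1, 1), se_exp = 1e-8)
    ivw <- mr_ivw(inst)$beta
    raps <- mr_raps(inst, overdispersion = FALSE, loss = "l2")$beta
    expect_equal(raps, ivw, tolerance = 1e-6)
  }
})

test_that("RAPS overdispersion is always non-negative and detected when present", {
  set.seed(53)
  taus <- vapply(1:10, function(r) {
    inst <- sim_instruments(j = 40, beta = 0.5,
                            direct_sd = if (r > 5) 0.05 else 0)
    mr_raps(inst)$diagnostics$tau2
  }, numeric(1))
  expect_true(all(taus >= 0))
  # balanced pleiotropy (sd 0.05 vs se 0.02) inflates tau2
  expect_gt(mean(taus[6:10]), mean(taus[1:5]))
})

test_that("RAPS with Tukey loss resists outlier contamination", {
  set.seed(54)
  wins <- 0
  for (r in 1:40) {
    inst <- sim_instruments(j = 30, beta = 0.5, n_outliers = 3,
                            outlier_size = 0.3)
    err_raps <- abs(mr_raps(inst)$beta - 0.5)
    err_ivw <- abs(mr_ivw(inst)$beta - 0.5)
    wins <- wins + (err_raps < err_ivw)
  }
  expect_gt(wins / 40, 0.8)
})

test_that("PRESSO flags a constructed outlier and its correction equals IVW on survivors", {
  set.seed(55)
  inst <- sim_instruments(j = 30, beta = 0.5, n_outliers = 1,
                          outlier_size = 10 * 0.02)
  pres <- mr_presso(inst, n_sim = 1000, seed = 99)
  expect_lt(pres$global_p, 0.05)
  expect_true("s001" %in% pres$outlier_ids)
  survivors <- inst[!inst$id %in% pres$outlier_ids, ]
  manual <- mr_ivw(instrument_set(survivors$id, survivors$beta_exp,
                                  survivors$se_exp, survivors$beta_out,
                                  survivors$se_out))
  expect_equal(pres$corrected$beta, manual$beta, tolerance = 1e-12)
  expect_equal(pres$corrected$se, manual$se, tolerance = 1e-12)
  expect_true(!is.null(pres$distortion_p))
  expect_error(mr_presso(inst[1:3, ]), "at least 4")
})

test_that("PRESSO is reproducible under its seed", {
  set.seed(56)
  inst <- sim_instruments(j = 20, beta = 0.3)
  p1 <- mr_presso(inst, n_sim = 500, seed = 7)
  p2 <- mr_presso(inst, n_sim = 500, seed = 7)
  expect_identical(p1$global_p, p2$global_p)
  expect_identical(p1$outlier_p, p2$outlier_p)
})

test_that("leave-one-out reduces to the complementary Wald ratio at J = 2", {
  inst <- instrument_set(c("a", "b"), c(0.2, 0.25), c(0.01, 0.01),
                        c(0.1, 0.2), c(0.02, 0.03))
  loo <- leave_one_out(inst)
  expect_equal(loo$beta[1], wald_ratio(0.25, 0.01, 0.2, 0.03)$beta)
  expect_equal(loo$beta[2], wald_ratio(0.2, 0.01, 0.1, 0.02)$beta)
  # identical instruments: every row equals the full estimate
  same <- instrument_set(letters[1:5], rep(0.2, 5), rep(0.01, 5),
                        rep(0.1, 5), rep(0.02, 5))
  loo2 <- leave_one_out(same)
  expect_true(all(abs(loo2$beta - mr_ivw(same)$beta) < 1e-12))
  expect_true(all(!loo2$outside_full_ci))
})

test_that("leave-one-out isolates a single dominant outlier", {
  # nine consistent low-weight instruments plus one high-precision
  # outlier that drags the pooled estimate; only its exclusion row
  # escapes the full-set confidence interval
  inst <- instrument_set(sprintf("i%02d", 1:10),
                        rep(1, 10), rep(0.01, 10),
                        c(rep(1, 9), 1.2),
                        c(rep(0.1, 9), 0.01))
  loo <- leave_one_out(inst)
  expect_true(loo$outside_full_ci[10])
  expect_true(all(!loo$outside_full_ci[1:9]))
})

test_that("reporting rules select the estimator the diagnostics dictate", {
  set.seed(57)
  # clean data: IVW reported, no correction
  clean <- sim_instruments(j = 20, beta = 0.5)
  rep_clean <- mr_report(clean, alpha_family = 0.05 / 22, scale = 0.1,
                         n_sim = 500)
  expect_equal(rep_clean$reported$method, "IVW")
  expect_gt(rep_clean$estimates$presso$global_p, 0.05)
  # strong directional pleiotropy: Egger substituted
  g <- runif(40, 0.05, 0.15)
  dir <- instrument_set(sprintf("d%02d", 1:40), g, rep(1e-8, 40),
                        0.1 + 0.5 * g + rnorm(40, 0, 0.005),
                        rep(0.02, 40))
  rep_dir <- mr_report(dir, n_sim = 2000)
  expect_lt(rep_dir$estimates$egger$diagnostics$egger_intercept_p, 0.05)
  expect_match(rep_dir$reported$method, "MR-Egger")
  # both triggers: Egger refit on the outlier-corrected set
  both <- dir
  both$beta_out[1] <- both$beta_out[1] + 0.5
  rep_both <- mr_report(both, n_sim = 2000)
  expect_match(rep_both$reported$method, "MR-Egger \\(outlier-corrected\\)")
  pres <- rep_both$estimates$presso
  expect_lt(pres$global_p, 0.05)
  surv <- both[!both$id %in% pres$outlier_ids, ]
  manual <- mr_egger(instrument_set(surv$id, surv$beta_exp, surv$se_exp,
                                    surv$beta_out, surv$se_out),
                     scale = 0.1)
  expect_equal(rep_both$reported$beta, manual$beta, tolerance = 1e-10)
})

test_that("binary outcomes are converted to log-odds before estimation", {
  set.seed(58)
  inst <- sim_instruments(j = 10, beta = 0.02, outcome_type = "binary",
                          k = 0.25)
  rep_bin <- mr_report(inst, run_presso = FALSE, run_raps = FALSE,
                       run_egger = FALSE)
  manual <- mr_ivw(inst_to_logodds(inst), scale = 0.1)
  expect_equal(rep_bin$reported$beta, manual$beta)
  # conversion factor 1/(k(1-k)) propagates linearly through IVW
  expect_equal(manual$beta, mr_ivw(inst, scale = 0.1)$beta / (0.25 * 0.75))
})
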