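test_that("Friedewald LDL follows the formula and validity domain", {
  expect_equal(friedewald_ldl(200, 50, 150), 120)
  expect_equal(friedewald_ldl(100, 100, 0), 0)
  expect_equal(friedewald_ldl(180, 45, 100), 115)
  expect_error(friedewald_ldl(300, 40, 400), "Friedewald invalid")
})

test_that("single-exam linear fits equal the closed-form OLS oracle", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 600,
                    n_exams_range = c(1, 1), seed = 12)
  co <- simulate_one(cfg)
  res_ind <- fit_linear_longitudinal(co$pheno, co$geno, "TG", "rs1051921",
                                     working_corr = "independence")
  dat <- co$pheno
  dat$g <- co$geno$dosages[match(dat$person_id, co$geno$person_ids),
                           "rs1051921"]
  ols <- lm(TG ~ g + sex + birth_year + site + exam_age, data = dat)
  expect_equal(res_ind$beta, unname(coef(ols)["g"]), tolerance = 1e-8)
  # with one exam per person the working correlation is irrelevant
  res_exch <- fit_linear_longitudinal(co$pheno, co$geno, "TG",
                                      "rs1051921",
                                      working_corr = "exchangeable")
  expect_equal(res_ind$beta, res_exch$beta, tolerance = 1e-8)
  # cluster sandwich SE agrees with the sandwich-package oracle
  skip_if_not_installed("sandwich")
  V <- sandwich::vcovCL(ols, cluster = dat$family_id, type = "HC0",
                        cadjust = FALSE)
  expect_equal(res_ind$se, sqrt(V["g", "g"]), tolerance = 1e-8)
})

test_that("longitudinal fit recovers an injected additive TG effect", {
  snps <- c("s1", "s2")
  betas <- matrix(0, 2, 4, dimnames = list(snps,
                                           c("TG", "HDL_C", "LDL_C", "TC")))
  betas["s1", "TG"] <- -8.9
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 20000,
                    snp_ids = snps, mafs = c(0.2, 0.15),
                    ld_targets = diag(1, 2),
                    snp_lipid_betas = betas, event_snp = "s1", seed = 77)
  co <- simulate_one(cfg)
  res <- fit_linear_longitudinal(co$pheno, co$geno, "TG", "s1")
  expect_lt(abs(res$beta - (-8.9)), 3 * res$se)
  # null SNP shows no association
  res0 <- fit_linear_longitudinal(co$pheno, co$geno, "TG", "s2")
  expect_lt(abs(res0$beta / res0$se), 3.5)
  # exchangeable working correlation leaves the estimate consistent
  res_ex <- fit_linear_longitudinal(co$pheno, co$geno, "TG", "s1",
                                    working_corr = "exchangeable")
  expect_lt(abs(res_ex$beta - (-8.9)), 3 * res_ex$se)
  expect_gt(attr(res_ex, "rho"), 0)  # repeated exams are correlated
})

test_that("degenerate designs are rejected with informative errors", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 120, seed = 2)
  co <- simulate_one(cfg)
  ph <- co$pheno
  ph$dup <- ph$exam_age
  expect_error(fit_linear_longitudinal(ph, co$geno, "TG", "rs1051921",
                                       covariates = c("exam_age", "dup")),
               "collinear")
  ph1 <- ph[ph$family_id == ph$family_id[1], ]
  expect_error(fit_linear_longitudinal(ph1, co$geno, "TG", "rs1051921"),
               "clusters")
  expect_error(fit_linear_longitudinal(ph, co$geno, "TG", "rs1051921",
                                       adjust_for = "TG"),
               "outcome")
})

test_that("Cox fit maximises the Efron partial likelihood (oracle suite)", {
  set.seed(101)
  for (i in 1:40) {
    d <- random_cox_data(sample(10:30, 1))
    fit <- survival::coxph(survival::Surv(time, status) ~ x, data = d,
                           ties = "efron")
    bhat <- unname(coef(fit))
    opt <- optimize(efron_loglik, c(-6, 6), time = d$time,
                    status = d$status, x = d$x, maximum = TRUE)
    expect_lt(abs(efron_loglik(bhat, d$time, d$status, d$x) -
                    opt$objective), 1e-6)
  }
})

test_that("fit_cox recovers an injected carrier log-hazard", {
  cfg <- recovery_config(10000, beta1 = 0, theta1 = 0.18, theta2 = 0,
                         lambda0 = 0.003, seed = 55)
  co <- simulate_one(cfg)
  res <- fit_cox(co$pheno, co$geno, "AD", "rs17145750", coding = "carrier")
  expect_lt(abs(res$beta - 0.18), 3 * res$se)
  expect_gt(res$n_events, 0)
  # the fitted model matches the oracle maximum on its own likelihood
  per <- person_level(co$pheno)
  per$g <- code_genotype(
    co$geno$dosages[match(per$person_id, co$geno$person_ids),
                    "rs17145750"], "carrier")
  fit1 <- survival::coxph(survival::Surv(event_age_AD, event_ind_AD) ~ g,
                          data = per, ties = "efron")
  opt <- optimize(efron_loglik, c(-4, 4), time = per$event_age_AD,
                  status = per$event_ind_AD, x = per$g, maximum = TRUE)
  expect_lt(abs(efron_loglik(unname(coef(fit1)), per$event_age_AD,
                             per$event_ind_AD, per$g) - opt$objective),
            1e-6)
})

test_that("fit_cox rejects impossible inputs", {
  cfg <- recovery_config(300, lambda0 = 0.003, seed = 14)
  co <- simulate_one(cfg)
  ph <- co$pheno
  ph$event_ind_AD <- 0L
  expect_error(fit_cox(ph, co$geno, "AD", "rs17145750"), "no events")
  ph2 <- co$pheno
  ph2$sex <- 1L
  expect_error(fit_cox(ph2, co$geno, "AD", "rs17145750",
                       covariates = c("sex", "birth_year")),
               "constant|singular")
})

test_that("conditional attenuation reproduces the printed percentages", {
  expect_equal(conditional_attenuation(0.98, 0.47)$percent, 52)
  expect_equal(conditional_attenuation(-8.90, -6.89)$percent, 23)
  expect_equal(conditional_attenuation(3.73, 1.76)$percent, 53)
  expect_equal(conditional_attenuation(-0.91, -0.65)$percent, 29)
  expect_equal(conditional_attenuation(5, 5)$percent, 0)
  expect_equal(conditional_attenuation(2, 0)$percent, 100)
  # sign-flip invariance and magnification
  expect_equal(conditional_attenuation(-2, 1)$percent,
               conditional_attenuation(2, -1)$percent)
  expect_lt(conditional_attenuation(1, 1.5)$percent_raw, 0)
  expect_error(conditional_attenuation(0, 1), "nonzero")
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 28), 3), 1.79e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("mediator-selection rule keeps the last pre-onset complete exam", {
  ph <- data.frame(
    person_id = c("a", "a", "a", "b", "b", "c"),
    family_id = "f1", cohort_id = "c1", sex = 0L, birth_year = 1940L,
    site = "siteA", exam_no = c(1:3, 1:2, 1),
    exam_age = c(45, 50, 55, 46, 58, 50),
    TG = c(100, 110, 120, 90, NA, 80),
    HDL_C = 50, LDL_C = 120, TC = 190,
    event_age_AD = c(52, 52, 52, 80, 80, 70),
    event_ind_AD = c(1L, 1L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  per <- person_level(ph)
  # person a: exam at 55 is post-onset, so the age-50 exam wins
  expect_equal(per$exam_age[per$person_id == "a"], 50)
  # person b: exam at 58 lacks TG, so the age-46 exam wins
  expect_equal(per$exam_age[per$person_id == "b"], 46)
  expect_equal(per$exam_age[per$person_id == "c"], 50)
})
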