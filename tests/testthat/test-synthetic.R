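test_that("copula genotype simulation hits MAF and LD targets", {
  mafs <- c(a = 0.2, b = 0.2)
  gm0 <- simulate_genotypes(10000, mafs, ld_targets = NULL, seed = 1)
  # independence: realized r2 essentially zero
  expect_lt(ld_r2(gm0$dosages[, 1], gm0$dosages[, 2]), 0.01)
  for (j in 1:2) {
    se <- sqrt(0.2 * 0.8 / (2 * 10000))
    expect_lt(abs(minor_allele_freq(gm0$dosages[, j]) - 0.2), 3 * se)
  }
  # strong-LD pair: realized r2 within the calibration band
  ld <- matrix(c(1, 0.77, 0.77, 1), 2, 2)
  gm1 <- simulate_genotypes(10000, c(a = 0.12, b = 0.12),
                            ld_targets = ld, seed = 2)
  r2 <- ld_r2(gm1$dosages[, 1], gm1$dosages[, 2])
  expect_gt(r2, 0.72); expect_lt(r2, 0.82)
  # determinism
  gm2 <- simulate_genotypes(500, mafs, seed = 99)
  gm3 <- simulate_genotypes(500, mafs, seed = 99)
  expect_identical(gm2$dosages, gm3$dosages)
  # infeasible targets are refused with the offending pair named
  expect_error(simulate_genotypes(100, c(x = 0.4, y = 0.05),
                                  matrix(c(1, .9, .9, 1), 2, 2), seed = 1),
               "unattainable|infeasible")
})

test_that("lipid simulation reproduces the target correlation structure", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 10000,
                    snp_lipid_betas = matrix(0, 4, 4), seed = 31)
  co <- simulate_one(cfg)
  ph <- co$pheno
  expect_lt(abs(cor(ph$TG, ph$HDL_C) - (-0.42)), 0.05)
  expect_lt(abs(cor(ph$LDL_C, ph$TC) - 0.95), 0.05)
  expect_true(all(ph[, c("TG", "HDL_C", "LDL_C", "TC")] > 0))
  # exam ages strictly increasing within person
  o <- order(ph$person_id, ph$exam_no)
  same <- ph$person_id[o][-1] == ph$person_id[o][-nrow(ph)]
  expect_true(all(diff(ph$exam_age[o])[same] > 0))
})

test_that("zero-noise lipids equal their configured means exactly", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 50,
                    snp_lipid_betas = matrix(0, 4, 4),
                    lipid_sds = c(TG = 0, HDL_C = 0, LDL_C = 0, TC = 0),
                    lipid_sex_effects = c(TG = 0, HDL_C = 0, LDL_C = 0,
                                          TC = 0),
                    lipid_age_slopes = c(TG = 0, HDL_C = 0, LDL_C = 0,
                                         TC = 0),
                    cohort_shift_frac = 0, seed = 5)
  ph <- simulate_one(cfg)$pheno
  expect_equal(unique(ph$TG), 120)
  expect_equal(unique(ph$HDL_C), 52)
  expect_equal(unique(ph$LDL_C), 130)
  expect_equal(unique(ph$TC), 200)
})

test_that("Friedewald flag makes TC internally consistent", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 500,
                    friedewald_ldl = TRUE, seed = 8)
  ph <- simulate_one(cfg)$pheno
  expect_equal(ph$TC, ph$LDL_C + ph$HDL_C + ph$TG / 5, tolerance = 1e-10)
  ok <- ph$TG < 400
  expect_equal(friedewald_ldl(ph$TC[ok], ph$HDL_C[ok], ph$TG[ok]),
               ph$LDL_C[ok], tolerance = 1e-10)
})

test_that("event simulation respects the proportional-hazards design", {
  # null model: Cox recovers beta ~ 0
  cfg0 <- recovery_config(10000, beta1 = 0, theta1 = 0, theta2 = 0,
                          lambda0 = 0.003, seed = 21)
  co <- simulate_one(cfg0)
  r <- fit_cox(co$pheno, co$geno, "AD", "rs17145750", coding = "carrier")
  expect_lt(abs(r$beta / r$se), 3)
  # case fraction lands near the analytic target for the baseline rate:
  # with hazard h past 60 and uniform censoring to 95,
  # P(event) = 1 - (1 - exp(-35 h)) / (35 h)
  h <- 0.0038
  target <- 1 - (1 - exp(-35 * h)) / (35 * h)
  cfgc <- sim_config(n_cohorts = 1, n_per_cohort = 20000, seed = 33)
  per <- person_level(simulate_one(cfgc)$pheno)
  expect_lt(abs(mean(per$event_ind_CHD) - target), 0.01)
  # event/censor age never precedes the mediator exam
  expect_true(all(per$event_age_CHD >= per$exam_age - 1e-8))
  expect_true(all(per$event_age_AD >= per$exam_age - 1e-8))
})

test_that("multi-cohort simulation is reproducible and independent", {
  cfg <- tiny_config(seed = 17)
  mc1 <- simulate_multicohort(cfg)
  mc2 <- simulate_multicohort(cfg)
  expect_identical(mc1[[1]]$pheno, mc2[[1]]$pheno)
  expect_identical(mc1[[2]]$geno$dosages, mc2[[2]]$geno$dosages)
  expect_length(mc1, 2)
  # disjoint person ids across cohorts
  expect_length(intersect(mc1[[1]]$pheno$person_id,
                          mc1[[2]]$pheno$person_id), 0)
  # a different seed moves the lipid values
  mc3 <- simulate_multicohort(tiny_config(seed = 18))
  expect_false(identical(mc1[[1]]$pheno$TG, mc3[[1]]$pheno$TG))
  # seven-cohort structure as in the reference design
  cfg7 <- sim_config(n_cohorts = 7, n_per_cohort = 40, seed = 3)
  mc7 <- simulate_multicohort(cfg7)
  expect_length(mc7, 7)
  ids <- unlist(lapply(mc7, function(co) co$pheno$person_id))
  expect_equal(anyDuplicated(unique(ids)), 0L)
  expect_error(sim_config(n_cohorts = 0), "n_cohorts")
})
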