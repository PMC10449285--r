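make_person_data <- function(cfg) {
  co <- simulate_one(cfg)
  per <- person_level(co$pheno)
  per$A <- code_genotype(
    co$geno$dosages[match(per$person_id, co$geno$person_ids),
                    cfg$event_snp], "carrier")
  per
}

test_that("mediator model recovers injected exposure effects", {
  cfg <- recovery_config(10000, beta1 = -8.9, seed = 41)
  per <- make_person_data(cfg)
  mfit <- fit_mediator_model(per, "TG", "A")
  expect_lt(abs(mfit$beta1 - (-8.9)), 3 * mfit$se_beta1)
  expect_gt(mfit$sigma, 0)
  # constant exposure cannot be fit
  per0 <- per; per0$A <- 1L
  expect_error(fit_mediator_model(per0, "TG", "A"), "collinear")
})

test_that("mediator model interpolates zero-noise data exactly", {
  set.seed(2)
  n <- 200
  d <- data.frame(A = rbinom(n, 1, 0.4), sex = rbinom(n, 1, 0.5),
                  birth_year = sample(1930:1950, n, TRUE),
                  site = "s1")
  d$TG <- 120 - 6 * d$A + 3 * d$sex + 0.1 * (d$birth_year - 1940)
  mfit <- fit_mediator_model(d, "TG", "A",
                             covariates = c("sex", "birth_year"))
  expect_equal(mfit$beta1, -6, tolerance = 1e-10)
  expect_equal(unname(mfit$gamma["sex"]), 3, tolerance = 1e-10)
  expect_lt(mfit$sigma, 1e-8)
})

test_that("product decomposition is exactly additive with product IE", {
  mfit <- structure(list(beta1 = -6), class = "mediator_fit")
  # theta2 = 0: no mediator->outcome path
  of0 <- structure(list(theta1 = 0.2, theta2 = 0, n = 10L,
                        n_events = 2L), class = "outcome_fit")
  r0 <- decompose_product(mfit, of0)
  expect_equal(r0$beta_IE, 0)
  expect_equal(r0$beta_TE, r0$beta_DE)
  # beta1 = 0: no exposure->mediator path
  m0 <- structure(list(beta1 = 0), class = "mediator_fit")
  of <- structure(list(theta1 = 0.1, theta2 = -0.0025, n = 10L,
                       n_events = 2L), class = "outcome_fit")
  expect_equal(decompose_product(m0, of)$beta_IE, 0)
  # the worked product: beta1 = -6, theta2 = -0.0025 -> IE = 0.015
  r <- decompose_product(mfit, of)
  expect_equal(r$beta_IE, 0.015, tolerance = 1e-12)
  expect_equal(r$beta_TE, r$beta_DE + r$beta_IE, tolerance = 1e-12)
  # sign logic across a grid
  for (b1 in c(-6, 2)) for (t2 in c(-0.01, 0.004)) {
    rr <- decompose_product(structure(list(beta1 = b1),
                                      class = "mediator_fit"),
                            structure(list(theta1 = 0, theta2 = t2,
                                           n = 1L, n_events = 1L),
                                      class = "outcome_fit"))
    expect_equal(sign(rr$beta_IE), sign(b1) * sign(t2))
  }
})

test_that("proportion mediated matches the worked ratio and flags", {
  expect_equal(proportion_mediated(0.015, 0.18)$percent, 8)
  expect_equal(proportion_mediated(0.5, 0.5)$percent, 100)
  expect_equal(proportion_mediated(0, 0.3)$percent, 0)
  expect_error(proportion_mediated(0.1, 0), "nonzero")
  expect_false(proportion_mediated(0.1, 0.5)$inconsistent)
  expect_true(proportion_mediated(0.3, 0.1)$inconsistent)
})

test_that("weighted natural-effect estimator behaves at the null and near
           the product estimator on rare outcomes", {
  # null: both effects within 3 SE-ish of zero (checked via bootstrap-free
  # point estimates against the known truth scale)
  cfg0 <- recovery_config(8000, beta1 = 0, theta1 = 0, theta2 = 0,
                          lambda0 = 0.0015, seed = 61)
  per0 <- make_person_data(cfg0)
  r0 <- decompose_msm_weighted(per0, "AD", "TG", "A")
  expect_lt(abs(r0$beta_DE), 0.3)
  expect_lt(abs(r0$beta_IE), 0.05)
  # rare-outcome agreement with the product method
  cfg <- recovery_config(20000, seed = 62)
  per <- make_person_data(cfg)
  prod <- lipmed:::mediation_point(per, "AD", "TG", "A",
                                   c("sex", "birth_year", "site"),
                                   "product")
  msm <- decompose_msm_weighted(per, "AD", "TG", "A")
  expect_lt(abs(msm$beta_IE - prod$beta_IE) / abs(prod$beta_IE), 0.2)
})

test_that("bootstrap mediation is reproducible and well calibrated on one
           draw", {
  cfg <- recovery_config(4000, seed = 71)
  co <- simulate_one(cfg)
  m1 <- mediate(co$pheno, co$geno, "rs17145750", "TG", "AD",
                n_boot = 120, seed = 9)
  m2 <- mediate(co$pheno, co$geno, "rs17145750", "TG", "AD",
                n_boot = 120, seed = 9)
  expect_identical(m1[c("beta_IE", "se_IE", "ci95_IE", "p_IE")],
                   m2[c("beta_IE", "se_IE", "ci95_IE", "p_IE")])
  expect_equal(m1$n_boot, 120)
  expect_true(m1$se_IE > 0)
  expect_true(m1$ci95_IE[1] < m1$ci95_IE[2])
  expect_equal(m1$beta_TE, m1$beta_DE + m1$beta_IE, tolerance = 1e-12)
  expect_error(mediate(co$pheno, co$geno, "rs17145750", "TG", "AD",
                       n_boot = 50), "n_boot")
})
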