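# Synthetic multi-cohort generator.  Emulates the data structure the
# downstream models assume: LD-structured SNP dosages, correlated
# longitudinal lipid panels with additive genetic and family effects, and
# proportional-hazards disease onset on the age axis driven by genotype
# and a lipid mediator.

LIPIDS <- c("TG", "HDL_C", "LDL_C", "TC")

default_lipid_corr <- function() {
  r <- matrix(c(
    1.00, -0.42, 0.18, 0.30,
    -0.42, 1.00, 0.05, 0.20,
    0.18,  0.05, 1.00, 0.95,
    0.30,  0.20, 0.95, 1.00), 4, 4, byrow = TRUE,
    dimnames = list(LIPIDS, LIPIDS))
  r
}

default_snp_lipid_betas <- function(snp_ids) {
  b <- matrix(0, length(snp_ids), 4, dimnames = list(snp_ids, LIPIDS))
  # per-allele effects in mg/dL; two SNPs lower TG / raise HDL-C, one does
  # the opposite, echoing the two association patterns in MLXIPL-locus data
  b["rs1051921", ]  <- c(-8.9, 0.98, 0.0, -1.14)
  b["rs17145750", ] <- c(-8.5, 0.90, 0.0, -1.05)
  b["rs6967028", ]  <- c(3.73, -0.91, 0.0, 0.40)
  b["rs11760752", ] <- c(2.00, -0.50, 0.0, 0.20)
  b
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic multi-cohort generator with
#' defaults representing the study conditions the pipeline is designed
#' for: four MLXIPL-locus SNPs (MAFs 10-20%, one pair in strong LD), four
#' correlated lipids in mg/dL measured over 1-5 exams at ages 45-60,
#' family clusters, and AD/CHD onset on the age axis after 60 with
#' uniform censoring to 95.
#'
#' @param n_cohorts number of independent cohorts.
#' @param n_per_cohort persons per cohort.
#' @param snp_ids SNP identifiers.
#' @param mafs per-SNP minor allele frequencies in (0, 0.5].
#' @param ld_targets symmetric matrix of pairwise dosage r-squared targets
#'   (diagonal ignored); default 0.77 for the first SNP pair, 0.03
#'   elsewhere.
#' @param lipid_means,lipid_sds named per-lipid means and SDs (mg/dL).
#' @param lipid_corr 4x4 target correlation of exam-level lipid noise;
#'   must be symmetric positive definite.
#' @param snp_lipid_betas matrix (SNP x lipid) of additive effects in
#'   mg/dL per minor allele.
#' @param snp_effect_coding `"additive"` (effects scale with dosage) or
#'   `"carrier"` (effects apply to carriers, dosage >= 1).
#' @param lipid_sex_effects,lipid_age_slopes named per-lipid shifts for
#'   sex = 1 and per-year slopes in exam age (centred at 52), so that the
#'   basic adjustments have real signal to remove.
#' @param sigma_family between-family SD of the shared lipid intercept,
#'   as a fraction of each lipid's SD.
#' @param sigma_person within-family person-level SD, same scale.
#' @param family_size_probs probabilities of family sizes 1, 2, 3, ...
#' @param n_exams_range inclusive range of exams per person.
#' @param exam_age_range age window (years) over which exams occur.
#' @param onset_age age (years) at which disease hazard switches on.
#' @param censor_age_range uniform censoring window (years).
#' @param diseases named list; per disease: `theta1` (log-hazard for
#'   carriers of `event_snp`), `theta2` (log-hazard per mg/dL of its
#'   `mediator`, centred at the configured mediator mean), `mediator`
#'   (lipid name), `lambda0` (baseline events per person-year past
#'   `onset_age`).  Defaults give roughly 5% AD and 6.6% CHD cases.
#' @param event_snp SNP whose carrier status enters the hazard.
#' @param friedewald_ldl if `TRUE`, TC is rebuilt from the Friedewald
#'   identity TC = LDL-C + HDL-C + TG/5 instead of being drawn from
#'   `lipid_corr`.
#' @param cohort_shift_frac SD of per-cohort lipid mean shifts, as a
#'   fraction of each lipid's SD.
#' @param seed integer seed for reproducibility.
#' @return A classed list (`sim_config`) of validated settings.
#' @export
sim_config <- function(n_cohorts = 7,
                       n_per_cohort = 3000,
                       snp_ids = c("rs1051921", "rs17145750",
                                   "rs6967028", "rs11760752"),
                       mafs = c(0.20, 0.19, 0.10, 0.15),
                       ld_targets = NULL,
                       lipid_means = c(TG = 120, HDL_C = 52,
                                       LDL_C = 130, TC = 200),
                       lipid_sds = c(TG = 45, HDL_C = 15,
                                     LDL_C = 33, TC = 38),
                       lipid_corr = default_lipid_corr(),
                       snp_lipid_betas = NULL,
                       snp_effect_coding = c("additive", "carrier"),
                       lipid_sex_effects = c(TG = -10, HDL_C = 8,
                                             LDL_C = -2, TC = -3),
                       lipid_age_slopes = c(TG = 0.8, HDL_C = 0,
                                            LDL_C = 0.8, TC = 1.0),
                       sigma_family = 0.3,
                       sigma_person = 0.3,
                       family_size_probs = c(0.5, 0.3, 0.2),
                       n_exams_range = c(1, 5),
                       exam_age_range = c(45, 60),
                       onset_age = 60,
                       censor_age_range = c(60, 95),
                       diseases = list(
                         AD = list(theta1 = 0.18, theta2 = -0.0025,
                                   mediator = "TG", lambda0 = 0.0030),
                         CHD = list(theta1 = 0.05, theta2 = 0.0035,
                                    mediator = "TG", lambda0 = 0.0038)),
                       event_snp = "rs17145750",
                       friedewald_ldl = FALSE,
                       cohort_shift_frac = 0.05,
                       seed = 1L) {
  snp_effect_coding <- match.arg(snp_effect_coding)
  m <- length(snp_ids)
  if (length(mafs) != m) stop("mafs must align with snp_ids")
  names(mafs) <- snp_ids
  if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
  if (is.null(ld_targets)) {
    ld_targets <- matrix(0.03, m, m, dimnames = list(snp_ids, snp_ids))
    if (m >= 2) ld_targets[1, 2] <- ld_targets[2, 1] <- 0.77
    diag(ld_targets) <- 1
  }
  ld_targets <- as.matrix(ld_targets)
  if (any(ld_targets[upper.tri(ld_targets)] < 0) ||
      any(ld_targets[upper.tri(ld_targets)] >= 1))
    stop("off-diagonal ld_targets must lie in [0, 1)")
  if (!isSymmetric(unname(ld_targets))) stop("ld_targets must be symmetric")
  if (!all(LIPIDS %in% names(lipid_means)) ||
      !all(LIPIDS %in% names(lipid_sds)))
    stop("lipid_means and lipid_sds must name TG, HDL_C, LDL_C, TC")
  lipid_corr <- as.matrix(lipid_corr)
  if (!isSymmetric(unname(lipid_corr)) ||
      any(eigen(lipid_corr, symmetric = TRUE,
                only.values = TRUE)$values <= 1e-10))
    stop("lipid_corr must be symmetric positive definite")
  if (is.null(snp_lipid_betas)) {
    snp_lipid_betas <- if (all(c("rs1051921", "rs17145750", "rs6967028",
                                 "rs11760752") %in% snp_ids))
      default_snp_lipid_betas(snp_ids)
    else matrix(0, m, 4, dimnames = list(snp_ids, LIPIDS))
  }
  snp_lipid_betas <- as.matrix(snp_lipid_betas)
  if (is.null(rownames(snp_lipid_betas))) {
    if (nrow(snp_lipid_betas) != m)
      stop("snp_lipid_betas must have one row per SNP")
    rownames(snp_lipid_betas) <- snp_ids
  }
  if (is.null(colnames(snp_lipid_betas))) {
    if (ncol(snp_lipid_betas) != 4)
      stop("snp_lipid_betas must have one column per lipid")
    colnames(snp_lipid_betas) <- LIPIDS
  }
  for (d in names(diseases)) {
    dz <- diseases[[d]]
    if (!all(c("theta1", "theta2", "mediator", "lambda0") %in% names(dz)))
      stop("disease '", d, "' needs theta1, theta2, mediator, lambda0")
    if (dz$lambda0 <= 0) stop("lambda0 must be positive for disease ", d)
    if (!dz$mediator %in% LIPIDS) stop("unknown mediator for disease ", d)
  }
  if (n_cohorts < 1) stop("n_cohorts must be >= 1")
  if (!event_snp %in% snp_ids) stop("event_snp must be one of snp_ids")
  structure(list(
    n_cohorts = as.integer(n_cohorts),
    n_per_cohort = as.integer(n_per_cohort),
    snp_ids = snp_ids, mafs = mafs, ld_targets = ld_targets,
    lipid_means = lipid_means[LIPIDS], lipid_sds = lipid_sds[LIPIDS],
    lipid_corr = lipid_corr,
    snp_lipid_betas = as.matrix(snp_lipid_betas)[snp_ids, LIPIDS,
                                                 drop = FALSE],
    snp_effect_coding = snp_effect_coding,
    lipid_sex_effects = lipid_sex_effects[LIPIDS],
    lipid_age_slopes = lipid_age_slopes[LIPIDS],
    sigma_family = sigma_family, sigma_person = sigma_person,
    family_size_probs = family_size_probs,
    n_exams_range = as.integer(n_exams_range),
    exam_age_range = exam_age_range,
    onset_age = onset_age, censor_age_range = censor_age_range,
    diseases = diseases, event_snp = event_snp,
    friedewald_ldl = isTRUE(friedewald_ldl),
    cohort_shift_frac = cohort_shift_frac,
    seed = as.integer(seed)), class = "sim_config")
}

# P(X <= u, Y <= v) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature.
pbvnorm <- function(u, v, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(u) * stats::pnorm(v))
  if (rho > 0.999999) return(stats::pnorm(min(u, v)))
  if (rho < -0.999999) return(max(0, stats::pnorm(u) - stats::pnorm(-v)))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((v - rho * x) / s),
    -Inf, u, rel.tol = 1e-10)$value
}

# Expected Pearson correlation of two {0,1,2} dosages produced by
# thresholding a standard bivariate normal with latent correlation rho.
copula_dosage_cor <- function(rho, p1, p2) {
  th <- function(p) stats::qnorm(c((1 - p)^2, (1 - p)^2 + 2 * p * (1 - p)))
  t1 <- th(p1); t2 <- th(p2)
  # dosage d = 1{Z > t[1]} + 1{Z > t[2]};  E d = 2p, Var d = 2p(1-p)+HW
  exy <- 0
  for (a in 1:2) for (b in 1:2) {
    u <- t1[a]; v <- t2[b]
    exy <- exy + (1 - stats::pnorm(u) - stats::pnorm(v) +
                    pbvnorm(u, v, rho))
  }
  vd <- function(p) 2 * p * (1 - p)  # HWE dosage variance
  (exy - 4 * p1 * p2) / sqrt(vd(p1) * vd(p2))
}

# Latent normal correlation achieving a target dosage correlation.
calibrate_latent_rho <- function(target_r, p1, p2) {
  if (abs(target_r) < 1e-8) return(0)
  f <- function(rho) copula_dosage_cor(rho, p1, p2) - target_r
  sgn <- sign(target_r)
  lo <- 0; hi <- sgn * 0.99999
  if (sgn * f(hi) < 0)
    stop(sprintf("target dosage correlation %.3f unattainable for MAFs %.3f/%.3f",
                 target_r, p1, p2))
  stats::uniroot(f, sort(c(lo, hi)), tol = 1e-8)$root
}

#' Simulate LD-structured genotype dosages
#'
#' Draws minor-allele dosages through a Gaussian copula: a latent
#' multivariate normal is thresholded per SNP at the Hardy-Weinberg
#' genotype-probability quantiles, with the latent correlation for each
#' SNP pair calibrated numerically (monotone root search on the exact
#' thresholded-normal dosage correlation) so the realized dosage
#' r-squared matches the requested target.
#'
#' @param n number of persons.
#' @param mafs named vector of minor allele frequencies.
#' @param ld_targets symmetric matrix of pairwise r-squared targets
#'   (or `NULL` for independent SNPs).
#' @param seed optional integer seed.
#' @param person_ids optional person identifiers.
#' @return A [genotype_matrix].
#' @export
simulate_genotypes <- function(n, mafs, ld_targets = NULL, seed = NULL,
                               person_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(mafs)
  snp_ids <- names(mafs)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (is.null(ld_targets)) {
    ld_targets <- diag(1, m)
  }
  lat <- diag(1, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
      r_target <- sqrt(max(0, ld_targets[i, j]))
      lat[i, j] <- lat[j, i] <-
        calibrate_latent_rho(r_target, mafs[i], mafs[j])
    }
  }
  ev <- eigen(lat, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-8)) {
    adj <- as.matrix(Matrix::nearPD(lat, corr = TRUE)$mat)
    delta <- abs(adj - lat)
    if (max(delta) > 0.05) {
      idx <- which(delta == max(delta), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "ld_targets infeasible: latent correlation for pair (%s, %s) not positive-definite after adjustment",
        snp_ids[idx[1]], snp_ids[idx[2]]))
    }
    lat <- adj
  }
  z <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = lat)
  if (m == 1) z <- matrix(z, ncol = 1)
  d <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    p <- mafs[j]
    cuts <- stats::qnorm(c((1 - p)^2, (1 - p)^2 + 2 * p * (1 - p)))
    d[, j] <- (z[, j] > cuts[1]) + (z[, j] > cuts[2])
  }
  if (is.null(person_ids)) person_ids <- sprintf("p%05d", seq_len(n))
  genotype_matrix(d, person_ids = person_ids, snp_ids = snp_ids)
}

# Assign persons to families with sizes drawn from family_size_probs.
assign_families <- function(n, size_probs, prefix = "f") {
  sizes <- integer(0)
  total <- 0L
  while (total < n) {
    s <- sample.int(length(size_probs), 1L, prob = size_probs)
    sizes <- c(sizes, s)
    total <- total + s
  }
  fam <- rep(seq_along(sizes), sizes)[seq_len(n)]
  sprintf("%s%05d", prefix, fam)
}

#' Simulate longitudinal lipid panels for given genotypes
#'
#' Per person and exam, each lipid is its configured mean plus additive
#' SNP effects, a sex shift, an exam-age slope, a family-shared and a
#' person-level Gaussian intercept, and exam-level multivariate normal
#' noise with the configured cross-lipid correlation.  With
#' `friedewald_ldl` set, TC is rebuilt as LDL-C + HDL-C + TG/5.
#'
#' @param gm a [genotype_matrix].
#' @param config a [sim_config].
#' @param seed optional integer seed.
#' @param cohort_shift optional named per-lipid mean shift (mg/dL).
#' @param family_prefix prefix for generated family ids.
#' @return Long-format data.frame, one row per person-exam, with columns
#'   `person_id`, `family_id`, `sex`, `birth_year`, `site`, `exam_no`,
#'   `exam_age`, and the four lipids in mg/dL.
#' @export
simulate_lipids <- function(gm, config, seed = NULL, cohort_shift = NULL,
                            family_prefix = "f") {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(gm$person_ids)
  if (is.null(cohort_shift))
    cohort_shift <- stats::setNames(rep(0, 4), LIPIDS)
  X <- gm$dosages[, config$snp_ids, drop = FALSE]
  X[is.na(X)] <- 0L
  if (config$snp_effect_coding == "carrier") X <- (X >= 1L) + 0L
  genetic <- X %*% config$snp_lipid_betas          # n x 4
  fam <- assign_families(n, config$family_size_probs, family_prefix)
  sdv <- config$lipid_sds
  ch <- chol(config$lipid_corr)
  # family, person and exam components all share the target cross-lipid
  # correlation, so the marginal exam-level correlation matches it too
  fam_levels <- unique(fam)
  fam_eff <- matrix(stats::rnorm(length(fam_levels) * 4), ncol = 4) %*%
    ch %*% diag(config$sigma_family * sdv)
  rownames(fam_eff) <- fam_levels
  per_eff <- matrix(stats::rnorm(n * 4), ncol = 4) %*% ch %*%
    diag(config$sigma_person * sdv)
  sex <- stats::rbinom(n, 1, 0.5)
  birth_year <- sample(1920:1960, n, replace = TRUE)
  site <- sample(c("siteA", "siteB"), n, replace = TRUE)
  n_exams <- sample(seq(config$n_exams_range[1], config$n_exams_range[2]),
                    n, replace = TRUE)
  idx <- rep(seq_len(n), n_exams)
  n_obs <- length(idx)
  exam_age <- unlist(lapply(n_exams, function(k)
    sort(stats::runif(k, config$exam_age_range[1],
                      config$exam_age_range[2]))))
  exam_no <- unlist(lapply(n_exams, seq_len))
  # residual exam-level noise: sd split between person level and exam
  # level so total per-lipid variance stays near lipid_sds^2
  resid_frac <- sqrt(max(0, 1 - config$sigma_family^2 -
                           config$sigma_person^2))
  noise <- matrix(stats::rnorm(n_obs * 4), ncol = 4) %*% ch %*%
    diag(resid_frac * sdv)
  vals <- matrix(rep(config$lipid_means + cohort_shift[LIPIDS],
                     each = n_obs), ncol = 4) +
    genetic[idx, , drop = FALSE] +
    outer(sex[idx], config$lipid_sex_effects) +
    outer(exam_age - 52, config$lipid_age_slopes) +
    fam_eff[fam[idx], , drop = FALSE] +
    per_eff[idx, , drop = FALSE] +
    noise
  colnames(vals) <- LIPIDS
  vals[vals < 1] <- 1            # lipids must stay positive
  if (config$friedewald_ldl)
    vals[, "TC"] <- vals[, "LDL_C"] + vals[, "HDL_C"] + vals[, "TG"] / 5
  data.frame(person_id = gm$person_ids[idx],
             family_id = fam[idx],
             sex = sex[idx], birth_year = birth_year[idx],
             site = site[idx],
             exam_no = exam_no, exam_age = exam_age,
             vals, stringsAsFactors = FALSE)
}

#' Simulate disease onset under a proportional-hazards process
#'
#' Event times follow a constant baseline hazard beyond `onset_age`,
#' multiplied by `exp(theta1 * carrier + theta2 * (M - mean))` where the
#' carrier indicator is taken from the configured event SNP and the
#' mediator M is the person's last-exam value of the configured lipid.
#' Censoring is uniform over `censor_age_range`, independent of the event
#' process.  Because exams end before `onset_age`, every event or censor
#' age is at or after the last exam.
#'
#' @param gm a [genotype_matrix].
#' @param lipids exam-level data.frame from [simulate_lipids].
#' @param config a [sim_config].
#' @param disease name of a disease configured in `config$diseases`.
#' @param seed optional integer seed.
#' @return data.frame with `person_id`, `event_age`, `event_ind`.
#' @export
simulate_events <- function(gm, lipids, config, disease, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dz <- config$diseases[[disease]]
  if (is.null(dz)) stop("unknown disease: ", disease)
  if (!is.null(seed)) set.seed(seed)
  ids <- gm$person_ids
  n <- length(ids)
  # last-exam mediator value per person
  o <- order(lipids$person_id, lipids$exam_age)
  lip <- lipids[o, ]
  last <- lip[!duplicated(lip$person_id, fromLast = TRUE), ]
  M <- last[[dz$mediator]][match(ids, last$person_id)]
  M[is.na(M)] <- config$lipid_means[dz$mediator]
  A <- code_genotype(gm$dosages[, config$event_snp], "carrier")
  A[is.na(A)] <- 0L
  rate <- dz$lambda0 * exp(dz$theta1 * A +
                             dz$theta2 * (M - config$lipid_means[dz$mediator]))
  onset <- pmax(config$onset_age,
                last$exam_age[match(ids, last$person_id)], na.rm = TRUE)
  t_event <- onset + stats::rexp(n, rate)
  t_cens <- stats::runif(n, config$censor_age_range[1],
                         config$censor_age_range[2])
  t_cens <- pmax(t_cens, onset)   # censoring cannot precede risk entry
  event_ind <- as.integer(t_event <= t_cens)
  data.frame(person_id = ids,
             event_age = pmin(t_event, t_cens),
             event_ind = event_ind, stringsAsFactors = FALSE)
}

simulate_cohort <- function(config, cohort_id = "cohort1", seed = NULL,
                            prefix = "c1") {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_per_cohort
  gm <- simulate_genotypes(n, config$mafs, config$ld_targets,
                           person_ids = sprintf("%s_p%05d", prefix,
                                                seq_len(n)))
  shift <- stats::rnorm(4, 0, config$cohort_shift_frac * config$lipid_sds)
  names(shift) <- LIPIDS
  lip <- simulate_lipids(gm, config, cohort_shift = shift,
                         family_prefix = paste0(prefix, "_f"))
  pheno <- lip
  pheno$cohort_id <- cohort_id
  for (d in names(config$diseases)) {
    ev <- simulate_events(gm, lip, config, d)
    pheno[[paste0("event_age_", d)]] <-
      ev$event_age[match(pheno$person_id, ev$person_id)]
    pheno[[paste0("event_ind_", d)]] <-
      ev$event_ind[match(pheno$person_id, ev$person_id)]
  }
  cols <- c("person_id", "family_id", "cohort_id", "sex", "birth_year",
            "site", "exam_no", "exam_age", LIPIDS,
            unlist(lapply(names(config$diseases), function(d)
              paste0(c("event_age_", "event_ind_"), d))))
  list(pheno = pheno[, cols], geno = gm)
}

#' Simulate a multi-cohort study
#'
#' Generates `config$n_cohorts` independent cohorts sharing the same SNP
#' effects but with cohort-specific lipid mean shifts and disjoint person
#' ids, enabling per-cohort analysis and cross-cohort meta-analysis.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config].
#' @return A list of class `multicohort`: one element per cohort, each a
#'   list with `pheno` (long-format phenotype table) and `geno`
#'   (a [genotype_matrix]).
#' @export
simulate_multicohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cohorts < 1) stop("n_cohorts must be >= 1")
  out <- vector("list", config$n_cohorts)
  names(out) <- paste0("cohort", seq_len(config$n_cohorts))
  for (k in seq_len(config$n_cohorts)) {
    out[[k]] <- simulate_cohort(config, cohort_id = names(out)[k],
                                seed = (config$seed + 7919L * k) %% .Machine$integer.max,
                                prefix = paste0("c", k))
  }
  structure(out, class = "multicohort", config = config)
}

#' @export
print.multicohort <- function(x, ...) {
  cat(sprintf("multicohort: %d cohorts\n", length(x)))
  for (k in seq_along(x))
    cat(sprintf("  %s: %d persons, %d person-exams\n", names(x)[k],
                length(unique(x[[k]]$pheno$person_id)),
                nrow(x[[k]]$pheno)))
  invisible(x)
}
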