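# Univariate unconditional and conditional association models:
# estimating-equation linear models for longitudinal lipids and Cox
# proportional-hazards models for disease, plus the attenuation and
# multiplicity helpers used to compare them.

#' LDL cholesterol by the Friedewald relation
#'
#' LDL-C = TC - HDL-C - TG/5 (all mg/dL), valid for TG below 400 mg/dL.
#'
#' @param tc,hdl,tg total, HDL and triglyceride concentrations in mg/dL.
#' @return LDL-C in mg/dL (vectorized).
#' @examples
#' friedewald_ldl(200, 50, 150)  # 120
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tg >= 400, na.rm = TRUE))
    stop("Friedewald invalid: TG >= 400 mg/dL")
  tc - hdl - tg / 5
}

#' One result row for a single model coefficient
#'
#' @param term coefficient name.
#' @param beta,se point estimate and standard error.
#' @param n_persons,n_obs,n_events sample-size bookkeeping.
#' @param model_desc human-readable model descriptor.
#' @return `assoc_result` object; p-value is two-sided normal, the CI is
#'   beta +/- 1.96 se.
#' @keywords internal
new_assoc_result <- function(term, beta, se, n_persons, n_obs,
                             n_events = NA_integer_, model_desc = "") {
  beta <- unname(beta); se <- unname(se)
  if (!is.finite(se) || se <= 0) stop("standard error must be positive")
  z <- beta / se
  structure(list(term = term, beta = beta, se = se,
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
                 n_persons = n_persons, n_obs = n_obs,
                 n_events = n_events, model_desc = model_desc),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s\n  %s: beta = %.4g, se = %.4g, p = %.3g, 95%% CI (%.4g, %.4g)\n",
              x$model_desc, x$term, x$beta, x$se, x$p,
              x$ci95[1], x$ci95[2]))
  cat(sprintf("  n_persons = %d, n_obs = %d%s\n", x$n_persons, x$n_obs,
              if (!is.na(x$n_events))
                sprintf(", n_events = %d", x$n_events) else ""))
  invisible(x)
}

# Merge dosage columns for requested SNPs into a phenotype table.
merge_geno <- function(pheno, geno, snps, coding = "additive") {
  stopifnot(inherits(geno, "genotype_matrix"))
  missing_snps <- setdiff(snps, geno$snp_ids)
  if (length(missing_snps))
    stop("SNP(s) not in genotype matrix: ",
         paste(missing_snps, collapse = ", "))
  ix <- match(pheno$person_id, geno$person_ids)
  for (s in snps)
    pheno[[s]] <- code_genotype(geno$dosages[ix, s], coding)
  pheno
}

# Design matrix with intercept, factor expansion for character columns.
build_design <- function(data, cols) {
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (cn in cols) {
    v <- data[[cn]]
    if (is.null(v)) stop("column not found: ", cn)
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      lv <- levels(v)
      if (length(lv) > 1) {
        dm <- stats::model.matrix(~ v)[, -1, drop = FALSE]
        colnames(dm) <- paste0(cn, lv[-1])
        X <- cbind(X, dm)
      }
    } else {
      X <- cbind(X, stats::setNames(data.frame(v), cn))
    }
  }
  as.matrix(X)
}

#' Longitudinal lipid association model with cluster-robust variance
#'
#' Fits a Gaussian estimating-equation regression of a lipid outcome on a
#' SNP over all person-exam rows, adjusting for the basic covariates,
#' optionally for another lipid (conditional model) and/or further SNPs
#' (pairwise-SNP model).  The variance is the cluster sandwich estimator
#' with the family as the cluster, so repeated exams and family
#' relatedness are both absorbed.  Under the `"independence"` working
#' correlation the point estimates are exactly ordinary least squares on
#' the stacked rows; `"exchangeable"` re-weights within clusters.
#'
#' @param pheno long-format phenotype table (one row per exam).
#' @param geno a [genotype_matrix].
#' @param outcome lipid column name (`"TG"`, `"HDL_C"`, `"LDL_C"`, `"TC"`).
#' @param snp exposure SNP id.
#' @param coding `"additive"` or `"carrier"` exposure coding.
#' @param covariates basic adjustment columns.
#' @param adjust_for optional additional lipid column(s) (conditional
#'   analysis).
#' @param other_snps optional further SNP ids entered additively.
#' @param cluster cluster id column (default `"family_id"`).
#' @param working_corr working correlation structure.
#' @return An `assoc_result` for the exposure SNP term; the full
#'   coefficient table is attached as attribute `"coefficients"`.
#' @export
fit_linear_longitudinal <- function(pheno, geno, outcome, snp,
                                    coding = "additive",
                                    covariates = c("sex", "birth_year",
                                                   "site", "exam_age"),
                                    adjust_for = NULL,
                                    other_snps = NULL,
                                    cluster = "family_id",
                                    working_corr = c("independence",
                                                     "exchangeable")) {
  working_corr <- match.arg(working_corr)
  if (outcome %in% c(adjust_for, covariates))
    stop("outcome cannot appear among covariates")
  dat <- merge_geno(pheno, geno, c(snp, other_snps), coding)
  cols <- c(snp, other_snps, covariates, adjust_for)
  keep <- stats::complete.cases(dat[, c(outcome, cols, cluster)])
  dat <- dat[keep, ]
  X <- build_design(dat, cols)
  fit <- gee_gaussian(dat[[outcome]], X, cluster_id = dat[[cluster]],
                      corr_id = dat$person_id,
                      working_corr = working_corr)
  desc <- sprintf(
    "linear EE (%s working corr., sandwich SE by %s): %s ~ %s [%s]%s",
    working_corr, cluster, outcome, snp, coding,
    if (length(c(adjust_for, other_snps)))
      paste0(" + ", paste(c(other_snps, adjust_for), collapse = " + "))
    else "")
  res <- new_assoc_result(snp, fit$coefficients[snp],
                          sqrt(fit$vcov[snp, snp]),
                          n_persons = length(unique(dat$person_id)),
                          n_obs = fit$n_obs, model_desc = desc)
  attr(res, "coefficients") <- data.frame(
    term = names(fit$coefficients), beta = fit$coefficients,
    se = sqrt(diag(fit$vcov)), row.names = NULL)
  attr(res, "rho") <- fit$rho
  res
}

#' Reduce an exam-level table to one row per person
#'
#' Applies the mediator-measurement rule: for each person, keep the
#' latest exam at which all four lipids are present and which precedes
#' disease onset (for persons who develop the disease; censoring ages do
#' not constrain the choice).  Persons with no qualifying exam are
#' dropped, with the count recorded in attribute `"n_dropped"`.
#'
#' @param pheno long-format phenotype table.
#' @param diseases disease suffixes whose onsets the exam must precede
#'   (default: every `event_ind_*` column present).
#' @return One-row-per-person data.frame.
#' @export
person_level <- function(pheno, diseases = NULL) {
  if (is.null(diseases)) {
    diseases <- sub("^event_ind_", "",
                    grep("^event_ind_", names(pheno), value = TRUE))
  }
  lip_ok <- stats::complete.cases(pheno[, intersect(LIPIDS, names(pheno)),
                                        drop = FALSE])
  pre_onset <- rep(TRUE, nrow(pheno))
  for (d in diseases) {
    ia <- pheno[[paste0("event_age_", d)]]
    ii <- pheno[[paste0("event_ind_", d)]]
    pre_onset <- pre_onset & (ii == 0L | pheno$exam_age <= ia)
  }
  ok <- lip_ok & pre_onset
  cand <- pheno[ok, ]
  o <- order(cand$person_id, cand$exam_age)
  cand <- cand[o, ]
  out <- cand[!duplicated(cand$person_id, fromLast = TRUE), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(unique(pheno$person_id)) - nrow(out)
  out
}

#' Cox proportional-hazards disease model on the age axis
#'
#' Fits a Cox model for disease onset with age as the time variable from
#' birth (no left truncation), Efron handling of ties, and optional
#' cluster-robust standard errors by family.  Lipid covariates, when
#' requested, are the person's values under the pre-onset
#' last-exam rule of [person_level].
#'
#' @param pheno long-format phenotype table (collapsed internally) or an
#'   already person-level table.
#' @param geno a [genotype_matrix].
#' @param outcome disease suffix, e.g. `"AD"` or `"CHD"`.
#' @param snp exposure SNP id.
#' @param coding `"additive"` or `"carrier"`.
#' @param covariates baseline covariates (age is the time axis, not a
#'   covariate).
#' @param adjust_for optional lipid column(s).
#' @param cluster cluster id column for robust SE, or `NULL` for
#'   model-based SE.
#' @return An `assoc_result` for the exposure term with `n_events` set;
#'   the fitted `coxph` object is attached as attribute `"fit"`.
#' @export
fit_cox <- function(pheno, geno, outcome, snp, coding = "additive",
                    covariates = c("sex", "birth_year", "site"),
                    adjust_for = NULL, cluster = "family_id") {
  age_col <- paste0("event_age_", outcome)
  ind_col <- paste0("event_ind_", outcome)
  if (!all(c(age_col, ind_col) %in% names(pheno)))
    stop("phenotype table lacks event columns for outcome ", outcome)
  per <- if (anyDuplicated(pheno$person_id)) person_level(pheno) else pheno
  dat <- merge_geno(per, geno, snp, coding)
  cols <- c(snp, covariates, adjust_for)
  keep <- stats::complete.cases(dat[, c(age_col, ind_col, cols)])
  dat <- dat[keep, ]
  n_events <- sum(dat[[ind_col]])
  if (n_events < 1) stop("no events for outcome ", outcome)
  X <- build_design(dat, cols)[, -1, drop = FALSE]  # coxph needs no intercept
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("singular design: constant column(s) ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  orig <- colnames(X)
  safe <- make.names(orig, unique = TRUE)
  dd <- as.data.frame(X)
  names(dd) <- safe
  dd$.time <- dat[[age_col]]
  dd$.status <- dat[[ind_col]]
  use_cluster <- !is.null(cluster) && cluster %in% names(dat) &&
    length(unique(dat[[cluster]])) > 1
  if (use_cluster) dd$.clust <- dat[[cluster]]
  notes <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(
      stats::as.formula(paste("survival::Surv(.time, .status) ~",
                              paste(safe, collapse = " + "),
                              if (use_cluster) "+ cluster(.clust)" else "")),
      data = dd, ties = "efron"),
    warning = function(w) {
      # monotone-likelihood notices are kept as diagnostics, not warnings
      if (grepl("Loglik converged before variable",
                conditionMessage(w))) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  if (!is.null(fit$info) && isTRUE(fit$info$fail))
    stop("Cox model failed to converge")
  cf <- summary(fit)$coefficients
  rn <- safe[match(snp, orig)]
  beta <- cf[rn, "coef"]
  if (!is.finite(beta)) stop("Cox coefficient for ", snp, " not estimable")
  se <- if (use_cluster) cf[rn, "robust se"] else cf[rn, "se(coef)"]
  desc <- sprintf("Cox PH (age axis, Efron ties%s): %s ~ %s [%s]%s",
                  if (use_cluster) paste0(", robust SE by ", cluster)
                  else "",
                  outcome, snp, coding,
                  if (length(adjust_for))
                    paste0(" + ", paste(adjust_for, collapse = " + "))
                  else "")
  res <- new_assoc_result(snp, beta, se,
                          n_persons = nrow(dat), n_obs = nrow(dat),
                          n_events = n_events, model_desc = desc)
  attr(res, "fit") <- fit
  if (length(notes)) attr(res, "notes") <- notes
  res
}

#' Attenuation of an association after mediator adjustment
#'
#' Percent decrease in the magnitude of a coefficient once a candidate
#' mediator enters the model: `100 (|b_unadj| - |b_adj|) / |b_unadj|`.
#' Negative values mean magnification.
#'
#' @param beta_unadj,beta_adj coefficients from the unadjusted and
#'   adjusted models, same outcome/exposure/units.
#' @return List with `percent` (nearest integer) and `percent_raw`.
#' @examples
#' conditional_attenuation(0.98, 0.47)$percent  # 52
#' @export
conditional_attenuation <- function(beta_unadj, beta_adj) {
  if (!is.finite(beta_unadj) || beta_unadj == 0)
    stop("unadjusted beta must be nonzero")
  raw <- 100 * (abs(beta_unadj) - abs(beta_adj)) / abs(beta_unadj)
  list(percent = round(raw), percent_raw = raw)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param n_tests number of tests, at least 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 28)  # 1.785714e-03
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}
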