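# Monotone-partial-likelihood notices from the Cox workhorse are routine
# in bootstrap resamples of small strata; the stopped coefficient is kept
# and the notice silenced.
quiet_monotone <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("Loglik converged before variable", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Natural direct/indirect effect estimation for a time-to-event outcome
# with a continuous lipid mediator and a binary (carrier vs. non-carrier)
# genetic exposure.  Two estimators are provided: the rare-outcome
# product method (primary; exactly additive on the log-hazard scale) and
# a weighted natural-effect Cox model (secondary), with nonparametric
# bootstrap inference over persons.

#' Linear mediator model
#'
#' Least-squares regression of the mediator on the carrier-coded exposure
#' and confounders: `M = beta0 + beta1 A + gamma' C + eps`.
#'
#' @param data one-row-per-person data.frame (see [person_level]).
#' @param mediator mediator column name (a lipid, mg/dL).
#' @param exposure exposure column name (binary 0/1).
#' @param covariates confounder column names.
#' @return `mediator_fit`: list with `beta1`, `beta0`, `gamma`, `sigma`
#'   (residual SD), `se_beta1`, `n`, plus the design information needed
#'   to compute fitted means.
#' @export
fit_mediator_model <- function(data, mediator, exposure,
                               covariates = c("sex", "birth_year",
                                              "site")) {
  X <- build_design(data, c(exposure, covariates))
  y <- data[[mediator]]
  if (is.null(y)) stop("mediator column not found: ", mediator)
  keep <- stats::complete.cases(cbind(y, X))
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  r <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  sigma <- sqrt(sum(r^2) / (n - p))
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sigma * sqrt(diag(XtXinv))
  structure(list(beta1 = unname(beta[exposure]),
                 beta0 = unname(beta["(Intercept)"]),
                 gamma = beta[setdiff(names(beta),
                                      c("(Intercept)", exposure))],
                 coefficients = beta,
                 sigma = sigma, se_beta1 = unname(se[match(exposure,
                                                           colnames(X))]),
                 n = n, mediator = mediator, exposure = exposure,
                 covariates = covariates),
            class = "mediator_fit")
}

# Cox outcome model with exposure + mediator + confounders; returns the
# named log-hazard coefficients.
fit_outcome_cox <- function(data, outcome, mediator, exposure,
                            covariates = c("sex", "birth_year", "site")) {
  age_col <- paste0("event_age_", outcome)
  ind_col <- paste0("event_ind_", outcome)
  X <- build_design(data, c(exposure, mediator, covariates))[, -1,
                                                             drop = FALSE]
  keep <- stats::complete.cases(cbind(data[[age_col]], data[[ind_col]], X))
  X <- X[keep, , drop = FALSE]
  yy <- cbind(time = data[[age_col]][keep],
              status = data[[ind_col]][keep])
  if (sum(yy[, "status"]) < 1) stop("no events for outcome ", outcome)
  fit <- quiet_monotone(
    survival::coxph.fit(X, yy, strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(),
                        weights = NULL, method = "efron",
                        rownames = NULL))
  theta <- fit$coefficients
  names(theta) <- colnames(X)
  if (any(!is.finite(theta))) stop("Cox outcome model did not converge")
  structure(list(theta1 = unname(theta[exposure]),
                 theta2 = unname(theta[mediator]),
                 theta3 = theta[setdiff(names(theta),
                                        c(exposure, mediator))],
                 coefficients = theta,
                 n = nrow(X), n_events = sum(yy[, "status"]),
                 outcome = outcome, mediator = mediator,
                 exposure = exposure),
            class = "outcome_fit")
}

new_mediation_result <- function(beta_DE, beta_IE, beta_TE, estimator,
                                 n = NA_integer_, n_events = NA_integer_) {
  structure(list(beta_DE = beta_DE, beta_IE = beta_IE, beta_TE = beta_TE,
                 se_DE = NA_real_, se_IE = NA_real_, se_TE = NA_real_,
                 ci95_DE = c(NA_real_, NA_real_),
                 ci95_IE = c(NA_real_, NA_real_),
                 ci95_TE = c(NA_real_, NA_real_),
                 p_IE = NA_real_,
                 prop_mediated = if (abs(beta_TE) > 0)
                   100 * beta_IE / beta_TE else NA_real_,
                 estimator = estimator, n_boot = 0L,
                 n = n, n_events = n_events),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation decomposition (%s estimator)\n", x$estimator))
  for (eff in c("TE", "DE", "IE")) {
    b <- x[[paste0("beta_", eff)]]
    s <- x[[paste0("se_", eff)]]
    ci <- x[[paste0("ci95_", eff)]]
    cat(sprintf("  beta_%s = %+.4f%s\n", eff, b,
                if (is.finite(s))
                  sprintf(" (se %.4f, 95%% CI %.4f..%.4f)", s, ci[1], ci[2])
                else ""))
  }
  if (is.finite(x$p_IE)) cat(sprintf("  p_IE = %.3g\n", x$p_IE))
  if (is.finite(x$prop_mediated))
    cat(sprintf("  proportion mediated = %.1f%%\n", x$prop_mediated))
  invisible(x)
}

#' Product-method natural effect decomposition
#'
#' Under a rare outcome, a Gaussian mediator model and a proportional-
#' hazards outcome model with no exposure-mediator interaction, the
#' natural effects for exposure `a` vs `a_star` on the log-hazard scale
#' are `beta_DE = theta1 (a - a_star)`, `beta_IE = theta2 beta1
#' (a - a_star)`, and the total effect is their sum (exactly additive).
#'
#' @param mfit a `mediator_fit` from [fit_mediator_model].
#' @param ofit an `outcome_fit` (Cox model including both exposure and
#'   mediator).
#' @param a,a_star exposure contrast, default carrier (1) vs.
#'   non-carrier (0).
#' @return A `mediation_result` with point estimates only.
#' @export
decompose_product <- function(mfit, ofit, a = 1, a_star = 0) {
  stopifnot(inherits(mfit, "mediator_fit"), inherits(ofit, "outcome_fit"))
  d <- a - a_star
  new_mediation_result(beta_DE = ofit$theta1 * d,
                       beta_IE = ofit$theta2 * mfit$beta1 * d,
                       beta_TE = (ofit$theta1 + ofit$theta2 * mfit$beta1) * d,
                       estimator = "product",
                       n = ofit$n, n_events = ofit$n_events)
}

#' Weighted natural-effect Cox decomposition
#'
#' Fits a natural-effect Cox model on a duplicated dataset: each person
#' appears once with the auxiliary exposure set to the observed value and
#' once with it flipped, weighted by the Gaussian mediator density ratio
#' `f(M | A = a_aux, C) / f(M | A = A_obs, C)`.  The coefficient of the
#' observed-exposure term is the natural direct effect and that of the
#' auxiliary term the natural indirect effect; their sum is the total
#' effect.  Weights are truncated at a configurable upper percentile.
#'
#' @param data one-row-per-person data.frame.
#' @param outcome disease suffix.
#' @param mediator,exposure,covariates model columns as in
#'   [fit_mediator_model].
#' @param a,a_star exposure contrast (only 1 vs 0 supported).
#' @param weight_trunc upper percentile at which to truncate weights.
#' @return A `mediation_result` with point estimates only.
#' @export
decompose_msm_weighted <- function(data, outcome, mediator, exposure,
                                   covariates = c("sex", "birth_year",
                                                  "site"),
                                   a = 1, a_star = 0,
                                   weight_trunc = 0.99) {
  if (!identical(c(a, a_star), c(1, 0)))
    stop("only the carrier (1) vs non-carrier (0) contrast is supported")
  age_col <- paste0("event_age_", outcome)
  ind_col <- paste0("event_ind_", outcome)
  keep <- stats::complete.cases(
    data[, c(age_col, ind_col, mediator, exposure, covariates)])
  data <- data[keep, ]
  mfit <- fit_mediator_model(data, mediator, exposure, covariates)
  Xm <- build_design(data, c(exposure, mfit$covariates))
  mu_obs <- as.numeric(Xm %*% mfit$coefficients)
  # fitted mediator mean with the exposure column replaced by a_aux
  b1 <- mfit$beta1
  A_obs <- data[[exposure]]
  M <- data[[mediator]]
  expand <- function(a_aux) {
    mu_aux <- mu_obs + b1 * (a_aux - A_obs)
    w <- stats::dnorm(M, mu_aux, mfit$sigma) /
      stats::dnorm(M, mu_obs, mfit$sigma)
    data.frame(.time = data[[age_col]], .status = data[[ind_col]],
               .a = A_obs, .astar = a_aux, .w = w, .id = seq_len(nrow(data)),
               data[, covariates, drop = FALSE])
  }
  big <- rbind(expand(0), expand(1))
  cap <- stats::quantile(big$.w, weight_trunc)
  capped <- big$.w > cap
  if (mean(capped) > 0.5)
    stop("degenerate mediator-density weights: >50% at truncation bound")
  big$.w[capped] <- cap
  Xo <- build_design(big, c(".a", ".astar", covariates))[, -1, drop = FALSE]
  fit <- quiet_monotone(
    survival::coxph.fit(Xo, cbind(time = big$.time, status = big$.status),
                        strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(),
                        weights = big$.w, method = "efron",
                        rownames = NULL))
  theta <- fit$coefficients
  names(theta) <- colnames(Xo)
  if (any(!is.finite(theta)))
    stop("natural-effect Cox model did not converge")
  new_mediation_result(beta_DE = unname(theta[".a"]),
                       beta_IE = unname(theta[".astar"]),
                       beta_TE = unname(theta[".a"] + theta[".astar"]),
                       estimator = "msm_weighted",
                       n = nrow(data), n_events = sum(data[[ind_col]]))
}

# One point estimate for the bootstrap loop (fast path, no validation).
mediation_point <- function(data, outcome, mediator, exposure, covariates,
                            estimator, weight_trunc = 0.99) {
  if (estimator == "product") {
    mfit <- fit_mediator_model(data, mediator, exposure, covariates)
    ofit <- fit_outcome_cox(data, outcome, mediator, exposure, covariates)
    decompose_product(mfit, ofit)
  } else {
    decompose_msm_weighted(data, outcome, mediator, exposure, covariates,
                           weight_trunc = weight_trunc)
  }
}

#' Mediation analysis with bootstrap inference
#'
#' Runs the chosen natural-effect estimator on the full sample, then
#' resamples persons with replacement `n_boot` times to obtain standard
#' errors (SD of bootstrap estimates), 95% percentile confidence
#' intervals, and a two-sided normal-approximation p-value for the
#' indirect effect.  The resampling unit is the person (no cluster
#' correction).
#'
#' @param data one-row-per-person data.frame (e.g. from [person_level]
#'   with a carrier-coded exposure column merged in; see [mediate] for
#'   the convenience wrapper).
#' @param outcome disease suffix.
#' @param mediator,exposure,covariates model columns.
#' @param estimator `"product"` or `"msm_weighted"`.
#' @param n_boot number of bootstrap replicates (>= 100; the reference
#'   analysis uses 1000).
#' @param seed integer seed for reproducibility.
#' @param weight_trunc weight-truncation percentile for the weighted
#'   estimator.
#' @return A complete `mediation_result`.
#' @export
bootstrap_mediation <- function(data, outcome, mediator, exposure,
                                covariates = c("sex", "birth_year",
                                               "site"),
                                estimator = c("product", "msm_weighted"),
                                n_boot = 1000, seed = NULL,
                                weight_trunc = 0.99) {
  estimator <- match.arg(estimator)
  if (n_boot < 100) stop("n_boot must be >= 100")
  age_col <- paste0("event_age_", outcome)
  ind_col <- paste0("event_ind_", outcome)
  keep <- stats::complete.cases(
    data[, c(age_col, ind_col, mediator, exposure, covariates)])
  data <- data[keep, ]
  point <- mediation_point(data, outcome, mediator, exposure, covariates,
                           estimator, weight_trunc)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  boots <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("DE", "IE", "TE")))
  failures <- character(0)
  if (estimator == "product") {
    # resampling only permutes rows of fixed design matrices, so build
    # them once and refit with the bare workhorses
    Xm <- build_design(data, c(exposure, covariates))
    M <- data[[mediator]]
    Xo <- cbind(Xm[, -1, drop = FALSE][, exposure, drop = FALSE],
                stats::setNames(data.frame(M), mediator),
                Xm[, setdiff(colnames(Xm), c("(Intercept)", exposure)),
                   drop = FALSE])
    Xo <- as.matrix(Xo)
    yy <- cbind(time = data[[age_col]], status = data[[ind_col]])
    iexp <- match(exposure, colnames(Xm))
    ctl <- survival::coxph.control()
    for (b in seq_len(n_boot)) {
      ix <- sample.int(n, n, replace = TRUE)
      est <- tryCatch({
        beta1 <- .lm.fit(Xm[ix, , drop = FALSE], M[ix])$coefficients[iexp]
        cfit <- quiet_monotone(
          survival::coxph.fit(Xo[ix, , drop = FALSE],
                              yy[ix, , drop = FALSE],
                              strata = NULL, offset = NULL,
                              init = NULL, control = ctl,
                              weights = NULL, method = "efron",
                              rownames = NULL))
        th <- cfit$coefficients
        if (any(!is.finite(th))) stop("outcome model did not converge")
        c(th[1], th[2] * beta1, th[1] + th[2] * beta1)
      }, error = function(e) e)
      if (inherits(est, "error")) failures <- c(failures,
                                                conditionMessage(est))
      else boots[b, ] <- est
    }
  } else {
    for (b in seq_len(n_boot)) {
      ix <- sample.int(n, n, replace = TRUE)
      est <- tryCatch(
        mediation_point(data[ix, ], outcome, mediator, exposure,
                        covariates, estimator, weight_trunc),
        error = function(e) e)
      if (inherits(est, "error")) {
        failures <- c(failures, conditionMessage(est))
      } else {
        boots[b, ] <- c(est$beta_DE, est$beta_IE, est$beta_TE)
      }
    }
  }
  if (length(failures) > 0.1 * n_boot)
    stop(sprintf(
      "bootstrap unstable: %d/%d replicates failed (first error: %s)",
      length(failures), n_boot, failures[1]))
  ok <- stats::complete.cases(boots)
  boots <- boots[ok, , drop = FALSE]
  out <- point
  for (eff in c("DE", "IE", "TE")) {
    v <- boots[, eff]
    out[[paste0("se_", eff)]] <- stats::sd(v)
    out[[paste0("ci95_", eff)]] <-
      unname(stats::quantile(v, c(0.025, 0.975)))
  }
  z <- out$beta_IE / out$se_IE
  out$p_IE <- 2 * stats::pnorm(-abs(z))
  out$n_boot <- nrow(boots)
  out
}

#' Convenience wrapper: mediation from phenotype + genotype tables
#'
#' Collapses the exam-level table with [person_level], merges the
#' carrier-coded SNP, and calls [bootstrap_mediation].
#'
#' @param pheno long-format phenotype table.
#' @param geno a [genotype_matrix].
#' @param snp SNP id (carrier-coded exposure).
#' @param mediator lipid column name.
#' @param outcome disease suffix.
#' @param covariates confounder columns.
#' @param estimator,n_boot,seed,weight_trunc passed to
#'   [bootstrap_mediation].
#' @return A complete `mediation_result`.
#' @export
mediate <- function(pheno, geno, snp, mediator, outcome,
                    covariates = c("sex", "birth_year", "site"),
                    estimator = c("product", "msm_weighted"),
                    n_boot = 1000, seed = NULL, weight_trunc = 0.99) {
  estimator <- match.arg(estimator)
  per <- person_level(pheno)
  per <- merge_geno(per, geno, snp, coding = "carrier")
  bootstrap_mediation(per, outcome, mediator, exposure = snp,
                      covariates = covariates, estimator = estimator,
                      n_boot = n_boot, seed = seed,
                      weight_trunc = weight_trunc)
}

#' Proportion of a total effect transmitted through the mediator
#'
#' `100 beta_IE / beta_TE`, with a flag for inconsistent mediation (the
#' direct and indirect components pulling in opposite directions, which
#' makes the percentage hard to interpret).
#'
#' @param beta_IE,beta_TE indirect and total effects on the same scale.
#' @return List with `percent`, `percent_raw`, `inconsistent`.
#' @examples
#' proportion_mediated(0.015, 0.18)$percent  # 8
#' @export
proportion_mediated <- function(beta_IE, beta_TE) {
  if (!is.finite(beta_TE) || beta_TE == 0)
    stop("total effect must be nonzero")
  raw <- 100 * beta_IE / beta_TE
  beta_DE <- beta_TE - beta_IE
  list(percent = round(raw), percent_raw = raw,
       inconsistent = beta_IE != 0 && beta_DE != 0 &&
         sign(beta_IE) != sign(beta_DE))
}
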