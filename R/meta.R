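# Fixed-effect inverse-variance meta-analysis across cohorts and the
# CI-overlap comparison used to contrast samples.

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-cohort estimates with weights `w_i = 1/se_i^2`:
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = 1/sqrt(sum(w))` (the
#' effect-based scheme used when combining betas with standard errors).
#' Cochran's Q and I-squared are reported as heterogeneity diagnostics
#' but never switch the model.
#'
#' @param beta numeric vector of per-cohort effects, or a data.frame/list
#'   with elements `beta` and `se`.
#' @param se numeric vector of per-cohort standard errors (omit when
#'   `beta` is a data.frame).
#' @param labels optional cohort labels.
#' @return `meta_result`: list with `beta_meta`, `se_meta`, `z`, `p`,
#'   `ci95`, `weights`, `k`, `q_stat`, `i2`.
#' @examples
#' fixed_effect_meta(c(0, 2), c(1, 1))  # beta_meta 1, Q = 2
#' @export
fixed_effect_meta <- function(beta, se = NULL, labels = NULL) {
  if (is.list(beta) && !is.null(beta$beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  beta <- as.numeric(beta); se <- as.numeric(se)
  if (length(beta) == 0L) stop("no studies to combine")
  if (length(se) != length(beta)) stop("beta and se must align")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be positive and finite")
  w <- 1 / se^2
  k <- length(beta)
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  q <- sum(w * (beta - beta_meta)^2)
  i2 <- if (q > 0) max(0, 100 * (q - (k - 1)) / q) else 0
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  structure(list(beta_meta = beta_meta, se_meta = se_meta, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 ci95 = c(beta_meta - 1.96 * se_meta,
                          beta_meta + 1.96 * se_meta),
                 weights = stats::setNames(w, labels), k = k,
                 q_stat = q, i2 = i2,
                 inputs = data.frame(label = labels, beta = beta,
                                     se = se)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "fixed-effect IVW meta-analysis of %d studies\n  beta = %.4g, se = %.4g, z = %.3f, p = %.3g\n  95%% CI (%.4g, %.4g); Q = %.3f, I2 = %.1f%%\n",
    x$k, x$beta_meta, x$se_meta, x$z, x$p, x$ci95[1], x$ci95[2],
    x$q_stat, x$i2))
  invisible(x)
}

extract_beta_se <- function(r) {
  if (inherits(r, "assoc_result")) c(r$beta, r$se)
  else if (inherits(r, "meta_result")) c(r$beta_meta, r$se_meta)
  else if (is.list(r) && !is.null(r$beta) && !is.null(r$se))
    c(r$beta, r$se)
  else stop("expected an assoc_result, meta_result, or list(beta, se)")
}

#' Compare two estimates by CI overlap and a z-test
#'
#' Reports whether the two 95% confidence intervals are disjoint (the
#' conservative criterion for declaring a significant difference between
#' samples) together with the standard two-sample z statistic
#' `(b1 - b2)/sqrt(se1^2 + se2^2)` and its two-sided p-value.
#'
#' @param r1,r2 `assoc_result`, `meta_result`, or `list(beta=, se=)`
#'   objects for the same outcome/exposure.
#' @return List with `disjoint`, `z`, `p`, `diff`, `ci1`, `ci2`.
#' @export
ci_overlap_compare <- function(r1, r2) {
  a <- extract_beta_se(r1); b <- extract_beta_se(r2)
  ci1 <- a[1] + c(-1.96, 1.96) * a[2]
  ci2 <- b[1] + c(-1.96, 1.96) * b[2]
  disjoint <- ci1[1] > ci2[2] || ci2[1] > ci1[2]
  diff <- a[1] - b[1]
  z <- diff / sqrt(a[2]^2 + b[2]^2)
  list(disjoint = disjoint, z = z, p = 2 * stats::pnorm(-abs(z)),
       diff = diff, ci1 = ci1, ci2 = ci2)
}
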