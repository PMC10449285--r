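# Independent oracles used across the suite.

# Full-enumeration Hardy-Weinberg exact test: conditional probability of
# each heterozygote count from direct log-factorials, then sum of
# configurations no more probable than the observed one.
hwe_oracle <- function(counts) {
  n <- sum(counts)
  het <- counts[2]
  R <- 2 * min(counts[1], counts[3]) + het
  if (R == 0) return(1.0)
  hs <- seq(R %% 2, R, by = 2)
  logp <- vapply(hs, function(h) {
    hom_r <- (R - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
      lfactorial(hom_c) + h * log(2) +
      lfactorial(R) + lfactorial(2 * n - R) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(het, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Efron-tie Cox log partial likelihood for a single covariate.
efron_loglik <- function(beta, time, status, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (ut in sort(unique(time[status == 1]))) {
    D <- which(time == ut & status == 1)
    R <- which(time >= ut)
    m <- length(D)
    sw <- sum(w[R])
    swD <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(m) - 1) ll <- ll - log(sw - (l / m) * swD)
  }
  ll
}

# Small random survival dataset with ties (discrete times).  Datasets
# with a monotone partial likelihood (infinite MPLE) are redrawn, since
# no finite maximiser exists for either implementation or oracle there.
random_cox_data <- function(n, beta = 0.5) {
  repeat {
    x <- rbinom(n, 2, 0.3)
    t_event <- rexp(n, 0.1 * exp(beta * x))
    t_cens <- rexp(n, 0.08)
    time <- ceiling(pmin(t_event, t_cens) * 4) / 4   # induce ties
    status <- as.integer(t_event <= t_cens)
    if (sum(status) < 3 || var(x) == 0) next
    fit <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(time, status) ~ x, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)) || abs(coef(fit)) > 4) next
    return(data.frame(time = time, status = status, x = x))
  }
}

# Tiny simulation settings shared by several tests.
tiny_config <- function(...) {
  sim_config(n_cohorts = 2, n_per_cohort = 400, ...)
}

# Single-SNP-causal configuration for clean parameter recovery: only the
# event SNP affects the mediator lipid, with carrier-coded effects.
recovery_config <- function(n, beta1 = -6, theta1 = 0.1,
                            theta2 = -0.0025, lambda0 = 0.0015,
                            seed = 1L, n_exams = c(1, 1)) {
  snps <- c("rs1051921", "rs17145750", "rs6967028", "rs11760752")
  betas <- matrix(0, 4, 4, dimnames = list(snps,
                                           c("TG", "HDL_C", "LDL_C", "TC")))
  betas["rs17145750", "TG"] <- beta1
  sim_config(n_cohorts = 1, n_per_cohort = n,
             snp_lipid_betas = betas, snp_effect_coding = "carrier",
             n_exams_range = n_exams,
             diseases = list(AD = list(theta1 = theta1, theta2 = theta2,
                                       mediator = "TG",
                                       lambda0 = lambda0)),
             seed = seed)
}

simulate_one <- function(config) {
  mc <- simulate_multicohort(config)
  mc[[1]]
}
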