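# Gaussian estimating-equation fit with cluster-robust (sandwich)
# variance.  The working correlation acts within persons (repeated
# exams): under independence the point estimates equal ordinary least
# squares on the stacked person-exam rows, while exchangeable adds a
# common within-person correlation estimated by moments.  The reported
# variance is always the sandwich estimator with the (possibly coarser)
# cluster id — here the family — as the independence unit, so standard
# errors stay valid whatever the true within-family correlation.
# Persons must nest within clusters.

gee_gaussian <- function(y, X, cluster_id, corr_id = cluster_id,
                         working_corr = c("independence", "exchangeable"),
                         max_iter = 25, tol = 1e-10) {
  working_corr <- match.arg(working_corr)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || length(cluster_id) != n || length(corr_id) != n)
    stop("inputs misaligned")
  clusters <- split(seq_len(n), cluster_id)
  if (length(clusters) < 2L)
    stop("need at least 2 clusters for cluster-robust variance")
  groups <- split(seq_len(n), corr_id)
  # nesting check: each correlation group sits inside one cluster
  g2c <- vapply(groups, function(ix) length(unique(cluster_id[ix])), 0L)
  if (any(g2c > 1L)) stop("correlation groups must nest within clusters")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  rho <- 0
  wx <- function(Xi, ni, rho) {
    # rows of R_i^{-1} X_i for exchangeable R_i, up to the 1/sigma^2 scale
    if (ni == 1 || rho == 0) return(Xi)
    c1 <- 1 / (1 - rho)
    c2 <- rho / ((1 - rho) * (1 + (ni - 1) * rho))
    c1 * Xi - c2 * matrix(colSums(Xi), ni, ncol(Xi), byrow = TRUE)
  }
  if (working_corr == "exchangeable") {
    for (it in seq_len(max_iter)) {
      r <- y - X %*% beta
      sigma2 <- sum(r^2) / (n - p)
      num <- 0; den <- 0
      for (ix in groups) {
        ni <- length(ix)
        if (ni > 1) {
          ri <- r[ix]
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          den <- den + ni * (ni - 1) / 2
        }
      }
      rho_new <- if (den > 0) max(min(num / (den * sigma2), 0.99), -0.49)
        else 0
      A <- matrix(0, p, p); b <- numeric(p)
      for (ix in groups) {
        Xi <- X[ix, , drop = FALSE]
        WXi <- wx(Xi, length(ix), rho_new)
        A <- A + crossprod(Xi, WXi)
        b <- b + crossprod(WXi, y[ix])
      }
      beta_new <- solve(A, b)
      done <- max(abs(beta_new - beta)) < tol && abs(rho_new - rho) < tol
      beta <- beta_new; rho <- rho_new
      if (done) break
    }
  }
  # sandwich: V = B^{-1} M B^{-1}, B = sum_g X'W X over correlation
  # groups, M = sum_c u_c u_c' with u_c the summed scores of cluster c
  r <- as.numeric(y - X %*% beta)
  B <- matrix(0, p, p)
  u_cluster <- matrix(0, length(clusters), p,
                      dimnames = list(names(clusters), NULL))
  for (gi in seq_along(groups)) {
    ix <- groups[[gi]]
    Xi <- X[ix, , drop = FALSE]
    WXi <- if (working_corr == "independence") Xi
      else wx(Xi, length(ix), rho)
    B <- B + crossprod(Xi, WXi)
    cl <- as.character(cluster_id[ix[1L]])
    u_cluster[cl, ] <- u_cluster[cl, ] + as.numeric(crossprod(WXi, r[ix]))
  }
  M <- crossprod(u_cluster)
  Binv <- solve(B)
  V <- Binv %*% M %*% t(Binv)
  beta <- as.numeric(beta)
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = V, working_corr = working_corr,
       rho = rho, n_obs = n, n_clusters = length(clusters),
       residuals = r)
}
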