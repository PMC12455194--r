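# Shared oracle helpers, independent of the package's own code paths.

# multivariate normal log-density, assembled from base operations
log_dmvnorm_oracle <- function(x, mu, Sigma) {
  p <- length(mu)
  d <- as.numeric(x - mu)
  -0.5 * (p * log(2 * pi) +
            as.numeric(determinant(Sigma, log = TRUE)$modulus) +
            drop(t(d) %*% solve(Sigma) %*% d))
}

# damped Newton-Raphson logistic regression
logistic_newton_oracle <- function(X, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, X)
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    g <- crossprod(X, y - p)
    W <- p * (1 - p)
    H <- crossprod(X, X * W)
    step <- drop(solve(H, g))
    damp <- 1
    ll <- sum(y * log(p) + (1 - y) * log(1 - p))
    repeat {
      bn <- b + damp * step
      pn <- 1 / (1 + exp(-drop(X %*% bn)))
      lln <- sum(y * log(pn) + (1 - y) * log(1 - pn))
      if (lln >= ll - 1e-12 || damp < 1e-6) break
      damp <- damp / 2
    }
    b <- bn
    if (sqrt(sum(g^2)) < tol) break
  }
  drop(b)
}

# difference-score multivariate regression: the closed-form ML solution
# of the just-identified bivariate LCS
difference_score_oracle <- function(data) {
  D <- cbind(data$thal_t1_ml - data$thal_t2_ml,
             data$hipp_t1_ml - data$hipp_t2_ml)
  fit <- stats::lm(D ~ thal_t1_ml + hipp_t1_ml, data = data)
  n <- nrow(data)
  list(coef = stats::coef(fit),
       resid_cov = crossprod(stats::resid(fit)) / (n - 1),
       exog_mean = colMeans(data[, c("thal_t1_ml", "hipp_t1_ml")]),
       exog_cov = stats::cov(data[, c("thal_t1_ml", "hipp_t1_ml")]))
}

# Monte-Carlo standard errors for comparing sample moments with analytic
# moments: SE of a sample covariance element under approximate normality
mc_se_cov <- function(S, n) {
  sqrt((outer(diag(S), diag(S)) + S^2) / n)
}
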