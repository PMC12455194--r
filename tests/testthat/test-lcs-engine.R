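# Structural engine: implied moments, discrepancy, ML / FIML /
# multigroup fitting, oracle equivalences, standard errors.

test_that("saturated spec maps parameters to implied moments verbatim", {
  spec <- saturated_spec(c("a", "b"))
  theta <- c(mean_a = 1.5, var_a = 2, cov_a_b = 0.3, mean_b = -1,
             var_b = 0.5)
  imp <- implied_moments(spec, theta)
  expect_equal(unname(imp$mean), c(1.5, -1))
  expect_equal(unname(imp$cov),
               matrix(c(2, 0.3, 0.3, 0.5), 2, 2))
})

test_that("baseline block of the bivariate LCS is exogenous", {
  spec <- lcs_bivariate_spec()
  base <- c(mu_t = 14, mu_h = 7, phi_t = 1.8, phi_h = 0.7, phi_ht = 0.75,
            psi_t = 0.08, psi_h = 0.02, rho_ht = 0.03,
            alpha_t = 0.2, alpha_h = 0.1)
  for (g in list(c(0, 0, 0, 0), c(0.3, -0.2, 0.1, 0.4))) {
    theta <- c(base, beta_t = g[1], beta_h = g[2],
               gamma_t_dh = g[3], gamma_h_dt = g[4])
    imp <- implied_moments(spec, theta)
    expect_equal(unname(imp$cov[c("thal_t1_ml", "hipp_t1_ml"),
                                c("thal_t1_ml", "hipp_t1_ml")]),
                 matrix(c(1.8, 0.75, 0.75, 0.7), 2, 2),
                 tolerance = 1e-12)
  }
  expect_error(implied_moments(spec, c(base, beta_t = NA, beta_h = 0,
                                       gamma_t_dh = 0, gamma_h_dt = 0)),
               "non-finite")
})

test_that("implied moments match a large generator sample", {
  cfg <- preset_bivariate_lcs(seed = 21)
  gt <- lcs_generating_theta(cfg)
  d <- generate_longitudinal(cfg, 500000)
  obs <- gt$spec$observed
  imp <- implied_moments(gt$spec, gt$theta)
  S <- stats::cov(d[, obs])
  tol <- 3 * mc_se_cov(imp$cov, nrow(d))
  expect_true(all(abs(S - imp$cov) < tol + 1e-8))
})

test_that("discrepancy is zero at the sample moments and matches hand math", {
  spec <- saturated_spec(c("x", "y"))
  m <- c(x = 1, y = 2)
  S <- matrix(c(2, 0.5, 0.5, 1), 2, 2, dimnames = list(c("x", "y"),
                                                       c("x", "y")))
  theta_perfect <- c(mean_x = 1, var_x = 2, cov_x_y = 0.5, mean_y = 2,
                     var_y = 1)
  expect_equal(ml_discrepancy(spec, theta_perfect, m, S), 0,
               tolerance = 1e-12)
  # hand computation at a different theta
  theta <- c(mean_x = 0.5, var_x = 1.5, cov_x_y = 0.2, mean_y = 2.5,
             var_y = 0.8)
  Sg <- matrix(c(1.5, 0.2, 0.2, 0.8), 2, 2)
  dlt <- c(1 - 0.5, 2 - 2.5)
  f_hand <- log(det(Sg)) + sum(diag(solve(Sg) %*% S)) +
    drop(t(dlt) %*% solve(Sg) %*% dlt) - log(det(S)) - 2
  expect_equal(ml_discrepancy(spec, theta, m, S), f_hand,
               tolerance = 1e-10)
})

test_that("discrepancy is invariant to a simultaneous variable reordering", {
  m <- c(x = 1, y = 2)
  S <- matrix(c(2, 0.5, 0.5, 1), 2, 2, dimnames = list(c("x", "y"),
                                                       c("x", "y")))
  theta <- c(mean_x = 0.5, var_x = 1.5, cov_x_y = 0.2, mean_y = 2.5,
             var_y = 0.8)
  f1 <- ml_discrepancy(saturated_spec(c("x", "y")), theta, m, S)
  theta2 <- c(mean_y = 2.5, var_y = 0.8, cov_y_x = 0.2, mean_x = 0.5,
              var_x = 1.5)
  f2 <- ml_discrepancy(saturated_spec(c("y", "x")), theta2,
                       m[c("y", "x")], S[c("y", "x"), c("y", "x")])
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("singular implied covariance is rejected with a diagnostic", {
  spec <- saturated_spec(c("x", "y"))
  theta <- c(mean_x = 0, var_x = 1, cov_x_y = 1, mean_y = 0, var_y = 1)
  m <- c(x = 0, y = 0)
  S <- diag(2); dimnames(S) <- list(c("x", "y"), c("x", "y"))
  expect_error(ml_discrepancy(spec, theta, m, S), "singular|indefinite")
})

test_that("saturated fit reproduces sample moments with zero chi-square", {
  set.seed(22)
  d <- data.frame(a = rnorm(200, 5, 2), b = rnorm(200, -1, 1))
  d$b <- d$b + 0.4 * d$a
  fit <- fit_ml(saturated_spec(c("a", "b")), d)
  expect_lt(fit$chi_square, 1e-8)
  expect_equal(fit$estimates[["mean_a"]], mean(d$a), tolerance = 1e-8)
  expect_equal(fit$estimates[["var_a"]], stats::var(d$a),
               tolerance = 1e-7)
  expect_equal(fit$estimates[["cov_a_b"]], stats::cov(d$a, d$b),
               tolerance = 1e-7)
  expect_equal(fit$df, 0)
})

test_that("just-identified LCS ML fit equals difference-score regression", {
  set.seed(23)
  for (rep in 1:3) {
    d <- generate_longitudinal(preset_bivariate_lcs(), 400)
    fit <- fit_ml(lcs_bivariate_spec(), d, se = FALSE)
    o <- difference_score_oracle(d)
    expect_lt(fit$chi_square, 1e-6)
    expect_equal(fit$estimates[["beta_t"]], unname(o$coef["thal_t1_ml", 1]),
                 tolerance = 1e-6)
    expect_equal(fit$estimates[["beta_h"]], unname(o$coef["hipp_t1_ml", 2]),
                 tolerance = 1e-6)
    expect_equal(fit$estimates[["gamma_t_dh"]], unname(o$coef["thal_t1_ml", 2]),
                 tolerance = 1e-6)
    expect_equal(fit$estimates[["gamma_h_dt"]], unname(o$coef["hipp_t1_ml", 1]),
                 tolerance = 1e-6)
    expect_equal(fit$estimates[["alpha_t"]], unname(o$coef["(Intercept)", 1]),
                 tolerance = 1e-6)
    expect_equal(fit$estimates[["rho_ht"]], o$resid_cov[1, 2],
                 tolerance = 1e-6)
    expect_equal(fit$estimates[["phi_ht"]], o$exog_cov[1, 2],
                 tolerance = 1e-6)
    expect_equal(fit$estimates[["mu_t"]], unname(o$exog_mean[1]),
                 tolerance = 1e-6)
  }
})

test_that("negating the change convention negates paths and intercepts", {
  set.seed(24)
  d <- generate_longitudinal(preset_bivariate_lcs(), 300)
  fa <- fit_ml(lcs_bivariate_spec(convention = "atrophy"), d, se = FALSE)
  fg <- fit_ml(lcs_bivariate_spec(convention = "growth"), d, se = FALSE)
  for (lab in c("beta_t", "beta_h", "gamma_t_dh", "gamma_h_dt",
                "alpha_t", "alpha_h"))
    expect_equal(fa$estimates[[lab]], -fg$estimates[[lab]],
                 tolerance = 1e-6)
  for (lab in c("phi_ht", "rho_ht", "psi_t", "psi_h", "mu_t", "mu_h"))
    expect_equal(fa$estimates[[lab]], fg$estimates[[lab]],
                 tolerance = 1e-6)
  expect_equal(fa$loglik, fg$loglik, tolerance = 1e-8)
})

test_that("under-identified or undersized problems are rejected", {
  d <- generate_longitudinal(preset_bivariate_lcs(seed = 25), 10)
  expect_error(fit_ml(lcs_bivariate_spec(), d), "complete cases")
})

test_that("FIML equals complete-data ML when nothing is missing", {
  set.seed(26)
  d <- generate_longitudinal(preset_bivariate_lcs(), 350)
  f1 <- fit_ml(lcs_bivariate_spec(), d, se = FALSE)
  f2 <- fit_fiml(lcs_bivariate_spec(), d, se = FALSE)
  expect_lt(abs(f1$loglik - f2$loglik) / abs(f1$loglik), 1e-8)
  expect_lt(max(abs(f1$estimates - f2$estimates)), 1e-6)
})

test_that("FIML log-likelihood equals hand-assembled marginal densities", {
  set.seed(27)
  d <- generate_longitudinal(preset_bivariate_lcs(), 120)
  d$hipp_t2_ml[1:60] <- NA
  spec <- lcs_bivariate_spec()
  fit <- fit_fiml(spec, d, se = FALSE)
  imp <- implied_moments(spec, fit$estimates)
  obs <- spec$observed
  ll <- 0
  for (i in seq_len(nrow(d))) {
    pres <- obs[!is.na(d[i, obs])]
    ll <- ll + log_dmvnorm_oracle(unlist(d[i, pres]), imp$mean[pres],
                                  imp$cov[pres, pres, drop = FALSE])
  }
  expect_equal(fit$loglik, unname(ll), tolerance = 1e-6)
})

test_that("FIML rejects a variable that is missing everywhere", {
  d <- generate_longitudinal(preset_bivariate_lcs(seed = 28), 60)
  d$hipp_t2_ml <- NA_real_
  expect_error(fit_fiml(lcs_bivariate_spec(), d), "missing in every row")
})

test_that("multigroup with duplicated data reproduces the one-group fit", {
  set.seed(29)
  d <- generate_longitudinal(preset_bivariate_lcs(), 250)
  single <- fit_ml(lcs_bivariate_spec(), d, se = FALSE)
  dd <- rbind(cbind(d, group = "g1"), cbind(d, group = "g2"))
  free <- fit_multigroup(lcs_bivariate_spec(), dd, "group", se = FALSE)
  for (g in c("g1", "g2"))
    expect_lt(max(abs(free$per_group[[g]]$estimates - single$estimates)),
              1e-5)
  eq <- fit_multigroup(lcs_bivariate_spec(), dd, "group",
                       equal = lcs_bivariate_spec()$labels, se = FALSE)
  expect_lt(max(abs(eq$per_group$g1$estimates - single$estimates)), 1e-5)
  expect_error(fit_multigroup(lcs_bivariate_spec(), dd, "group",
                              equal = "nope"), "unknown labels")
  expect_error(fit_multigroup(lcs_bivariate_spec(), cbind(d, group = "g1"),
                              "group"), "at least two groups")
})

test_that("standard errors are non-negative and match the normal-theory
           closed form for a saturated variance", {
  set.seed(30)
  n <- 2000
  d <- data.frame(x = rnorm(n, 3, 1.7))
  fit <- fit_ml(saturated_spec("x"), d)
  expect_true(all(fit$ses >= 0 | is.na(fit$ses)))
  s2 <- fit$estimates[["var_x"]]
  expect_lt(abs(fit$ses[["var_x"]] - s2 * sqrt(2 / n)) /
              (s2 * sqrt(2 / n)), 0.05)
  # mean SE: classical sd/sqrt(n)
  expect_lt(abs(fit$ses[["mean_x"]] - sqrt(s2 / n)) / sqrt(s2 / n), 0.05)
})

test_that("model spec JSON round-trips and fits identically", {
  spec <- lcs_bivariate_spec()
  js <- lcs_spec_to_json(spec)
  spec2 <- lcs_spec_from_json(js)
  d <- generate_longitudinal(preset_bivariate_lcs(seed = 31), 200)
  f1 <- fit_ml(spec, d, se = FALSE)
  f2 <- fit_ml(spec2, d, se = FALSE)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-10)
})

test_that("tidy export carries Wald z and p per group", {
  d <- generate_longitudinal(preset_multigroup_lcs(seed = 32), 400)
  fit <- fit_multigroup(lcs_bivariate_spec(), d, "group")
  tab <- tidy_lcs_fit(fit)
  expect_setequal(unique(tab$group), c("Female", "Male"))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
  expect_equal(tab$z, tab$estimate / tab$se, tolerance = 1e-12)
})
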