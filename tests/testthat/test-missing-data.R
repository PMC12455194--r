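# Propensity scores, caliper matching, PMM imputation, Rubin pooling.

test_that("null-model propensity scores sit at the group proportion", {
  set.seed(61)
  n <- 2000
  d <- data.frame(x = rnorm(n), g = rbinom(n, 1, 0.5))
  ps <- estimate_propensity(d, "x", "g")
  expect_lt(abs(mean(ps$scores) - mean(d$g)), 1e-8)
  expect_lt(abs(ps$coefficients[["(Intercept)"]]), 0.15)
  expect_lt(abs(ps$coefficients[["x"]]), 0.15)
  # intercept-only model: every score equals the prevalence
  ps0 <- estimate_propensity(d, character(0), "g")
  expect_equal(ps0$scores, rep(mean(d$g), n), tolerance = 1e-10)
})

test_that("logistic coefficients match a damped Newton oracle", {
  set.seed(62)
  n <- 20
  X <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, stats::plogis(0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  d <- data.frame(x1 = X[, 1], x2 = X[, 2], g = y)
  ps <- estimate_propensity(d, c("x1", "x2"), "g")
  b_oracle <- logistic_newton_oracle(X, y)
  expect_equal(unname(ps$coefficients), unname(b_oracle),
               tolerance = 1e-6)
})

test_that("complete separation is rejected with a diagnostic", {
  d <- data.frame(x = c(-(5:1), 1:5), g = rep(0:1, each = 5))
  expect_error(estimate_propensity(d, "x", "g"), "separation")
})

test_that("matching: identical scores give full match, caliper 0 gives none", {
  s <- c(0.2, 0.4, 0.6, 0.2, 0.4, 0.6)
  g <- c(1, 1, 1, 0, 0, 0)
  mr <- match_nearest(s, g, caliper = 0.001, seed = 1)
  expect_equal(mr$match_rate, 1)
  expect_equal(nrow(mr$pairs), 3)
  s2 <- c(0.1, 0.2, 0.3, 0.15, 0.25, 0.35)
  mr0 <- match_nearest(s2, g, caliper = 0, seed = 1)
  expect_equal(nrow(mr0$pairs), 0)
  expect_equal(mr0$match_rate, 0)
})

test_that("3-vs-3 toy matching reproduces the enumerated pairing", {
  s <- c(0.1, 0.2, 0.9, 0.15, 0.21, 0.5)
  g <- c(1, 1, 1, 0, 0, 0)
  mr <- match_nearest(s, g, caliper = 0.06, seed = 1)
  expect_equal(nrow(mr$pairs), 2)
  got <- mr$pairs[order(mr$pairs$treated), c("treated", "control")]
  expect_equal(got$treated, c(1, 2))
  expect_equal(got$control, c(4, 5))
  expect_equal(mr$match_rate, 2 / 3)
})

test_that("matching is injective and respects the caliper", {
  set.seed(63)
  n <- 400
  s <- runif(n)
  g <- rbinom(n, 1, 0.3)
  mr <- match_nearest(s, g, caliper = 0.02, seed = 2)
  expect_false(anyDuplicated(mr$pairs$treated) > 0)
  expect_false(anyDuplicated(mr$pairs$control) > 0)
  expect_true(all(abs(mr$pairs$treated_score -
                        mr$pairs$control_score) <= 0.02))
  expect_true(all(g[mr$pairs$treated] == 1))
  expect_true(all(g[mr$pairs$control] == 0))
})

test_that("PMM with nothing missing returns identical copies", {
  d <- generate_longitudinal(preset_bivariate_lcs(seed = 64), 50)
  imp <- impute_pmm(d, "hipp_t2_ml", c("thal_t1_ml", "hipp_t1_ml"),
                    m = 3, seed = 1)
  expect_equal(imp$m, 3)
  for (k in 1:3) expect_identical(imp$imputations[[k]], d)
})

test_that("every imputed value is an observed donor value", {
  set.seed(65)
  d <- generate_longitudinal(preset_bivariate_lcs(), 300)
  msk <- apply_missingness(d, missingness_spec(
    "MCAR", c("hipp_t2_ml"), rate = 0.3, seed = 66))
  obs_vals <- msk$hipp_t2_ml[!is.na(msk$hipp_t2_ml)]
  imp <- impute_pmm(msk, "hipp_t2_ml", c("thal_t1_ml", "hipp_t1_ml"),
                    m = 5, seed = 2)
  for (k in 1:5) {
    filled <- imp$imputations[[k]]$hipp_t2_ml[is.na(msk$hipp_t2_ml)]
    expect_true(all(filled %in% obs_vals))
    expect_false(anyNA(imp$imputations[[k]]$hipp_t2_ml))
    # only originally-missing cells changed
    expect_identical(imp$imputations[[k]]$hipp_t2_ml[!is.na(msk$hipp_t2_ml)],
                     obs_vals)
  }
})

test_that("k = 1 without parameter draws is deterministic nearest-value", {
  set.seed(67)
  d <- generate_longitudinal(preset_bivariate_lcs(), 200)
  msk <- apply_missingness(d, missingness_spec(
    "MCAR", "hipp_t2_ml", rate = 0.25, seed = 68))
  i1 <- impute_pmm(msk, "hipp_t2_ml", c("thal_t1_ml", "hipp_t1_ml"),
                   m = 2, k_donors = 1, draw_params = FALSE, seed = 3)
  expect_identical(i1$imputations[[1]], i1$imputations[[2]])
  # oracle: nearest observed prediction
  obs <- !is.na(msk$hipp_t2_ml)
  f <- lm(hipp_t2_ml ~ thal_t1_ml + hipp_t1_ml, data = msk[obs, ])
  yhat_obs <- stats::fitted(f)
  yhat_mis <- stats::predict(f, msk[!obs, ])
  donor <- vapply(yhat_mis, function(p)
    msk$hipp_t2_ml[obs][which.min(abs(yhat_obs - p))], numeric(1))
  expect_equal(i1$imputations[[1]]$hipp_t2_ml[!obs], unname(donor))
})

test_that("MCAR pooled mean is consistent with the complete data", {
  set.seed(69)
  d <- generate_longitudinal(preset_bivariate_lcs(), 2000)
  msk <- apply_missingness(d, missingness_spec(
    "MCAR", "hipp_t2_ml", rate = 0.3, seed = 70))
  imp <- impute_pmm(msk, "hipp_t2_ml", c("thal_t1_ml", "hipp_t1_ml"),
                    m = 20, seed = 4)
  ests <- vapply(imp$imputations, function(t) mean(t$hipp_t2_ml),
                 numeric(1))
  vars <- vapply(imp$imputations, function(t)
    stats::var(t$hipp_t2_ml) / nrow(t), numeric(1))
  pooled <- pool_rubin(matrix(ests, ncol = 1), matrix(vars, ncol = 1))
  expect_lt(abs(pooled$estimate - mean(d$hipp_t2_ml)), 2 * pooled$se)
})

test_that("Rubin pooling: hand case, degenerate case, inequality", {
  p <- pool_rubin(matrix(c(1, 2), ncol = 1), matrix(c(0.1, 0.1), ncol = 1))
  expect_equal(p$estimate, 1.5)
  expect_equal(p$se^2, 0.1 + 1.5 * 0.5, tolerance = 1e-12)
  ident <- pool_rubin(matrix(c(2, 2, 2), ncol = 1),
                      matrix(c(0.3, 0.3, 0.3), ncol = 1))
  expect_equal(ident$between_var, 0)
  expect_equal(ident$se, sqrt(0.3), tolerance = 1e-6)
  set.seed(71)
  Q <- matrix(rnorm(30), 10, 3)
  U <- matrix(runif(30, 0.1, 0.5), 10, 3)
  pr <- pool_rubin(Q, U)
  expect_true(all(pr$se^2 >= colMeans(U)))
  expect_error(pool_rubin(Q, U[, 1:2]), "mismatched")
  # finite complete-data df shrinks the Barnard-Rubin df
  pr_fin <- pool_rubin(Q, U, dfcom = 50)
  expect_true(all(pr_fin$df <= pr$df))
  expect_true(all(pr_fin$df <= 50))
})

test_that("imputation rejects impossible inputs", {
  d <- generate_longitudinal(preset_bivariate_lcs(seed = 72), 30)
  d$hipp_t2_ml[1:28] <- NA
  expect_error(impute_pmm(d, "hipp_t2_ml",
                          c("thal_t1_ml", "hipp_t1_ml", "thal_t2_ml",
                            "hipp_t1_ml")),
               "fewer observed rows|predictors must be observed")
  expect_error(impute_pmm(d, "nope", "thal_t1_ml"), "unknown column")
})
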