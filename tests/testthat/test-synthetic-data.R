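# Synthetic cohort generators: schema, degenerate limits, calibration to
# the configured moments, seed determinism, missingness machinery.

test_that("empty cross-sectional cohort keeps the full schema", {
  cfg <- cross_sectional_config(n = 0, seed = 1)
  d <- generate_cross_sectional(cfg)
  expect_equal(nrow(d), 0)
  expect_true(all(c("participant_id", "age_y", "sex", "thal_ml",
                    "hipp_ml", "etiv_ml", "dsst", "tmt_a_s", "tmt_b_s",
                    "nmt_score", "cog_composite") %in% names(d)))
})

test_that("noise-free composite equals the deterministic linear predictor", {
  cfg <- cross_sectional_config(n = 50, cognition_resid_sd = 0, seed = 2)
  d <- generate_cross_sectional(cfg)
  b <- cs_default_coefs()
  lin <- 0.817 + as.matrix(d[, names(b)]) %*% b
  expect_equal(d$cog_composite, drop(lin), tolerance = 1e-12)
})

test_that("non-positive-definite volume correlation matrix is rejected", {
  R <- diag(11); R[1, 2] <- R[2, 1] <- 1.2
  expect_error(cross_sectional_config(n = 10, volume_corr = R),
               "positive definite")
  R2 <- diag(11); R2[1, 2] <- 0.5
  expect_error(cross_sectional_config(n = 10, volume_corr = R2),
               "symmetric")
})

test_that("large-sample thalamus moments match the configured values", {
  cfg <- cross_sectional_config(n = 100000, seed = 3)
  d <- generate_cross_sectional(cfg)
  se_mean <- 1.34 / sqrt(nrow(d))
  expect_lt(abs(mean(d$thal_ml) - 14.95), 3 * se_mean)
  expect_lt(abs(stats::sd(d$thal_ml) - 1.34) / 1.34, 0.02)
})

test_that("generated predictor moments match the analytic design moments", {
  cfg <- cross_sectional_config(n = 200000, seed = 4)
  d <- generate_cross_sectional(cfg)
  pm <- cs_predictor_moments(cfg)
  sub <- c("thal_ml", "hipp_ml", "frontal_gm_ml", "age_y", "sex_male")
  S <- stats::cov(d[, sub])
  A <- pm$cov[sub, sub]
  tol <- 3 * mc_se_cov(A + diag(1e-12, length(sub)), nrow(d))
  expect_true(all(abs(S - A) < tol + 1e-8))
  m_tol <- 3 * sqrt(diag(A)) / sqrt(nrow(d))
  expect_true(all(abs(colMeans(d[, sub]) - pm$mean[sub]) < m_tol))
})

test_that("degenerate LCS model yields the intercepts exactly", {
  cfg <- lcs_generator_config(
    self_feedback = c(thal = 0, hipp = 0),
    cross_coupling = c(t_dh = 0, h_dt = 0),
    change_intercepts = c(thal = 0.213, hipp = 0.155),
    change_resid_cov = matrix(0, 2, 2), seed = 5)
  d <- generate_longitudinal(cfg, 40)
  expect_equal(d$thal_t1_ml - d$thal_t2_ml, rep(0.213, 40),
               tolerance = 1e-12)
  expect_equal(d$hipp_t1_ml - d$hipp_t2_ml, rep(0.155, 40),
               tolerance = 1e-12)
})

test_that("longitudinal sample mean of hippocampal change is calibrated", {
  cfg <- preset_bivariate_lcs(seed = 6)
  d <- generate_longitudinal(cfg, 653)
  dh <- d$hipp_t1_ml - d$hipp_t2_ml
  expect_lt(abs(mean(dh) - 0.155), 3 * 0.136 / sqrt(653))
})

test_that("generator moments match the implied model moments", {
  for (preset in list(preset_bivariate_lcs(seed = 7),
                      preset_multivariate_lcs(seed = 8))) {
    d <- generate_longitudinal(preset, 200000)
    gt <- lcs_generating_theta(preset)
    imp <- implied_moments(gt$spec, gt$theta)
    obs <- gt$spec$observed
    S <- stats::cov(d[, obs])
    tol <- 3 * mc_se_cov(imp$cov, nrow(d))
    expect_true(all(abs(S - imp$cov) < tol + 1e-8))
    m_tol <- 3 * sqrt(diag(imp$cov)) / sqrt(nrow(d))
    expect_true(all(abs(colMeans(d[, obs]) - imp$mean) < m_tol))
  }
})

test_that("atrophy-positive sign convention holds row by row", {
  d <- generate_longitudinal(preset_bivariate_lcs(seed = 9), 500)
  # follow-up = baseline - change by construction; the observed change
  # must therefore be positive on average (volume loss)
  expect_gt(mean(d$thal_t1_ml - d$thal_t2_ml), 0)
  expect_gt(mean(d$hipp_t1_ml - d$hipp_t2_ml), 0)
  expect_equal(mean(d$hipp_t2_ml),
               mean(d$hipp_t1_ml) - mean(d$hipp_t1_ml - d$hipp_t2_ml),
               tolerance = 1e-12)
})

test_that("same seed reproduces byte-identical cohorts, new seeds differ", {
  a <- generate_longitudinal(preset_bivariate_lcs(seed = 11), 100)
  b <- generate_longitudinal(preset_bivariate_lcs(seed = 11), 100)
  c3 <- generate_longitudinal(preset_bivariate_lcs(seed = 12), 100)
  expect_identical(a, b)
  expect_false(identical(a$thal_t1_ml, c3$thal_t1_ml))
  x <- generate_cross_sectional(cross_sectional_config(n = 50, seed = 13))
  y <- generate_cross_sectional(cross_sectional_config(n = 50, seed = 13))
  expect_identical(x, y)
})

test_that("group overrides must cover every declared group", {
  expect_error(lcs_generator_config(
    group_overrides = list(proportions = c(A = 0.5, B = 0.5),
                           params = list(A = list()))),
    "cover every declared group")
})

test_that("missingness: identity, saturation and MCAR counts", {
  d <- generate_longitudinal(preset_bivariate_lcs(seed = 14), 4348)
  id <- apply_missingness(d, missingness_spec(
    "MCAR", c("thal_t2_ml", "hipp_t2_ml"), rate = 0, seed = 1))
  expect_equal(id$thal_t2_ml, d$thal_t2_ml)
  sat <- apply_missingness(d, missingness_spec(
    "MCAR", c("thal_t2_ml", "hipp_t2_ml"), rate = 1, seed = 1))
  expect_true(all(is.na(sat$thal_t2_ml)))
  expect_true(all(is.na(sat$hipp_t2_ml)))
  # original untouched
  expect_false(anyNA(d$thal_t2_ml))
  msk <- apply_missingness(d, missingness_spec(
    "MCAR", c("thal_t2_ml", "hipp_t2_ml"), rate = 0.85, jointly = TRUE,
    seed = 15))
  ncc <- sum(stats::complete.cases(msk[, c("thal_t2_ml", "hipp_t2_ml")]))
  expect_gte(ncc, stats::qbinom(0.005, 4348, 0.15))
  expect_lte(ncc, stats::qbinom(0.995, 4348, 0.15))
  expect_error(apply_missingness(d, missingness_spec(
    "MCAR", "nonexistent", rate = 0.5)), "unknown target")
})

test_that("MAR missingness tracks its logistic predictors", {
  d <- generate_longitudinal(preset_bivariate_lcs(seed = 16), 5000)
  msk <- apply_missingness(d, missingness_spec(
    "MAR", "hipp_t2_ml", rate = 0.3,
    mar_predictors = c(thal_t1_ml = 2), seed = 17))
  miss <- is.na(msk$hipp_t2_ml)
  expect_lt(abs(mean(miss) - 0.3), 0.03)
  expect_gt(mean(d$thal_t1_ml[miss]), mean(d$thal_t1_ml[!miss]))
  expect_error(missingness_spec("MAR", "x", 0.5), "requires named")
})
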