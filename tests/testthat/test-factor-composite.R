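# Cognitive composite: standardization, the three-indicator closed form,
# regression-method scores, orientation handling, generator calibration.

test_that("standardize centers and scales with the n-1 denominator", {
  d <- data.frame(x = c(1, 2, 3), y = c(10, 20, 40))
  z <- standardize(d, c("x", "y"))
  expect_equal(z$x, c(-1, 0, 1))
  expect_equal(mean(z$y), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$y), 1, tolerance = 1e-12)
  z2 <- standardize(z, "x")
  expect_equal(z2$x, z$x, tolerance = 1e-12)
  expect_error(standardize(data.frame(x = rep(1, 5)), "x"),
               "zero variance")
  expect_error(standardize(d, "zz"), "unknown column")
})

test_that("equicorrelated triad yields the closed-form loadings", {
  R <- matrix(0.49, 3, 3); diag(R) <- 1
  sol <- efa_one_factor(R)
  expect_equal(unname(sol$loadings), rep(0.7, 3), tolerance = 1e-12)
  expect_equal(sol$variance_explained, 0.49, tolerance = 1e-12)
  expect_equal(unname(sol$uniquenesses), rep(1 - 0.49, 3),
               tolerance = 1e-12)
  Rp <- matrix(1, 3, 3)
  sol1 <- efa_one_factor(Rp)
  expect_equal(unname(sol1$loadings), rep(1, 3), tolerance = 1e-6)
  expect_equal(sol1$variance_explained, 1, tolerance = 1e-6)
})

test_that("negative triad radicand is rejected with a diagnostic", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.5
  R[1, 3] <- R[3, 1] <- -0.5
  R[2, 3] <- R[3, 2] <- 0.5
  expect_error(efa_one_factor(R), "radicand")
})

test_that("closed form agrees with the iterative ML factor fit", {
  lam <- c(0.58, -0.69, -0.82)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(R) <- list(c("d", "a", "b"), c("d", "a", "b"))
  sol <- efa_one_factor(R, anchor = "d")
  fa <- stats::factanal(covmat = R, factors = 1, n.obs = 10000)
  lam_fa <- drop(fa$loadings)
  if (lam_fa[1] < 0) lam_fa <- -lam_fa
  expect_equal(unname(sol$loadings), unname(lam_fa), tolerance = 1e-4)
})

test_that("anchor orientation flips the whole solution, not the model", {
  lam <- c(0.6, -0.7, -0.9)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  sol_pos <- efa_one_factor(R, anchor = 1)
  sol_neg <- efa_one_factor(R, anchor = 2)
  expect_equal(sol_pos$loadings, -sol_neg$loadings, tolerance = 1e-12)
  expect_equal(sol_pos$orientation, -sol_neg$orientation)
  expect_equal(sol_pos$variance_explained, sol_neg$variance_explained)
})

test_that("scores are zero at the indicator means and flip-invariant", {
  lam <- c(0.6, -0.7, -0.9)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(R) <- list(paste0("z", 1:3), paste0("z", 1:3))
  sol <- efa_one_factor(R)
  at_mean <- data.frame(z1 = 0, z2 = 0, z3 = 0)
  expect_equal(composite_scores(at_mean, sol), 0, tolerance = 1e-12)
  set.seed(41)
  z <- as.data.frame(matrix(rnorm(300), 100, 3))
  names(z) <- paste0("z", 1:3)
  s1 <- composite_scores(z, sol)
  # flip indicator 2's sign convention in both data and model
  Rf <- R
  Rf[2, ] <- -Rf[2, ]; Rf[, 2] <- -Rf[, 2]; diag(Rf) <- 1
  solf <- efa_one_factor(Rf)
  zf <- z; zf$z2 <- -zf$z2
  s2 <- composite_scores(zf, solf)
  expect_equal(s1, s2, tolerance = 1e-10)
  # missing indicator gives a missing score
  z$z1[1] <- NA
  expect_true(is.na(composite_scores(z, sol)[1]))
})

test_that("factor scores beat any single indicator at tracking the factor", {
  set.seed(42)
  n <- 20000
  lam <- c(0.66, -0.78, -0.93)
  f <- rnorm(n)
  z <- vapply(lam, function(l) l * f + sqrt(1 - l^2) * rnorm(n),
              numeric(n))
  colnames(z) <- c("dsst", "tmta", "tmtb")
  zt <- as.data.frame(z)
  R <- stats::cor(z)
  sol <- efa_one_factor(R, anchor = "dsst")
  sc <- composite_scores(zt, sol)
  r_score <- stats::cor(sc, f)
  expect_gt(r_score, max(abs(stats::cor(z, f))))
})

test_that("generator preset reproduces the score-indicator correlations", {
  cfg <- cross_sectional_config(n = 50000, seed = 43)
  d <- generate_cross_sectional(cfg)
  d$log_tmt_a <- log(d$tmt_a_s)
  d$log_tmt_b <- log(d$tmt_b_s)
  comp <- build_composite(d, c("dsst", "log_tmt_a", "log_tmt_b"),
                          anchor = "dsst")
  sc <- comp$table$cog_composite_efa
  expect_lt(abs(stats::cor(sc, d$dsst) - 0.66), 0.02)
  expect_lt(abs(stats::cor(sc, log(d$tmt_a_s)) - (-0.78)), 0.02)
  expect_lt(abs(stats::cor(sc, log(d$tmt_b_s)) - (-0.93)), 0.02)
  expect_lt(abs(comp$solution$variance_explained - 0.493), 0.02)
  expect_gt(stats::cor(sc, d$cog_composite), 0.8)
})
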