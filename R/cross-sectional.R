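# Cross-sectional cohort generator: regional volumes with an age slope, a
# sex offset and a shared size factor; independent demographic/lifestyle
# covariates; a cognitive composite generated as the multivariable linear
# predictor plus Gaussian noise; and DSST/TMT indicator scores derived
# from the composite through a one-factor measurement model.

# moments of round(clip(N(mean, sd), lo, hi)) on the integer grid lo..hi
disc_clip_norm_moments <- function(mean, sd, lo, hi) {
  k <- lo:hi
  if (sd <= 0) {
    v <- pmin(pmax(round(mean), lo), hi)
    return(list(mean = v, var = 0))
  }
  cuts <- c(-Inf, k[-length(k)] + 0.5, Inf)
  p <- diff(stats::pnorm(cuts, mean, sd))
  m <- sum(k * p)
  list(mean = m, var = sum((k - m)^2 * p))
}

#' Default regional-volume table for the cross-sectional generator
#'
#' Means and SDs (mL) for eleven volume columns; thalamus and hippocampus
#' age slopes reproduce the age-volume covariances of the longitudinal
#' sample (-1.63 and -1.10 mL x years), other regions get a mild negative
#' age correlation (-0.25), men are offset upward, and a shared size
#' factor induces positive inter-regional correlations.  The
#' thalamus-hippocampus factor loadings are solved by
#' [cross_sectional_config()] so that their covariance equals 0.76 mL^2.
#'
#' @return data frame with columns region, mean, sd, age_slope,
#'   sex_effect, loading
#' @export
cs_default_regions <- function() {
  r <- data.frame(
    region = c("thal", "hipp", "amyg", "caud", "put", "pall", "accu",
               "frontal_gm", "wm", "gm", "vcsf"),
    mean = c(14.95, 7.52, 2.46, 6.85, 9.36, 3.49, 0.83, 48.9, 540, 600, 30),
    sd = c(1.34, 0.85, 0.43, 0.81, 1.07, 0.46, 0.20, 5.83, 60, 70, 10),
    stringsAsFactors = FALSE)
  age_var <- 4.8^2
  r$age_slope <- -0.25 * r$sd / 4.8
  r$age_slope[r$region == "thal"] <- -1.63 / age_var
  r$age_slope[r$region == "hipp"] <- -1.10 / age_var
  r$sex_effect <- 0.7 * r$sd
  r$sex_effect[r$region == "thal"] <- 0.8
  r$sex_effect[r$region == "hipp"] <- 0.5
  r$loading <- 0.6
  r$loading[r$region %in% c("thal", "hipp")] <- NA
  r
}

cs_default_covariates <- function() {
  list(age_mean = 67.9, age_sd = 4.8, p_male = 0.454,
       education_mean = 17.2, education_sd = 2.3,
       smoking_probs = c(never = 0.537, past = 0.410, current = 0.053),
       alcohol_mean = 2.73, alcohol_sd = 1.42,
       sleep_mean = 7.2, sleep_sd = 1.0)
}

#' Aim-1 model terms and default generating coefficients
#'
#' The fifteen predictors of the multivariable cross-sectional model of
#' the cognitive composite, with the generating slopes on their natural
#' scales (mL, years, hours; binary indicators for male sex and ever
#' smoking).
#'
#' @return named numeric vector of slopes
#' @export
cs_default_coefs <- function() {
  c(thal_ml = 0.069, frontal_gm_ml = 0.008, age_y = -0.039,
    sex_male = -0.053, education_y = 0.030, smoking_ever = 0.020,
    alcohol_freq = -0.034, sleep_h = -0.007, wm_ml = -0.004,
    hipp_ml = 0.024, caud_ml = -0.015, put_ml = 0.035, pall_ml = 0.004,
    amyg_ml = -0.069, accu_ml = -0.001)
}

# loadings lambda = rho * c reproducing target score-indicator
# correlations c under regression-method factor scoring, where
# rho^2 = s/(1+s), s = sum(lambda^2 / (1 - lambda^2))
calibrate_indicator_loadings <- function(target_cors) {
  f <- function(rho) {
    lam2 <- (rho * target_cors)^2
    s <- sum(lam2 / (1 - lam2))
    rho^2 - s / (1 + s)
  }
  upper <- 1 / max(abs(target_cors)) - 1e-6
  rho <- stats::uniroot(f, c(0.2, upper), tol = 1e-12)$root
  rho * target_cors
}

#' Configuration for the cross-sectional cohort generator
#'
#' @param n number of participants
#' @param regions regional-volume table, see [cs_default_regions()]
#' @param covariates list of demographic/lifestyle distribution settings
#' @param cognition_coefs named generating slopes, see [cs_default_coefs()]
#' @param cognition_intercept intercept of the composite model
#' @param cognition_resid_sd residual SD of the composite; `NULL` tunes it
#'   so the population R-squared of the generating model equals
#'   `target_r2`
#' @param target_r2 variance fraction of the composite explained by the
#'   linear predictor (default 0.09)
#' @param indicator_target_cors target correlations between the composite
#'   factor score and the three standardized indicators
#' @param indicator_scales raw-scale parameters for DSST counts and
#'   (log-normal) TMT completion times
#' @param nmt numeric-memory model settings (slopes, target R-squared,
#'   mean score)
#' @param volume_corr optional explicit region correlation matrix; when
#'   given, volumes are drawn directly from it (no age/sex/size-factor
#'   structure) and it must be symmetric with unit diagonal and positive
#'   definite
#' @param cov_th_target thalamus-hippocampus covariance the size-factor
#'   loadings are solved for (structural route only)
#' @param seed optional integer seed
#' @return object of class `cross_sectional_config`
#' @export
cross_sectional_config <- function(n,
                                   regions = cs_default_regions(),
                                   covariates = cs_default_covariates(),
                                   cognition_coefs = cs_default_coefs(),
                                   cognition_intercept = 0.817,
                                   cognition_resid_sd = NULL,
                                   target_r2 = 0.09,
                                   indicator_target_cors =
                                     c(dsst = 0.66, tmt_a = -0.78,
                                       tmt_b = -0.93),
                                   indicator_scales =
                                     list(dsst_mean = 60, dsst_sd = 12,
                                          tmt_a_meanlog = log(40),
                                          tmt_a_sdlog = 0.30,
                                          tmt_b_meanlog = log(70),
                                          tmt_b_sdlog = 0.35),
                                   nmt = list(coef_thal = 0.10,
                                              coef_frontal = 0.03,
                                              target_r2 = 0.027,
                                              mean = 6.8),
                                   volume_corr = NULL,
                                   cov_th_target = 0.76,
                                   seed = NULL) {
  stopifnot(n >= 0, all(regions$sd >= 0))
  cv <- covariates
  if (!is.null(volume_corr)) {
    volume_corr <- as.matrix(volume_corr)
    if (!isSymmetric(unname(volume_corr), tol = 1e-8))
      stop("volume_corr must be symmetric")
    if (any(abs(diag(volume_corr) - 1) > 1e-8))
      stop("volume_corr must have a unit diagonal")
    ev <- eigen(volume_corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop("volume_corr is not positive definite (min eigenvalue ",
           format(min(ev)), ")")
  } else {
    age_var <- cv$age_sd^2
    pq <- cv$p_male * (1 - cv$p_male)
    s2 <- regions$sd^2 - regions$age_slope^2 * age_var -
      regions$sex_effect^2 * pq
    if (any(s2 < -1e-10))
      stop("region SD too small for its age/sex components: ",
           paste(regions$region[s2 < -1e-10], collapse = ", "))
    regions$resid_scale <- sqrt(pmax(s2, 0))
    it <- match("thal", regions$region); ih <- match("hipp", regions$region)
    excess <- cov_th_target -
      regions$age_slope[it] * regions$age_slope[ih] * age_var -
      regions$sex_effect[it] * regions$sex_effect[ih] * pq
    denom <- regions$resid_scale[it] * regions$resid_scale[ih]
    if (denom > 1e-12) {
      l2 <- excess / denom
      if (l2 < 0 || l2 >= 1)
        stop("thalamus-hippocampus covariance target infeasible ",
             "(implied loading^2 = ", format(l2), ")")
      regions$loading[c(it, ih)] <- sqrt(l2)
    } else {
      if (abs(excess) > 1e-8)
        stop("thalamus-hippocampus covariance target infeasible with ",
             "zero residual volume variance")
      regions$loading[c(it, ih)] <- 0
    }
  }
  cfg <- list(n = n, regions = regions, covariates = cv,
              cognition_coefs = cognition_coefs,
              cognition_intercept = cognition_intercept,
              target_r2 = target_r2,
              indicator_target_cors = indicator_target_cors,
              indicator_loadings =
                calibrate_indicator_loadings(indicator_target_cors),
              indicator_scales = indicator_scales,
              nmt = nmt, volume_corr = volume_corr,
              seed = seed)
  class(cfg) <- "cross_sectional_config"
  pm <- cs_predictor_moments(cfg)
  b <- cognition_coefs[pm$terms]
  if (any(is.na(b)))
    stop("cognition_coefs must cover: ", paste(pm$terms, collapse = ", "))
  vxb <- drop(t(b) %*% pm$cov %*% b)
  cfg$lin_pred_var <- vxb
  if (is.null(cognition_resid_sd)) {
    cognition_resid_sd <- sqrt(vxb * (1 - target_r2) / target_r2)
  }
  cfg$cognition_resid_sd <- cognition_resid_sd
  cfg$composite_mean <- cognition_intercept + sum(b * pm$mean)
  cfg$composite_sd <- sqrt(vxb + cognition_resid_sd^2)
  # numeric-memory model calibration
  nb <- c(thal_ml = nmt$coef_thal, frontal_gm_ml = nmt$coef_frontal)
  idx <- match(names(nb), pm$terms)
  vn <- drop(t(nb) %*% pm$cov[idx, idx] %*% nb)
  cfg$nmt_resid_sd <- nmt$resid_sd %||%
    sqrt(vn * (1 - nmt$target_r2) / nmt$target_r2)
  cfg$nmt_intercept <- nmt$intercept %||%
    (nmt$mean - sum(nb * pm$mean[idx]))
  cfg
}

#' Implied first and second moments of the Aim-1 design
#'
#' Analytic mean vector and covariance matrix of the fifteen model
#' predictors under a [cross_sectional_config()], used for residual-SD
#' calibration and as the Monte-Carlo oracle in tests.
#'
#' @param config a `cross_sectional_config`
#' @return list with `terms`, `mean`, `cov`
#' @export
cs_predictor_moments <- function(config) {
  r <- config$regions
  cv <- config$covariates
  vols <- paste0(r$region, "_ml")
  age_var <- cv$age_sd^2
  pq <- cv$p_male * (1 - cv$p_male)
  nv <- nrow(r)
  if (!is.null(config$volume_corr)) {
    Vv <- diag(r$sd, nv) %*% config$volume_corr %*% diag(r$sd, nv)
    v_age <- rep(0, nv); v_sex <- rep(0, nv)
  } else {
    fac <- r$resid_scale * r$loading
    Vv <- outer(r$age_slope, r$age_slope) * age_var +
      outer(r$sex_effect, r$sex_effect) * pq + tcrossprod(fac)
    diag(Vv) <- r$sd^2
    v_age <- r$age_slope * age_var
    v_sex <- r$sex_effect * pq
  }
  dimnames(Vv) <- list(vols, vols)
  alc <- disc_clip_norm_moments(cv$alcohol_mean, cv$alcohol_sd, 1, 6)
  covs <- c("age_y", "sex_male", "education_y", "smoking_ever",
            "alcohol_freq", "sleep_h")
  p_ever <- unname(sum(cv$smoking_probs[c("past", "current")]))
  cvar <- c(age_var, pq, cv$education_sd^2, p_ever * (1 - p_ever),
            alc$var, cv$sleep_sd^2)
  cmean <- c(cv$age_mean, cv$p_male, cv$education_mean, p_ever,
             alc$mean, cv$sleep_mean)
  terms <- c(vols, covs)
  k <- length(terms)
  V <- matrix(0, k, k, dimnames = list(terms, terms))
  V[vols, vols] <- Vv
  V[covs, covs] <- diag(cvar)
  V[vols, "age_y"] <- V["age_y", vols] <- v_age
  V[vols, "sex_male"] <- V["sex_male", vols] <- v_sex
  mu <- setNames(c(r$mean, cmean), terms)
  model_terms <- names(cs_default_coefs())
  list(terms = model_terms, mean = mu[model_terms],
       cov = V[model_terms, model_terms])
}

#' Generate a cross-sectional cohort
#'
#' Draws demographics/lifestyle covariates, regional brain volumes (with
#' age slope, sex offset and shared size factor, or from an explicit
#' correlation matrix), a cognitive composite equal to the multivariable
#' linear predictor plus Gaussian noise, DSST/TMT indicator scores derived
#' from the standardized composite through the calibrated one-factor
#' measurement model (TMT times are exponentiated so they stay positive),
#' and a numeric-memory score.
#'
#' @param config a [cross_sectional_config()]
#' @return data frame with one row per participant; columns
#'   `participant_id`, `age_y`, `sex`, `sex_male`, `education_y`,
#'   `smoking`, `smoking_ever`, `alcohol_freq`, `sleep_h`, the eleven
#'   `*_ml` volume columns, `etiv_ml`, `dsst`, `tmt_a_s`, `tmt_b_s`,
#'   `nmt_score`, `cog_composite`
#' @export
generate_cross_sectional <- function(config) {
  stopifnot(inherits(config, "cross_sectional_config"))
  set_seed_if(config$seed)
  n <- config$n
  cv <- config$covariates
  r <- config$regions
  age <- stats::rnorm(n, cv$age_mean, cv$age_sd)
  sex_male <- stats::rbinom(n, 1, cv$p_male)
  education <- stats::rnorm(n, cv$education_mean, cv$education_sd)
  smoking <- if (n > 0)
    sample(names(cv$smoking_probs), n, replace = TRUE,
           prob = cv$smoking_probs) else character(0)
  smoking_ever <- as.integer(smoking %in% c("past", "current"))
  alcohol <- pmin(pmax(round(stats::rnorm(n, cv$alcohol_mean,
                                          cv$alcohol_sd)), 1), 6)
  sleep <- stats::rnorm(n, cv$sleep_mean, cv$sleep_sd)
  nv <- nrow(r)
  if (!is.null(config$volume_corr)) {
    z <- matrix(stats::rnorm(n * nv), n, nv) %*% chol(config$volume_corr)
    volm <- sweep(z %*% diag(r$sd, nv), 2, r$mean, `+`)
  } else {
    f <- stats::rnorm(n)
    u <- matrix(stats::rnorm(n * nv), n, nv)
    volm <- matrix(0, n, nv)
    for (j in seq_len(nv)) {
      volm[, j] <- r$mean[j] +
        r$age_slope[j] * (age - cv$age_mean) +
        r$sex_effect[j] * (sex_male - cv$p_male) +
        r$resid_scale[j] * (r$loading[j] * f +
                              sqrt(1 - r$loading[j]^2) * u[, j])
    }
  }
  colnames(volm) <- paste0(r$region, "_ml")
  X <- cbind(volm, age_y = age, sex_male = sex_male, education_y = education,
             smoking_ever = smoking_ever, alcohol_freq = alcohol,
             sleep_h = sleep)
  b <- config$cognition_coefs
  lin <- config$cognition_intercept +
    drop(X[, names(b), drop = FALSE] %*% b)
  composite <- lin + stats::rnorm(n, 0, config$cognition_resid_sd)
  cz <- (composite - config$composite_mean) / config$composite_sd
  lam <- config$indicator_loadings
  zind <- vapply(seq_along(lam), function(j)
    lam[j] * cz + sqrt(1 - lam[j]^2) * stats::rnorm(n),
    numeric(n))
  if (n == 0) zind <- matrix(numeric(0), 0, length(lam))
  sc <- config$indicator_scales
  dsst <- round(pmax(sc$dsst_mean + sc$dsst_sd * zind[, 1], 0))
  tmt_a <- exp(sc$tmt_a_meanlog + sc$tmt_a_sdlog * zind[, 2])
  tmt_b <- exp(sc$tmt_b_meanlog + sc$tmt_b_sdlog * zind[, 3])
  nmt <- pmin(pmax(round(config$nmt_intercept +
                           config$nmt$coef_thal * volm[, "thal_ml"] +
                           config$nmt$coef_frontal * volm[, "frontal_gm_ml"] +
                           stats::rnorm(n, 0, config$nmt_resid_sd)), 2), 12)
  out <- data.frame(
    participant_id = seq_len(n),
    age_y = age,
    sex = ifelse(sex_male == 1, "Male", "Female"),
    sex_male = sex_male,
    education_y = education,
    smoking = smoking,
    smoking_ever = smoking_ever,
    alcohol_freq = as.numeric(alcohol),
    sleep_h = sleep,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(volm))
  out$etiv_ml <- out$gm_ml + out$wm_ml + out$vcsf_ml
  out$dsst <- as.numeric(dsst)
  out$tmt_a_s <- as.numeric(tmt_a)
  out$tmt_b_s <- as.numeric(tmt_b)
  out$nmt_score <- as.numeric(nmt)
  out$cog_composite <- as.numeric(composite)
  rownames(out) <- NULL
  attr(out, "generator_config") <- config
  out
}

#' Formula of the Aim-1 multivariable model
#'
#' @param outcome outcome column (default `cog_composite`)
#' @param etiv replace total white-matter volume with estimated total
#'   intracranial volume (the sensitivity covariate set)
#' @return a formula over the fifteen predictor columns
#' @export
aim1_formula <- function(outcome = "cog_composite", etiv = FALSE) {
  terms <- names(cs_default_coefs())
  if (etiv) terms[terms == "wm_ml"] <- "etiv_ml"
  stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
}
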