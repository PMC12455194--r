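# Synthetic cohort generators.  The cross-sectional generator emulates a
# large aging cohort (regional volumes + demographics + cognitive scores);
# the longitudinal generator draws baseline volume pairs and latent change
# scores from the bivariate / multivariate / multigroup LCS structural
# equations under the atrophy-positive convention
# (follow-up = baseline - change).

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# exact moments of a normal truncated below at `lower`
truncnorm_moments <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  list(mean = mean + sd * lam,
       var = sd^2 * (1 + a * lam - lam^2))
}

rtruncnorm_lower <- function(n, mean, sd, lower) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

rmvnorm_chol <- function(n, mean, cov) {
  p <- length(mean)
  z <- matrix(stats::rnorm(n * p), n, p)
  # eigen-based square root tolerates semi-definite covariances
  ev <- eigen(cov, symmetric = TRUE)
  rt <- ev$vectors %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0)))
  sweep(z %*% rt, 2, mean, `+`)
}

check_psd <- function(m, name, strict = FALSE) {
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop(name, " must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lim <- if (strict) 1e-10 else -1e-8
  if (any(ev < lim))
    stop(name, " is not positive ", if (strict) "definite" else
      "semi-definite", " (min eigenvalue ", format(min(ev)), ")")
  invisible(TRUE)
}

# --- longitudinal generator ----------------------------------------------

#' Configuration for the latent change score cohort generator
#'
#' Defines the structural parameters of the data-generating LCS system:
#' baseline volume moments, self-feedback (`beta`), cross-couplings
#' (`gamma`), change intercepts (`alpha`) and the change residual
#' covariance, with optional per-group (sex) overrides, an age/interval
#' block, and a fornix-FA block.
#'
#' @param baseline_means named numeric `c(thal=, hipp=)` in mL
#' @param baseline_cov 2x2 baseline covariance (mL^2); off-diagonal is the
#'   baseline thalamus-hippocampus covariance `phi_ht`
#' @param self_feedback named `c(thal=, hipp=)` regressions of each change
#'   on its own baseline (`beta_t`, `beta_h`)
#' @param cross_coupling named `c(t_dh=, h_dt=)`: baseline thalamus ->
#'   hippocampal change and baseline hippocampus -> thalamic change
#' @param change_intercepts named `c(thal=, hipp=)` (mL)
#' @param change_resid_cov 2x2 residual covariance of the latent changes
#'   (mL^2); off-diagonal is `rho_ht`
#' @param group_overrides optional list with `proportions` (named, summing
#'   to 1) and `params` (per-group named lists overriding any of the
#'   fields above)
#' @param age_block optional list with `mean`, `sd`, `lower` (baseline-age
#'   truncation, years), `cov_t_age`, `cov_h_age` (age-volume covariances
#'   on the realized/truncated scale), `gamma_age_dh`, `gamma_age_dt`,
#'   `interval_mean`, `interval_iqr`, `interval_min` (years)
#' @param fa_block optional list with `mean`, `sd`, `slope_hipp`,
#'   `slope_thal` linking fornix fractional anisotropy to follow-up volumes
#' @param seed optional integer seed
#' @return an object of class `lcs_generator_config`
#' @export
lcs_generator_config <- function(baseline_means = c(thal = 14.95, hipp = 7.52),
                                 baseline_cov = matrix(c(1.34^2, 0.76,
                                                         0.76, 0.85^2), 2, 2),
                                 self_feedback = c(thal = 0.05, hipp = 0.05),
                                 cross_coupling = c(t_dh = -0.048, h_dt = 0.043),
                                 change_intercepts = c(thal = 0, hipp = 0),
                                 change_resid_cov = diag(c(0.05, 0.05)),
                                 group_overrides = NULL,
                                 age_block = NULL,
                                 fa_block = NULL,
                                 seed = NULL) {
  baseline_cov <- unname(as.matrix(baseline_cov))
  change_resid_cov <- unname(as.matrix(change_resid_cov))
  check_psd(baseline_cov, "baseline_cov")
  check_psd(change_resid_cov, "change_resid_cov")
  cfg <- list(baseline_means = baseline_means, baseline_cov = baseline_cov,
              self_feedback = self_feedback, cross_coupling = cross_coupling,
              change_intercepts = change_intercepts,
              change_resid_cov = change_resid_cov,
              group_overrides = group_overrides,
              age_block = age_block, fa_block = fa_block, seed = seed)
  if (!is.null(group_overrides)) {
    pr <- group_overrides$proportions
    if (is.null(pr) || is.null(names(pr)) || abs(sum(pr) - 1) > 1e-8)
      stop("group_overrides$proportions must be named and sum to 1")
    if (!setequal(names(pr), names(group_overrides$params)))
      stop("group_overrides$params must cover every declared group label")
  }
  class(cfg) <- "lcs_generator_config"
  cfg
}

merge_config <- function(cfg, override) {
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  cfg$group_overrides <- NULL
  cfg
}

generate_longitudinal_one <- function(cfg, n) {
  has_age <- !is.null(cfg$age_block)
  if (has_age) {
    ab <- cfg$age_block
    tm <- truncnorm_moments(ab$mean, ab$sd, ab$lower)
    age <- rtruncnorm_lower(n, ab$mean, ab$sd, ab$lower)
    slopes <- c(ab$cov_t_age, ab$cov_h_age) / tm$var
    cond_cov <- cfg$baseline_cov - tm$var * tcrossprod(slopes)
    check_psd(cond_cov, "age-conditional baseline covariance", strict = TRUE)
    base <- rmvnorm_chol(n, c(0, 0), cond_cov)
    t1 <- cfg$baseline_means["thal"] + slopes[1] * (age - tm$mean) + base[, 1]
    h1 <- cfg$baseline_means["hipp"] + slopes[2] * (age - tm$mean) + base[, 2]
    interval <- pmax(stats::rnorm(n, ab$interval_mean,
                                  ab$interval_iqr / (2 * stats::qnorm(0.75))),
                     ab$interval_min)
    g_age <- c(dh = ab$gamma_age_dh %||% 0, dt = ab$gamma_age_dt %||% 0)
  } else {
    base <- rmvnorm_chol(n, cfg$baseline_means, cfg$baseline_cov)
    t1 <- base[, 1]; h1 <- base[, 2]
    age <- interval <- NULL
    g_age <- c(dh = 0, dt = 0)
  }
  eps <- rmvnorm_chol(n, c(0, 0), cfg$change_resid_cov)
  d_thal <- cfg$change_intercepts["thal"] +
    cfg$self_feedback["thal"] * t1 + cfg$cross_coupling["h_dt"] * h1 +
    (if (has_age) g_age["dt"] * age else 0) + eps[, 1]
  d_hipp <- cfg$change_intercepts["hipp"] +
    cfg$self_feedback["hipp"] * h1 + cfg$cross_coupling["t_dh"] * t1 +
    (if (has_age) g_age["dh"] * age else 0) + eps[, 2]
  out <- data.frame(
    thal_t1_ml = as.numeric(t1), hipp_t1_ml = as.numeric(h1),
    thal_t2_ml = as.numeric(t1 - d_thal),
    hipp_t2_ml = as.numeric(h1 - d_hipp))
  if (has_age) {
    out$age_y <- age
    out$interval_y <- interval
  }
  if (!is.null(cfg$fa_block)) {
    fb <- cfg$fa_block
    out$fornix_fa <- fb$mean +
      fb$slope_hipp * (out$hipp_t2_ml - mean(out$hipp_t2_ml)) +
      fb$slope_thal * (out$thal_t2_ml - mean(out$thal_t2_ml)) +
      stats::rnorm(n, 0, fb$sd)
  }
  out
}

#' Generate a longitudinal two-scan cohort from the LCS structural equations
#'
#' Per row: a baseline volume pair, latent change scores from the LCS
#' regressions plus correlated residuals, and follow-up volumes computed
#' under the atrophy-positive sign convention
#' (`follow-up = baseline - change`), so the observed difference
#' `baseline - follow-up` equals the generated change score exactly.
#'
#' @param config an [lcs_generator_config()]
#' @param n number of participants (>= 0)
#' @return data frame with columns `participant_id`, optional `group`,
#'   optional `age_y`/`interval_y`/`fornix_fa`, and
#'   `thal_t1_ml`, `hipp_t1_ml`, `thal_t2_ml`, `hipp_t2_ml`
#' @export
generate_longitudinal <- function(config, n) {
  stopifnot(inherits(config, "lcs_generator_config"), n >= 0)
  set_seed_if(config$seed)
  if (!is.null(config$group_overrides)) {
    pr <- config$group_overrides$proportions
    sizes <- floor(pr * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      frac <- order(pr * n - sizes, decreasing = TRUE)
      sizes[frac[seq_len(rem)]] <- sizes[frac[seq_len(rem)]] + 1
    }
    parts <- lapply(names(pr), function(g) {
      cfg_g <- merge_config(config, config$group_overrides$params[[g]])
      d <- generate_longitudinal_one(cfg_g, sizes[[g]])
      if (nrow(d)) d$group <- g else d$group <- character(0)
      d
    })
    out <- do.call(rbind, parts)
  } else {
    out <- generate_longitudinal_one(config, n)
  }
  out <- cbind(participant_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "generator_config") <- config
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generating parameter vector for a generator configuration
#'
#' Maps an [lcs_generator_config()] (without group overrides) onto the
#' parameter labels of the matching model specification, using exact
#' truncated-normal moments for the age block.  Useful as the ground truth
#' in parameter-recovery studies and as `theta` for [implied_moments()].
#'
#' @param config an [lcs_generator_config()]
#' @return list with elements `spec` (an `lcs_spec`) and `theta`
#' @export
lcs_generating_theta <- function(config) {
  stopifnot(is.null(config$group_overrides))
  has_age <- !is.null(config$age_block)
  spec <- if (has_age) lcs_multivariate_spec() else lcs_bivariate_spec()
  th <- c(
    mu_t = unname(config$baseline_means["thal"]),
    mu_h = unname(config$baseline_means["hipp"]),
    phi_t = config$baseline_cov[1, 1],
    phi_h = config$baseline_cov[2, 2],
    phi_ht = config$baseline_cov[1, 2],
    beta_t = unname(config$self_feedback["thal"]),
    beta_h = unname(config$self_feedback["hipp"]),
    gamma_t_dh = unname(config$cross_coupling["t_dh"]),
    gamma_h_dt = unname(config$cross_coupling["h_dt"]),
    alpha_t = unname(config$change_intercepts["thal"]),
    alpha_h = unname(config$change_intercepts["hipp"]),
    psi_t = config$change_resid_cov[1, 1],
    psi_h = config$change_resid_cov[2, 2],
    rho_ht = config$change_resid_cov[1, 2])
  if (has_age) {
    ab <- config$age_block
    tm <- truncnorm_moments(ab$mean, ab$sd, ab$lower)
    isd <- ab$interval_iqr / (2 * stats::qnorm(0.75))
    th <- c(th,
            mu_age = tm$mean, phi_age = tm$var,
            phi_t_age = ab$cov_t_age, phi_h_age = ab$cov_h_age,
            mu_int = ab$interval_mean, phi_int = isd^2,
            phi_age_int = 0, phi_t_int = 0, phi_h_int = 0,
            rho_t_int = 0, rho_h_int = 0,
            gamma_age_dh = ab$gamma_age_dh %||% 0,
            gamma_age_dt = ab$gamma_age_dt %||% 0)
  }
  list(spec = spec, theta = th[spec$labels])
}

# --- missingness ----------------------------------------------------------

#' Missingness specification
#'
#' @param mechanism `"MCAR"` or `"MAR"`
#' @param target_columns columns to mask
#' @param rate target marginal missingness fraction in `[0, 1]`
#' @param mar_predictors for MAR: named numeric vector of logistic slopes
#'   on (standardized) predictor columns; the intercept is calibrated so
#'   the expected rate matches `rate`
#' @param jointly if TRUE a single per-row indicator masks all target
#'   columns together (e.g. a missed follow-up visit); if FALSE cells are
#'   masked independently
#' @param seed optional integer seed
#' @return object of class `missingness_spec`
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR"), target_columns,
                             rate, mar_predictors = NULL, jointly = FALSE,
                             seed = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(rate >= 0, rate <= 1)
  if (mechanism == "MAR" &&
      (is.null(mar_predictors) || is.null(names(mar_predictors))))
    stop("MAR requires named mar_predictors weights")
  out <- list(mechanism = mechanism, target_columns = target_columns,
              rate = rate, mar_predictors = mar_predictors,
              jointly = jointly, seed = seed)
  class(out) <- "missingness_spec"
  out
}

#' Mask cells of a cohort table according to a missingness specification
#'
#' Returns a masked copy (the input is untouched); the realized
#' missingness rate is recorded in the `"missingness"` attribute.
#'
#' @param table a data frame
#' @param spec a [missingness_spec()]
#' @return masked copy of `table`
#' @export
apply_missingness <- function(table, spec) {
  stopifnot(inherits(spec, "missingness_spec"))
  unknown <- setdiff(spec$target_columns, names(table))
  if (length(unknown))
    stop("unknown target column(s): ", paste(unknown, collapse = ", "))
  set_seed_if(spec$seed)
  n <- nrow(table)
  out <- table
  if (spec$mechanism == "MAR") {
    miss_p <- setdiff(names(spec$mar_predictors), names(table))
    if (length(miss_p))
      stop("unknown MAR predictor(s): ", paste(miss_p, collapse = ", "))
    X <- scale(as.matrix(table[, names(spec$mar_predictors), drop = FALSE]))
    eta <- drop(X %*% spec$mar_predictors)
    a <- if (spec$rate <= 0) -Inf else if (spec$rate >= 1) Inf else
      stats::uniroot(function(a) mean(stats::plogis(a + eta)) - spec$rate,
                     c(-40, 40))$root
    pr <- stats::plogis(a + eta)
  } else {
    pr <- rep(spec$rate, n)
  }
  if (spec$jointly) {
    hit <- stats::runif(n) < pr
    for (cl in spec$target_columns) out[hit, cl] <- NA
    realized <- mean(hit)
  } else {
    hits <- 0
    for (cl in spec$target_columns) {
      hit <- stats::runif(n) < pr
      out[hit, cl] <- NA
      hits <- hits + sum(hit)
    }
    realized <- hits / (n * length(spec$target_columns))
  }
  attr(out, "missingness") <- list(realized_rate = realized, spec = spec)
  out
}

#' Simulate a second segmentation pipeline's volume estimates
#'
#' Adds a constant bias plus independent Gaussian disagreement noise to a
#' vector of volumes, emulating the output of an alternative automated
#' segmentation pipeline for Bland-Altman comparison.
#'
#' @param x numeric volumes (mL)
#' @param bias systematic offset (mL)
#' @param sd SD of the pipeline disagreement (mL)
#' @param seed optional integer seed
#' @return numeric vector of the same length
#' @export
simulate_pipeline_pair <- function(x, bias = 0.15, sd = 0.25, seed = NULL) {
  set_seed_if(seed)
  x + bias + stats::rnorm(length(x), 0, sd)
}
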