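# Monte-Carlo parameter-recovery studies: generate replicate cohorts at
# the calibration presets, fit the matching model, and summarize the
# estimates.  These are the package's verification experiments (the real
# cohort is access-controlled, so recovery on synthetic cohorts generated
# at the published parameter values is the reproducibility check).

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly generates a cohort from the named scenario's calibration
#' preset, fits the matching LCS or regression model, and collects the
#' estimates.
#'
#' Scenarios: `"bivariate"` (bivariate LCS, ML), `"multigroup"`
#' (sex-stratified multigroup LCS; labels are suffixed `|Female` /
#' `|Male`), `"multivariate_age"` (age-augmented LCS), `"fiml"`
#' (bivariate LCS on a large cohort with most follow-up pairs deleted
#' completely at random, fitted by FIML), `"cross_sectional"` (the
#' fifteen-predictor OLS model of the cognitive composite; labels are the
#' predictor columns).
#'
#' @param scenario study design, see Details
#' @param reps number of replicate cohorts
#' @param n cohort size per replicate
#' @param seed integer seed for the whole study
#' @param labels parameter labels to track (default: the scenario's
#'   headline parameters)
#' @param missing_rate MCAR follow-up missingness for `"fiml"`
#' @param se also collect per-replicate standard errors
#' @return list with `summary` (data frame: label, mean, mc_sd, mc_se),
#'   `estimates` (reps x labels matrix) and, when `se = TRUE`, `ses`
#' @export
recovery_study <- function(scenario = c("bivariate", "multigroup",
                                        "multivariate_age", "fiml",
                                        "cross_sectional"),
                           reps, n, seed, labels = NULL,
                           missing_rate = 0.85, se = FALSE) {
  scenario <- match.arg(scenario)
  set_seed_if(seed)
  labels <- labels %||% switch(scenario,
    bivariate = c("gamma_t_dh", "gamma_h_dt", "phi_ht", "rho_ht"),
    multigroup = c("gamma_t_dh|Female", "gamma_h_dt|Female",
                   "gamma_t_dh|Male", "gamma_h_dt|Male"),
    multivariate_age = c("gamma_age_dh", "gamma_t_dh", "gamma_h_dt"),
    fiml = c("gamma_t_dh", "gamma_h_dt"),
    cross_sectional = "thal_ml")
  one <- switch(scenario,
    bivariate = function() {
      d <- generate_longitudinal(preset_bivariate_lcs(), n)
      fit_ml(lcs_bivariate_spec(), d, se = se)
    },
    multigroup = function() {
      d <- generate_longitudinal(preset_multigroup_lcs(), n)
      fit_multigroup(lcs_bivariate_spec(), d, "group", se = se)
    },
    multivariate_age = function() {
      d <- generate_longitudinal(preset_multivariate_lcs(), n)
      fit_ml(lcs_multivariate_spec(), d, se = se)
    },
    fiml = function() {
      d <- generate_longitudinal(preset_bivariate_lcs(), n)
      msk <- apply_missingness(d, missingness_spec(
        "MCAR", c("thal_t2_ml", "hipp_t2_ml"), rate = missing_rate,
        jointly = TRUE))
      fit_fiml(lcs_bivariate_spec(), msk, se = se)
    },
    cross_sectional = function() {
      d <- generate_cross_sectional(cross_sectional_config(n = n))
      fit_ols(d, aim1_formula())
    })
  est <- matrix(NA_real_, reps, length(labels),
                dimnames = list(NULL, labels))
  ses <- if (se) est else NULL
  for (r in seq_len(reps)) {
    fit <- one()
    if (scenario == "cross_sectional") {
      ct <- fit$coefficients
      est[r, ] <- ct$estimate[match(labels, ct$term)]
      if (se) ses[r, ] <- ct$se[match(labels, ct$term)]
    } else {
      est[r, ] <- fit$estimates[labels]
      if (se) ses[r, ] <- fit$ses[labels]
    }
  }
  sds <- apply(est, 2, stats::sd)
  out <- list(
    summary = data.frame(
      label = labels,
      mean = unname(colMeans(est)),
      mc_sd = unname(sds),
      mc_se = unname(sds / sqrt(reps)),
      stringsAsFactors = FALSE),
    estimates = est)
  if (se) out$ses <- ses
  out
}
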