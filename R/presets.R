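# Calibration presets: generator configurations whose parameters are the
# fitted values of the study the package emulates.  The hippocampal
# change-score moments (mean 0.155 mL, SD 0.136 mL) are preserved exactly
# by solving the change intercept and the hippocampal residual variance;
# the thalamic residual variance is then set from the residual covariance
# (0.03 mL^2) at a fixed residual correlation, because no residual
# variance consistent with the printed thalamic change SD can support a
# residual covariance of that size (see the methods vignette).

lcs_change_calibration <- function(exog_cov, coef_dh, coef_dt,
                                   exog_mean, target_mean_dh = 0.155,
                                   target_mean_dt = 0.213,
                                   target_sd_dh = 0.136,
                                   rho_ht = 0.03, resid_cor = 0.85) {
  struct_var_dh <- drop(t(coef_dh) %*% exog_cov %*% coef_dh)
  psi_h <- target_sd_dh^2 - struct_var_dh
  if (psi_h <= 0)
    stop("structural variance exceeds the target change-score variance")
  psi_t <- rho_ht^2 / (resid_cor^2 * psi_h)
  alpha_h <- target_mean_dh - sum(coef_dh * exog_mean)
  alpha_t <- target_mean_dt - sum(coef_dt * exog_mean)
  list(change_intercepts = c(thal = alpha_t, hipp = alpha_h),
       change_resid_cov = matrix(c(psi_t, rho_ht, rho_ht, psi_h), 2, 2))
}

#' Bivariate LCS generator preset at the study's fitted parameters
#'
#' Baseline moments: thalamus 14.95 (SD 1.34) mL, hippocampus 7.52
#' (SD 0.85) mL, covariance 0.76 mL^2.  Couplings: baseline thalamus ->
#' hippocampal atrophy -0.048, baseline hippocampus -> thalamic atrophy
#' 0.043.  Change residual covariance 0.03 mL^2.  Self-feedback defaults
#' to 0.05 on both sides; intercepts and the hippocampal residual
#' variance are solved so the hippocampal change score has mean 0.155 and
#' SD 0.136 mL.
#'
#' @param self_feedback named `c(thal=, hipp=)` self-feedback values
#' @param seed optional integer seed
#' @return an [lcs_generator_config()]
#' @export
preset_bivariate_lcs <- function(self_feedback = c(thal = 0.05, hipp = 0.05),
                                 seed = NULL) {
  bcov <- matrix(c(1.34^2, 0.76, 0.76, 0.85^2), 2, 2)
  bmean <- c(thal = 14.95, hipp = 7.52)
  gamma <- c(t_dh = -0.048, h_dt = 0.043)
  cal <- lcs_change_calibration(
    exog_cov = bcov,
    coef_dh = c(gamma["t_dh"], self_feedback["hipp"]),
    coef_dt = c(self_feedback["thal"], gamma["h_dt"]),
    exog_mean = bmean)
  lcs_generator_config(baseline_means = bmean, baseline_cov = bcov,
                       self_feedback = self_feedback,
                       cross_coupling = gamma,
                       change_intercepts = cal$change_intercepts,
                       change_resid_cov = cal$change_resid_cov,
                       seed = seed)
}

#' Sex-stratified multigroup LCS generator preset
#'
#' Group-specific cross-couplings at the fitted sex-stratified values
#' (women: thalamus->hippocampal atrophy -0.057, hippocampus->thalamic
#' atrophy 0.049; men: -0.040 and 0.008), shared baseline moments,
#' self-feedback and residual covariance, and group proportions matching
#' the cohort's sex split (54.6% women).  Change intercepts are re-solved
#' per group so both groups keep the pooled change-score means.
#'
#' @inheritParams preset_bivariate_lcs
#' @return an [lcs_generator_config()] with `group_overrides`
#' @export
preset_multigroup_lcs <- function(self_feedback = c(thal = 0.05, hipp = 0.05),
                                  seed = NULL) {
  base <- preset_bivariate_lcs(self_feedback = self_feedback)
  gammas <- list(Female = c(t_dh = -0.057, h_dt = 0.049),
                 Male = c(t_dh = -0.040, h_dt = 0.008))
  params <- lapply(gammas, function(g) {
    cal <- lcs_change_calibration(
      exog_cov = base$baseline_cov,
      coef_dh = c(g["t_dh"], self_feedback["hipp"]),
      coef_dt = c(self_feedback["thal"], g["h_dt"]),
      exog_mean = base$baseline_means)
    list(cross_coupling = g,
         change_intercepts = cal$change_intercepts,
         change_resid_cov = cal$change_resid_cov)
  })
  base$group_overrides <- list(
    proportions = c(Female = 0.546, Male = 0.454),
    params = params)
  base$seed <- seed
  class(base) <- "lcs_generator_config"
  base
}

#' Multivariate (age-augmented) LCS generator preset
#'
#' Adds the age block: baseline age normal (67.9, SD 4.8) truncated at 60
#' years, age-volume covariances -1.63 (thalamus) and -1.10 (hippocampus)
#' mL x years on the realized scale, age -> hippocampal-atrophy coupling
#' 0.013 mL/year and no age effect on thalamic atrophy; volume couplings
#' at the age-adjusted fitted values (-0.042 and 0.048); scan interval
#' normal with mean 2.26 y and IQR 0.33 y, clipped below at 1.5 y.
#'
#' @inheritParams preset_bivariate_lcs
#' @return an [lcs_generator_config()] with an `age_block`
#' @export
preset_multivariate_lcs <- function(self_feedback = c(thal = 0.05, hipp = 0.05),
                                    seed = NULL) {
  bcov <- matrix(c(1.34^2, 0.76, 0.76, 0.85^2), 2, 2)
  bmean <- c(thal = 14.95, hipp = 7.52)
  gamma <- c(t_dh = -0.042, h_dt = 0.048)
  ab <- list(mean = 67.9, sd = 4.8, lower = 60,
             cov_t_age = -1.63, cov_h_age = -1.10,
             gamma_age_dh = 0.013, gamma_age_dt = 0,
             interval_mean = 2.26, interval_iqr = 0.33, interval_min = 1.5)
  tm <- truncnorm_moments(ab$mean, ab$sd, ab$lower)
  exog_cov <- rbind(cbind(bcov, c(ab$cov_t_age, ab$cov_h_age)),
                    c(ab$cov_t_age, ab$cov_h_age, tm$var))
  exog_mean <- c(bmean, age = tm$mean)
  cal <- lcs_change_calibration(
    exog_cov = exog_cov,
    coef_dh = c(gamma["t_dh"], self_feedback["hipp"], ab$gamma_age_dh),
    coef_dt = c(self_feedback["thal"], gamma["h_dt"], ab$gamma_age_dt),
    exog_mean = exog_mean)
  lcs_generator_config(baseline_means = bmean, baseline_cov = bcov,
                       self_feedback = self_feedback,
                       cross_coupling = gamma,
                       change_intercepts = cal$change_intercepts,
                       change_resid_cov = cal$change_resid_cov,
                       age_block = ab, seed = seed)
}
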