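# End-to-end orchestration: the cross-sectional thalamus-cognition
# analysis (aim 1), the longitudinal LCS analyses with sensitivity suite
# (aim 2), and plain-text/CSV/JSON reports.

#' Assemble a run configuration
#'
#' @param seed integer seed; mandatory (every stochastic stage derives
#'   its own sub-seed from it and logs it)
#' @param out_dir output directory (created if needed); `NULL` returns
#'   results without writing files
#' @param n_cross cross-sectional sample size
#' @param n_long longitudinal sample size
#' @param input optional CSV path with a pre-made cohort table (otherwise
#'   the synthetic generators are used)
#' @param aim1,session,bivariate,multigroup,multivariate_age,fiml,mi,psm,agreement,connectivity
#'   analysis toggles
#' @param m_imputations imputations for the MI stage
#' @param followup_missing_rate MCAR follow-up missingness applied to the
#'   cross-sectional-sized cohort for the FIML/MI/PSM stages
#' @param caliper propensity-score caliper
#' @return list of class `run_config`
#' @export
run_config <- function(seed, out_dir = NULL, n_cross = 4348, n_long = 653,
                       input = NULL,
                       aim1 = TRUE, session = TRUE, bivariate = TRUE,
                       multigroup = TRUE, multivariate_age = TRUE,
                       fiml = FALSE, mi = FALSE, psm = FALSE,
                       agreement = FALSE, connectivity = FALSE,
                       m_imputations = 40L, followup_missing_rate = 0.85,
                       caliper = 0.001) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory for a run configuration")
  cfg <- as.list(environment())
  toggles <- c("aim1", "session", "bivariate", "multigroup",
               "multivariate_age", "fiml", "mi", "psm", "agreement",
               "connectivity")
  if (!any(unlist(cfg[toggles])))
    stop("at least one analysis must be enabled")
  class(cfg) <- "run_config"
  cfg
}

ensure_dir <- function(d) {
  if (!is.null(d) && !dir.exists(d)) dir.create(d, recursive = TRUE)
  invisible(d)
}

write_lines_report <- function(lines, out_dir, file) {
  if (!is.null(out_dir)) writeLines(lines, file.path(out_dir, file))
  invisible(lines)
}

#' Run the cross-sectional thalamus-cognition analysis
#'
#' Generates (or loads) the cross-sectional cohort, builds the cognitive
#' composite from the DSST / log-TMT indicators by one-factor EFA, fits
#' the fifteen-predictor multivariable model of the composite, the
#' numeric-memory model, the eTIV sensitivity refit, the VIF screen and
#' the FDR-adjusted p-value table, and writes CSV tables plus a text
#' summary.
#'
#' @param config a [run_config()] with `aim1 = TRUE`
#' @return list with the cohort, factor solution, fitted models, VIF
#'   tables and report lines
#' @export
run_aim1 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!config$aim1) stop("aim1 analysis is not enabled in this config")
  ensure_dir(config$out_dir)
  if (!is.null(config$input)) {
    cohort <- utils::read.csv(config$input)
  } else {
    cohort <- generate_cross_sectional(
      cross_sectional_config(n = config$n_cross, seed = config$seed))
  }
  need <- c("dsst", "tmt_a_s", "tmt_b_s", "thal_ml")
  miss_c <- setdiff(need, names(cohort))
  if (length(miss_c))
    stop("missing required column(s): ", paste(miss_c, collapse = ", "))
  # composite from indicators: log-transform TMT times (positive, skewed)
  cohort$log_tmt_a <- log(cohort$tmt_a_s)
  cohort$log_tmt_b <- log(cohort$tmt_b_s)
  comp <- build_composite(cohort, c("dsst", "log_tmt_a", "log_tmt_b"),
                          anchor = "dsst")
  cohort <- comp$table
  outcome <- if ("cog_composite" %in% names(cohort)) "cog_composite" else
    "cog_composite_efa"
  main <- fit_ols(cohort, aim1_formula(outcome))
  etiv_fit <- fit_ols(cohort, aim1_formula(outcome, etiv = TRUE))
  nmt_fit <- fit_ols(cohort, aim1_formula("nmt_score"))
  terms <- names(cs_default_coefs())
  vif_main <- vif(cohort, terms)
  vif_etiv <- vif(cohort, replace(terms, terms == "wm_ml", "etiv_ml"))
  main_tab <- main$coefficients
  idx <- main_tab$term != "(Intercept)"
  main_tab$p_fdr <- NA_real_
  main_tab$p_fdr[idx] <- bh_fdr(main_tab$p[idx])
  if (!is.null(config$out_dir)) {
    utils::write.csv(main_tab, file.path(config$out_dir, "aim1_model.csv"),
                     row.names = FALSE)
    export_linear_fit(etiv_fit,
                      file.path(config$out_dir, "aim1_model_etiv.csv"))
    export_linear_fit(nmt_fit, file.path(config$out_dir, "nmt_model.csv"))
    utils::write.csv(rbind(cbind(model = "main", vif_main),
                           cbind(model = "etiv", vif_etiv)),
                     file.path(config$out_dir, "vif.csv"),
                     row.names = FALSE)
    factor_solution_to_json(comp$solution,
                            file.path(config$out_dir,
                                      "factor_solution.json"))
  }
  thal_row <- main_tab[main_tab$term == "thal_ml", ]
  lines <- c(
    "== Cross-sectional thalamus-cognition analysis ==",
    sprintf("seed: %d  n: %d", config$seed, main$n),
    sprintf("composite loadings: %s",
            paste(sprintf("%s=%.3f", names(comp$solution$loadings),
                          comp$solution$loadings), collapse = ", ")),
    sprintf("variance explained by factor: %.3f",
            comp$solution$variance_explained),
    sprintf("thalamus coefficient: %.4f (SE %.4f, p %.3g, FDR p %.3g)",
            thal_row$estimate, thal_row$se, thal_row$p, thal_row$p_fdr),
    sprintf("model adjusted R2: %.4f", main$adj_r_squared),
    sprintf("eTIV sensitivity thalamus coefficient: %.4f",
            etiv_fit$coefficients$estimate[
              etiv_fit$coefficients$term == "thal_ml"]),
    sprintf("max VIF (main model): %.2f", max(vif_main$vif)),
    sprintf("NMT thalamus coefficient: %.4f (p %.3g)",
            nmt_fit$coefficients$estimate[
              nmt_fit$coefficients$term == "thal_ml"],
            nmt_fit$coefficients$p[nmt_fit$coefficients$term == "thal_ml"]))
  write_lines_report(lines, config$out_dir, "aim1_summary.txt")
  list(cohort = cohort, solution = comp$solution, main = main,
       main_table = main_tab, etiv = etiv_fit, nmt = nmt_fit,
       vif_main = vif_main, vif_etiv = vif_etiv, report = lines)
}

#' Run the longitudinal LCS analyses and sensitivity suite
#'
#' Generates the longitudinal cohorts, runs the session random-intercept
#' test, the bivariate LCS fit, the sex-stratified multigroup fit and the
#' age-augmented multivariate fit, plus any enabled sensitivity stages
#' (propensity-matched refit, FIML on the attrition-sized cohort,
#' PMM multiple imputation with Rubin pooling) and the segmentation
#' agreement and fornix-connectivity stages, and writes a parameter table
#' per fit.
#'
#' @param config a [run_config()]
#' @return list with cohorts, fits and report lines
#' @export
run_aim2 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  enabled <- c("session", "bivariate", "multigroup", "multivariate_age",
               "fiml", "mi", "psm", "agreement", "connectivity")
  if (!any(unlist(config[enabled])))
    stop("no aim-2 analysis enabled")
  ensure_dir(config$out_dir)
  res <- list()
  lines <- c("== Longitudinal LCS analyses ==",
             sprintf("seed: %d  n_long: %d", config$seed, config$n_long))
  seed_of <- function(k) config$seed + k
  spec_bi <- lcs_bivariate_spec()
  save_fit <- function(fit, name) {
    if (!is.null(config$out_dir))
      utils::write.csv(tidy_lcs_fit(fit),
                       file.path(config$out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    fit
  }
  cohort_bi <- generate_longitudinal(preset_bivariate_lcs(seed = seed_of(1)),
                                     config$n_long)
  cohort_mv <- generate_longitudinal(
    preset_multivariate_lcs(seed = seed_of(2)), config$n_long)
  if (config$session) {
    st <- lapply(c(thal = "thal", hipp = "hipp"), function(rg)
      fit_session_lmm(to_session_long(cohort_mv, rg)))
    res$session <- st
    if (!is.null(config$out_dir)) {
      tab <- do.call(rbind, lapply(names(st), function(rg)
        data.frame(region = rg, session_effect = st[[rg]]$session_effect,
                   se = st[[rg]]$session_se, t = st[[rg]]$session_t,
                   p = st[[rg]]$session_p)))
      utils::write.csv(tab, file.path(config$out_dir, "session_test.csv"),
                       row.names = FALSE)
    }
    lines <- c(lines, sprintf(
      "session effect (%s): %.4f mL (p %.3g) [stage seed %d]",
      names(st), vapply(st, `[[`, 0, "session_effect"),
      vapply(st, `[[`, 0, "session_p"), seed_of(2)))
  }
  if (config$bivariate) {
    fit <- save_fit(fit_ml(spec_bi, cohort_bi), "lcs_bivariate")
    res$bivariate <- fit
    g <- fit$estimates
    lines <- c(lines, sprintf(
      "bivariate LCS: gamma_t_dh %.4f (SE %.4f), gamma_h_dt %.4f (SE %.4f), phi_ht %.3f, rho_ht %.4f [stage seed %d]",
      g["gamma_t_dh"], fit$ses["gamma_t_dh"], g["gamma_h_dt"],
      fit$ses["gamma_h_dt"], g["phi_ht"], g["rho_ht"], seed_of(1)))
  }
  if (config$multigroup) {
    cohort_mg <- generate_longitudinal(
      preset_multigroup_lcs(seed = seed_of(3)), config$n_long)
    fit <- save_fit(fit_multigroup(spec_bi, cohort_mg, "group"),
                    "lcs_multigroup")
    res$multigroup <- fit
    lines <- c(lines, sprintf(
      "multigroup LCS: female gamma_t_dh %.4f, male gamma_h_dt %.4f [stage seed %d]",
      fit$per_group$Female$estimates["gamma_t_dh"],
      fit$per_group$Male$estimates["gamma_h_dt"], seed_of(3)))
  }
  if (config$multivariate_age) {
    fit <- save_fit(fit_ml(lcs_multivariate_spec(), cohort_mv),
                    "lcs_multivariate_age")
    res$multivariate_age <- fit
    lines <- c(lines, sprintf(
      "multivariate LCS: gamma_age_dh %.4f (SE %.4f) [stage seed %d]",
      fit$estimates["gamma_age_dh"], fit$ses["gamma_age_dh"], seed_of(2)))
  }
  if (config$fiml || config$mi || config$psm) {
    cohort_full <- generate_longitudinal(
      preset_bivariate_lcs(seed = seed_of(4)), config$n_cross)
    masked <- apply_missingness(cohort_full, missingness_spec(
      "MCAR", c("thal_t2_ml", "hipp_t2_ml"),
      rate = config$followup_missing_rate, jointly = TRUE,
      seed = seed_of(5)))
    res$masked_cohort <- masked
  }
  if (config$fiml) {
    fit <- save_fit(fit_fiml(spec_bi, masked), "lcs_fiml")
    res$fiml <- fit
    lines <- c(lines, sprintf(
      "FIML (n %d, %.0f%% follow-up missing): gamma_t_dh %.4f (SE %.4f) [stage seed %d]",
      fit$n_used, 100 * attr(masked, "missingness")$realized_rate,
      fit$estimates["gamma_t_dh"], fit$ses["gamma_t_dh"], seed_of(5)))
  }
  if (config$mi) {
    imp <- impute_pmm(masked, c("thal_t2_ml", "hipp_t2_ml"),
                      c("thal_t1_ml", "hipp_t1_ml"),
                      m = config$m_imputations, seed = seed_of(6))
    mi_res <- pool_lcs_fits(imp, spec_bi,
                            labels = c("gamma_t_dh", "gamma_h_dt"))
    res$mi <- mi_res$pooled
    if (!is.null(config$out_dir))
      utils::write.csv(mi_res$pooled,
                       file.path(config$out_dir, "lcs_mi_pooled.csv"),
                       row.names = FALSE)
    gp <- mi_res$pooled[mi_res$pooled$parameter == "gamma_t_dh", ]
    lines <- c(lines, sprintf(
      "MI (m = %d, PMM): pooled gamma_t_dh %.4f (SE %.4f, df %.1f) [stage seed %d]",
      config$m_imputations, gp$estimate, gp$se, gp$df, seed_of(6)))
  }
  if (config$psm) {
    set.seed(seed_of(7))
    n_all <- nrow(masked)
    complete <- as.integer(stats::complete.cases(
      masked[, c("thal_t2_ml", "hipp_t2_ml")]))
    # stand-in lifestyle/health covariates for the propensity model (not
    # calibrated to any printed table; small association with retention)
    psd <- data.frame(
      smoking_ever = stats::rbinom(n_all, 1, 0.46 - 0.03 * complete),
      alcohol_freq = pmin(pmax(round(stats::rnorm(
        n_all, 2.73 - 0.1 * complete, 1.42)), 1), 6),
      diabetes = stats::rbinom(n_all, 1, 0.08 - 0.02 * complete),
      bmi = stats::rnorm(n_all, 27 - 0.5 * complete, 4),
      complete = complete)
    ps <- estimate_propensity(psd, c("smoking_ever", "alcohol_freq",
                                     "diabetes", "bmi"), "complete")
    mr <- match_nearest(ps$scores, complete, caliper = config$caliper,
                        seed = seed_of(7))
    matched_rows <- masked[mr$pairs$treated, , drop = FALSE]
    refit <- save_fit(fit_ml(spec_bi, matched_rows), "lcs_psm_refit")
    res$psm <- list(match = mr, refit = refit)
    if (!is.null(config$out_dir))
      utils::write.csv(mr$pairs, file.path(config$out_dir,
                                           "psm_pairs.csv"),
                       row.names = FALSE)
    lines <- c(lines, sprintf(
      "PSM: match rate %.3f (%d pairs); matched-refit gamma_t_dh %.4f [stage seed %d]",
      mr$match_rate, nrow(mr$pairs),
      refit$estimates["gamma_t_dh"], seed_of(7)))
  }
  if (config$agreement) {
    set.seed(seed_of(8))
    idx <- sample.int(nrow(cohort_bi), min(125, nrow(cohort_bi)))
    agr <- lapply(c(thal_t1_ml = "thal_t1_ml", hipp_t1_ml = "hipp_t1_ml",
                    thal_t2_ml = "thal_t2_ml", hipp_t2_ml = "hipp_t2_ml"),
                  function(cl) {
                    x <- cohort_bi[[cl]][idx]
                    bland_altman(x, simulate_pipeline_pair(x))
                  })
    res$agreement <- agr
    if (!is.null(config$out_dir)) {
      tab <- do.call(rbind, lapply(names(agr), function(cl)
        data.frame(column = cl, bias = agr[[cl]]$bias,
                   sd_diff = agr[[cl]]$sd_diff,
                   pct_within = 100 * agr[[cl]]$fraction_within)))
      utils::write.csv(tab, file.path(config$out_dir, "agreement.csv"),
                       row.names = FALSE)
    }
    lines <- c(lines, sprintf(
      "agreement (%s): %.1f%% within LOA [stage seed %d]",
      names(agr), 100 * vapply(agr, `[[`, 0, "fraction_within"),
      seed_of(8)))
  }
  if (config$connectivity) {
    cfg_fa <- preset_bivariate_lcs(seed = seed_of(9))
    cfg_fa$age_block <- preset_multivariate_lcs()$age_block
    cfg_fa$fa_block <- list(mean = 0.45, sd = 0.035,
                            slope_hipp = 0.02, slope_thal = 0.01)
    cohort_fa <- generate_longitudinal(cfg_fa, config$n_long)
    fits <- list(
      hipp = fit_ols(cohort_fa, hipp_t2_ml ~ fornix_fa + age_y +
                       interval_y + hipp_t1_ml + thal_t1_ml),
      thal = fit_ols(cohort_fa, thal_t2_ml ~ fornix_fa + age_y +
                       interval_y + hipp_t1_ml + thal_t1_ml))
    res$connectivity <- fits
    if (!is.null(config$out_dir))
      utils::write.csv(
        do.call(rbind, lapply(names(fits), function(rg)
          cbind(region = rg, fits[[rg]]$coefficients))),
        file.path(config$out_dir, "connectivity.csv"), row.names = FALSE)
    lines <- c(lines, sprintf(
      "connectivity: fornix FA -> follow-up %s volume %.3f (p %.3g) [stage seed %d]",
      names(fits),
      vapply(fits, function(f)
        f$coefficients$estimate[f$coefficients$term == "fornix_fa"], 0),
      vapply(fits, function(f)
        f$coefficients$p[f$coefficients$term == "fornix_fa"], 0),
      seed_of(9)))
  }
  write_lines_report(lines, config$out_dir, "aim2_summary.txt")
  res$report <- lines
  res$cohort_bivariate <- cohort_bi
  res$cohort_multivariate <- cohort_mv
  res
}
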