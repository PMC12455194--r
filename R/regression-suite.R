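# Multivariable linear models for the cross-sectional aim, collinearity
# (VIF) screening, Benjamini-Hochberg false-discovery-rate adjustment,
# and the two-timepoint random-intercept session test.

#' Multivariable ordinary least squares fit
#'
#' Wraps [stats::lm()] and returns a tidy coefficient table with
#' classical standard errors and two-sided t p-values (df = n - k).
#' Rank-deficient designs are rejected, naming the aliased terms.
#'
#' @param table data frame
#' @param formula model formula, e.g. `cog_composite ~ thal_ml + age_y`
#' @return object of class `linear_fit`: `coefficients` (term, estimate,
#'   se, t, p), `r_squared`, `adj_r_squared`, `n`, `residual_sd`,
#'   `model` (the underlying lm)
#' @export
fit_ols <- function(table, formula) {
  if (is.character(formula)) formula <- stats::as.formula(formula)
  mf <- stats::model.frame(formula, data = table)
  fit <- stats::lm(formula, data = table)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  out <- list(
    coefficients = data.frame(
      term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
      t = ct[, 3], p = ct[, 4], row.names = NULL,
      stringsAsFactors = FALSE),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = nrow(mf),
    residual_sd = sm$sigma,
    model = fit)
  class(out) <- "linear_fit"
  out
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear model fit: n =", x$n,
      " R2 =", round(x$r_squared, 4),
      " adj R2 =", round(x$adj_r_squared, 4),
      " residual SD =", round(x$residual_sd, 4), "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' j on the remaining predictors; values above `threshold` are flagged as
#' a collinearity risk, and perfect collinearity is reported as infinite.
#'
#' @param table data frame
#' @param terms predictor columns
#' @param threshold flag level (default 5)
#' @return data frame with columns term, vif, flagged
#' @export
vif <- function(table, terms, threshold = 5) {
  stopifnot(length(terms) >= 2)
  X <- table[, terms, drop = FALSE]
  out <- vapply(terms, function(tj) {
    f <- stats::as.formula(paste(tj, "~", paste(setdiff(terms, tj),
                                                collapse = " + ")))
    r2 <- summary(stats::lm(f, data = X))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = terms, vif = unname(out),
             flagged = unname(out > threshold),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1),
#' invariant to the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @return adjusted p-values in the input order
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Convert a wide two-scan cohort table to session-long format
#'
#' @param cohort data frame with `<region>_t1_ml` / `<region>_t2_ml`
#'   columns, `participant_id` and `interval_y`
#' @param region region prefix, e.g. `"hipp"`
#' @return long data frame with columns participant_id, session (0 =
#'   baseline, 1 = follow-up), time_y (the participant's between-scan
#'   interval, the same at both rows) and volume_ml
#' @export
to_session_long <- function(cohort, region) {
  v1 <- paste0(region, "_t1_ml"); v2 <- paste0(region, "_t2_ml")
  stopifnot(all(c(v1, v2, "participant_id", "interval_y") %in%
                  names(cohort)))
  data.frame(
    participant_id = rep(cohort$participant_id, 2),
    session = rep(c(0, 1), each = nrow(cohort)),
    time_y = rep(cohort$interval_y, 2),
    volume_ml = c(cohort[[v1]], cohort[[v2]]))
}

#' Two-timepoint random-intercept session test
#'
#' Fits `volume ~ session + time + (1 | participant)` by REML with
#' [lme4::lmer()], where `time` is the participant's between-scan
#' interval (a participant-level covariate): the session fixed effect
#' tests for a systematic volume difference between scans after
#' accounting for between-participant differences in the time between
#' scans.  Because the interval is constant within participant, in the
#' balanced two-timepoint case the session effect is estimated purely
#' within participants and equals the mean within-participant difference
#' (the difference-score OLS estimate) exactly.  Unpaired participants
#' are dropped with a warning.
#'
#' @param long_table data frame with columns participant_id, session
#'   (0/1), time_y and volume_ml (see [to_session_long()])
#' @return object of class `session_test` with the session effect, its
#'   SE, t, a two-sided p (df = number of pairs - 2), the time (interval)
#'   effect and the variance components
#' @export
fit_session_lmm <- function(long_table) {
  need <- c("participant_id", "session", "time_y", "volume_ml")
  stopifnot(all(need %in% names(long_table)))
  cnt <- table(long_table$participant_id)
  keep <- names(cnt)[cnt == 2]
  dropped <- sum(cnt != 2)
  if (dropped > 0) {
    warning(dropped, " unpaired participant(s) dropped")
    long_table <- long_table[long_table$participant_id %in% keep, ,
                             drop = FALSE]
  }
  fit <- lme4::lmer(volume_ml ~ session + time_y + (1 | participant_id),
                    data = long_table, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  t_sess <- fe[["session"]] / se[["session"]]
  npairs <- length(keep)
  out <- list(
    session_effect = fe[["session"]],
    session_se = se[["session"]],
    session_t = t_sess,
    session_p = 2 * stats::pt(-abs(t_sess), df = max(npairs - 2, 1)),
    time_effect = fe[["time_y"]],
    intercept = fe[["(Intercept)"]],
    random_intercept_var = vc$vcov[vc$grp == "participant_id"],
    residual_var = vc$vcov[vc$grp == "Residual"],
    n_pairs = npairs, n_dropped = dropped,
    model = fit)
  class(out) <- "session_test"
  out
}

#' @export
print.session_test <- function(x, ...) {
  cat("Session test (random-intercept model, ", x$n_pairs, " pairs)\n",
      sep = "")
  cat(sprintf("  session effect %.4f (SE %.4f, t %.2f, p %.3g)\n",
              x$session_effect, x$session_se, x$session_t, x$session_p))
  cat(sprintf("  time-between-scans effect %.4f\n", x$time_effect))
  cat(sprintf("  variance: random intercept %.4f, residual %.4f\n",
              x$random_intercept_var, x$residual_var))
  invisible(x)
}

#' Export a linear fit as a tidy CSV table
#'
#' @param fit a `linear_fit`
#' @param path output CSV path
#' @param fdr append BH-adjusted p-values for the non-intercept terms
#' @return the exported data frame, invisibly
#' @export
export_linear_fit <- function(fit, path, fdr = FALSE) {
  tab <- fit$coefficients
  if (fdr) {
    tab$p_fdr <- NA_real_
    idx <- tab$term != "(Intercept)"
    tab$p_fdr[idx] <- bh_fdr(tab$p[idx])
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
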