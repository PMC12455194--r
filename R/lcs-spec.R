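# Internal representation of a structural model over observed + latent
# variables: directed paths A (A[to, from]), symmetric covariances S, and
# means/intercepts M.  Free cells carry a label; cells sharing a label are
# constrained equal.  Implied moments are assembled from
#   mu    = G (I - A)^-1 M
#   Sigma = G (I - A)^-1 S (I - A)^-T G'
# where G selects the observed rows.

new_lcs_spec <- function(observed, latent, free, A0, S0, M0,
                         changes = NULL, exog = character(),
                         convention = "atrophy") {
  vars <- c(observed, latent)
  stopifnot(!anyDuplicated(vars))
  lab <- unique(free$label)
  kind <- vapply(lab, function(l) free$kind[match(l, free$label)], character(1))
  start <- vapply(lab, function(l) free$start[match(l, free$label)], numeric(1))
  spec <- list(
    observed = observed, latent = latent, vars = vars,
    free = free, labels = lab, kinds = kind, start = start,
    A0 = A0, S0 = S0, M0 = M0,
    changes = changes, exog = exog, convention = convention
  )
  class(spec) <- "lcs_spec"
  spec
}

free_row <- function(matrix, row, col, label, kind, start) {
  data.frame(matrix = matrix, row = row, col = col, label = label,
             kind = kind, start = start, stringsAsFactors = FALSE)
}

#' Number of free parameters in a model specification
#' @param spec an `lcs_spec` object
#' @return integer count of unique parameter labels
#' @export
n_free_params <- function(spec) length(spec$labels)

#' Number of first- and second-order sample moments the model is fitted to
#' @param spec an `lcs_spec` object
#' @return integer: p means plus p(p+1)/2 (co)variances
#' @export
n_sample_moments <- function(spec) {
  p <- length(spec$observed)
  p + p * (p + 1L) / 2L
}

fill_matrices <- function(spec, theta) {
  A <- spec$A0; S <- spec$S0; M <- spec$M0
  f <- spec$free
  v <- theta[f$label]
  for (m in c("A", "S", "M")) {
    sel <- f$matrix == m
    if (!any(sel)) next
    i <- match(f$row[sel], spec$vars)
    j <- match(f$col[sel], spec$vars)
    if (m == "A") {
      A[cbind(i, j)] <- v[sel]
    } else if (m == "S") {
      S[cbind(i, j)] <- v[sel]
      S[cbind(j, i)] <- v[sel]
    } else {
      M[i] <- v[sel]
    }
  }
  list(A = A, S = S, M = M)
}

check_theta <- function(spec, theta) {
  if (is.null(names(theta))) {
    if (length(theta) != length(spec$labels))
      stop("theta must be named or have length ", length(spec$labels))
    names(theta) <- spec$labels
  }
  missing_lab <- setdiff(spec$labels, names(theta))
  if (length(missing_lab))
    stop("theta lacks parameters: ", paste(missing_lab, collapse = ", "))
  if (!all(is.finite(theta[spec$labels])))
    stop("non-finite parameter values in theta")
  theta[spec$labels]
}

#' Model-implied mean vector and covariance matrix
#'
#' Substitutes the latent change scores out of the structural equations and
#' returns the implied first and second moments of the observed variables.
#'
#' @param spec an `lcs_spec` object
#' @param theta named numeric vector covering every free parameter label
#' @return list with elements `mean` (named vector) and `cov` (matrix)
#' @export
implied_moments <- function(spec, theta) {
  theta <- check_theta(spec, theta)
  mats <- fill_matrices(spec, theta)
  k <- length(spec$vars)
  B <- solve(diag(k) - mats$A)
  mu <- drop(B %*% mats$M)
  Sg <- B %*% mats$S %*% t(B)
  oi <- match(spec$observed, spec$vars)
  mean_o <- mu[oi]; names(mean_o) <- spec$observed
  cov_o <- Sg[oi, oi, drop = FALSE]
  dimnames(cov_o) <- list(spec$observed, spec$observed)
  list(mean = mean_o, cov = cov_o)
}

#' Normal-theory maximum-likelihood discrepancy
#'
#' `F = ln|Sigma| + tr(S Sigma^-1) + (m - mu)' Sigma^-1 (m - mu) - ln|S| - p`,
#' non-negative and zero exactly when the implied moments reproduce the
#' sample moments.
#'
#' @param spec an `lcs_spec` object
#' @param theta named parameter vector
#' @param sample_mean sample mean vector over `spec$observed`
#' @param sample_cov sample covariance matrix (n-1 denominator)
#' @param n sample size (unused by F itself; kept for interface symmetry)
#' @return scalar discrepancy value
#' @export
ml_discrepancy <- function(spec, theta, sample_mean, sample_cov, n = NULL) {
  imp <- implied_moments(spec, theta)
  p <- length(spec$observed)
  sample_mean <- sample_mean[spec$observed]
  sample_cov <- sample_cov[spec$observed, spec$observed, drop = FALSE]
  ch <- tryCatch(chol(imp$cov), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular or indefinite implied covariance (condition number ",
         format(kappa(imp$cov)), ")")
  }
  logdet_imp <- 2 * sum(log(diag(ch)))
  Sinv_S <- chol2inv(ch) %*% sample_cov
  d <- sample_mean - imp$mean
  quad <- drop(crossprod(backsolve(ch, d, transpose = TRUE)))
  logdet_s <- as.numeric(determinant(sample_cov, logarithm = TRUE)$modulus)
  as.numeric(logdet_imp + sum(diag(Sinv_S)) + quad - logdet_s - p)
}

# --- constructors for the LCS family -------------------------------------

lcs_change_block <- function(pairs, convention) {
  # pairs: data.frame(change, baseline, followup)
  sgn <- if (convention == "atrophy") -1 else 1
  cbind(pairs, sign = sgn)
}

#' Bivariate latent change score model specification
#'
#' Two regions measured at two occasions.  Follow-up volumes are defined by
#' fixed unit loadings (follow-up = baseline - change under the
#' atrophy-positive convention), the two latent changes regress on both
#' baselines (self-feedback `beta_*` and cross-couplings `gamma_*`), the
#' baselines carry a free covariance `phi_ht` and the change residuals a
#' free covariance `rho_ht`.  Just-identified: 14 free parameters against
#' 14 sample moments.
#'
#' @param vars character(4): baseline/follow-up column names, in the order
#'   thalamus baseline, thalamus follow-up, hippocampus baseline,
#'   hippocampus follow-up
#' @param convention `"atrophy"` (change = baseline - follow-up, the
#'   default) or `"growth"` (change = follow-up - baseline)
#' @return an `lcs_spec` object
#' @export
lcs_bivariate_spec <- function(vars = c("thal_t1_ml", "thal_t2_ml",
                                        "hipp_t1_ml", "hipp_t2_ml"),
                               convention = c("atrophy", "growth")) {
  convention <- match.arg(convention)
  stopifnot(length(vars) == 4)
  tb <- vars[1]; tf <- vars[2]; hb <- vars[3]; hf <- vars[4]
  observed <- c(tb, hb, tf, hf)
  latent <- c("d_thal", "d_hipp")
  allv <- c(observed, latent)
  k <- length(allv)
  A0 <- matrix(0, k, k, dimnames = list(allv, allv))
  S0 <- matrix(0, k, k, dimnames = list(allv, allv))
  M0 <- setNames(numeric(k), allv)
  sgn <- if (convention == "atrophy") -1 else 1
  A0[tf, tb] <- 1; A0[tf, "d_thal"] <- sgn
  A0[hf, hb] <- 1; A0[hf, "d_hipp"] <- sgn
  free <- rbind(
    free_row("A", "d_thal", tb, "beta_t",     "path", 0),
    free_row("A", "d_hipp", hb, "beta_h",     "path", 0),
    free_row("A", "d_hipp", tb, "gamma_t_dh", "path", 0),
    free_row("A", "d_thal", hb, "gamma_h_dt", "path", 0),
    free_row("S", tb, tb, "phi_t",  "variance", 1),
    free_row("S", hb, hb, "phi_h",  "variance", 1),
    free_row("S", tb, hb, "phi_ht", "covariance", 0),
    free_row("S", "d_thal", "d_thal", "psi_t", "variance", 0.05),
    free_row("S", "d_hipp", "d_hipp", "psi_h", "variance", 0.05),
    free_row("S", "d_thal", "d_hipp", "rho_ht", "covariance", 0),
    free_row("M", tb, tb, "mu_t", "mean", 10),
    free_row("M", hb, hb, "mu_h", "mean", 5),
    free_row("M", "d_thal", "d_thal", "alpha_t", "intercept", 0),
    free_row("M", "d_hipp", "d_hipp", "alpha_h", "intercept", 0)
  )
  changes <- data.frame(change = c("d_thal", "d_hipp"),
                        baseline = c(tb, hb), followup = c(tf, hf),
                        stringsAsFactors = FALSE)
  new_lcs_spec(observed, latent, free, A0, S0, M0,
               changes = lcs_change_block(changes, convention),
               exog = c(tb, hb), convention = convention)
}

#' Multivariate latent change score model with baseline age and scan interval
#'
#' Extends [lcs_bivariate_spec()] with baseline age as an exogenous
#' predictor of both latent changes (`gamma_age_dh`, `gamma_age_dt`) and the
#' between-scan interval as an exogenous variable whose covariances with the
#' change residuals are free (`rho_t_int`, `rho_h_int`).  The exogenous
#' block (two baselines, age, interval) is saturated.  Just-identified.
#'
#' @inheritParams lcs_bivariate_spec
#' @param age_var,interval_var column names for baseline age (years) and the
#'   between-scan interval (years)
#' @return an `lcs_spec` object
#' @export
lcs_multivariate_spec <- function(vars = c("thal_t1_ml", "thal_t2_ml",
                                           "hipp_t1_ml", "hipp_t2_ml"),
                                  age_var = "age_y",
                                  interval_var = "interval_y",
                                  convention = c("atrophy", "growth")) {
  convention <- match.arg(convention)
  base <- lcs_bivariate_spec(vars, convention)
  tb <- vars[1]; hb <- vars[3]
  observed <- c(base$observed, age_var, interval_var)
  latent <- base$latent
  allv <- c(observed, latent)
  k <- length(allv)
  A0 <- matrix(0, k, k, dimnames = list(allv, allv))
  S0 <- matrix(0, k, k, dimnames = list(allv, allv))
  M0 <- setNames(numeric(k), allv)
  old <- c(base$observed, base$latent)
  A0[old, old] <- base$A0; S0[old, old] <- base$S0; M0[old] <- base$M0
  free <- rbind(
    base$free,
    free_row("A", "d_hipp", age_var, "gamma_age_dh", "path", 0),
    free_row("A", "d_thal", age_var, "gamma_age_dt", "path", 0),
    free_row("S", age_var, age_var, "phi_age", "variance", 1),
    free_row("S", interval_var, interval_var, "phi_int", "variance", 0.05),
    free_row("S", age_var, tb, "phi_t_age", "covariance", 0),
    free_row("S", age_var, hb, "phi_h_age", "covariance", 0),
    free_row("S", age_var, interval_var, "phi_age_int", "covariance", 0),
    free_row("S", interval_var, tb, "phi_t_int", "covariance", 0),
    free_row("S", interval_var, hb, "phi_h_int", "covariance", 0),
    free_row("S", interval_var, "d_thal", "rho_t_int", "covariance", 0),
    free_row("S", interval_var, "d_hipp", "rho_h_int", "covariance", 0),
    free_row("M", age_var, age_var, "mu_age", "mean", 60),
    free_row("M", interval_var, interval_var, "mu_int", "mean", 2)
  )
  new_lcs_spec(observed, latent, free, A0, S0, M0,
               changes = base$changes,
               exog = c(tb, hb, age_var, interval_var),
               convention = convention)
}

#' Saturated model specification
#'
#' All means, variances and covariances of the observed variables free;
#' zero degrees of freedom, so the ML fit reproduces the sample moments
#' exactly and the chi-square is zero.
#'
#' @param vars observed variable names
#' @return an `lcs_spec` object
#' @export
saturated_spec <- function(vars) {
  k <- length(vars)
  A0 <- matrix(0, k, k, dimnames = list(vars, vars))
  S0 <- A0
  M0 <- setNames(numeric(k), vars)
  rows <- list()
  for (i in seq_len(k)) {
    rows[[length(rows) + 1]] <-
      free_row("M", vars[i], vars[i], paste0("mean_", vars[i]), "mean", 0)
    rows[[length(rows) + 1]] <-
      free_row("S", vars[i], vars[i], paste0("var_", vars[i]),
               "variance", 1)
    if (i < k) for (j in seq((i + 1), k)) {
      rows[[length(rows) + 1]] <-
        free_row("S", vars[i], vars[j],
                 paste0("cov_", vars[i], "_", vars[j]), "covariance", 0)
    }
  }
  free <- do.call(rbind, rows)
  changes <- data.frame(change = character(0), baseline = character(0),
                        followup = character(0), sign = numeric(0))
  new_lcs_spec(vars, character(0), free, A0, S0, M0,
               changes = changes, exog = vars, convention = "atrophy")
}

# --- serialization --------------------------------------------------------

#' Serialize a model specification to JSON
#' @param spec an `lcs_spec` object
#' @param path optional file to write to
#' @return JSON string (invisibly when `path` given)
#' @export
lcs_spec_to_json <- function(spec, path = NULL) {
  payload <- list(
    observed = spec$observed, latent = spec$latent,
    convention = spec$convention, exog = spec$exog,
    changes = spec$changes, free = spec$free,
    A0 = spec$A0, S0 = spec$S0, M0 = as.list(spec$M0)
  )
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a model specification from JSON
#' @param json JSON string or path to a JSON file
#' @return an `lcs_spec` object
#' @export
lcs_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  allv <- c(x$observed, x$latent)
  as_named_matrix <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(allv, allv)
    m
  }
  A0 <- as_named_matrix(x$A0)
  S0 <- as_named_matrix(x$S0)
  M0 <- setNames(as.numeric(unlist(x$M0)[allv]), allv)
  new_lcs_spec(x$observed, x$latent, as.data.frame(x$free), A0, S0, M0,
               changes = as.data.frame(x$changes), exog = x$exog,
               convention = x$convention)
}

#' @export
print.lcs_spec <- function(x, ...) {
  cat("Latent change score model specification\n")
  cat("  observed:", paste(x$observed, collapse = ", "), "\n")
  cat("  latent:  ", paste(x$latent, collapse = ", "), "\n")
  cat("  free parameters:", length(x$labels),
      " sample moments:", n_sample_moments(x),
      " df:", n_sample_moments(x) - length(x$labels), "\n")
  cat("  change convention:", x$convention, "\n")
  invisible(x)
}
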