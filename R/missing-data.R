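# Selection-bias sensitivity machinery: logistic propensity scores,
# greedy 1:1 nearest-neighbour caliper matching without replacement,
# predictive-mean-matching multiple imputation, and Rubin's-rules pooling
# with Barnard-Rubin degrees of freedom.

#' Logistic propensity scores
#'
#' Fits membership ~ covariates by logistic regression (iteratively
#' reweighted least squares via [stats::glm()]) and returns the fitted
#' probabilities.  Complete separation is rejected with a diagnostic.
#'
#' @param table data frame
#' @param covariates covariate columns (numeric or 0/1 encoded)
#' @param membership_column binary (0/1 or logical) group indicator
#' @return list with `scores` (per-row probabilities in (0,1)),
#'   `coefficients` and the glm `model`
#' @export
estimate_propensity <- function(table, covariates, membership_column) {
  y <- table[[membership_column]]
  if (is.null(y)) stop("membership column '", membership_column,
                       "' not found")
  y <- as.integer(as.logical(y))
  if (!all(y %in% 0:1) || length(unique(y)) < 2)
    stop("membership must be binary with both groups present")
  f <- stats::as.formula(paste(
    ".y ~", if (length(covariates)) paste(covariates, collapse = " + ")
    else "1"))
  dd <- table[, covariates, drop = FALSE]
  dd$.y <- y
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = dd, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  p <- stats::fitted(fit)
  if (warned && (min(p[y == 1]) > max(p[y == 0])))
    stop("complete separation: covariates perfectly predict membership ",
         "(max |coefficient| = ",
         format(max(abs(stats::coef(fit))), digits = 3), ")")
  list(scores = as.numeric(p), coefficients = stats::coef(fit),
       model = fit)
}

#' Greedy 1:1 nearest-neighbour caliper matching without replacement
#'
#' Walks the smaller group in the stated order (default: descending
#' propensity score, seed-controlled tie-breaking), matching each member
#' to the nearest unused member of the larger group; candidate matches
#' whose absolute score difference exceeds the caliper (on the
#' probability scale) are discarded.
#'
#' @param scores per-row propensity scores
#' @param membership binary indicator (1 = smaller/treated group in the
#'   usual design, but the smaller group is detected automatically)
#' @param caliper maximum |score difference| for a valid pair
#' @param order `"desc"`, `"asc"` or `"given"` processing order over the
#'   smaller group
#' @param seed optional seed for tie-breaking
#' @return object of class `match_result`: `pairs` (data frame of row
#'   indices `treated`, `control`, and their scores), `scores`,
#'   `caliper`, `match_rate` (fraction of the smaller group matched)
#' @export
match_nearest <- function(scores, membership, caliper,
                          order = c("desc", "asc", "given"), seed = NULL) {
  order <- match.arg(order)
  set_seed_if(seed)
  membership <- as.integer(as.logical(membership))
  stopifnot(length(scores) == length(membership))
  g1 <- which(membership == 1); g0 <- which(membership == 0)
  if (!length(g1) || !length(g0)) stop("both groups must be non-empty")
  swap <- length(g1) > length(g0)
  small <- if (swap) g0 else g1
  large <- if (swap) g1 else g0
  ord <- switch(order,
                desc = small[order(scores[small], stats::runif(length(small)),
                                   decreasing = TRUE)],
                asc = small[order(scores[small], stats::runif(length(small)))],
                given = small)
  used <- logical(length(scores))
  pairs <- matrix(0L, 0, 2)
  for (i in ord) {
    cand <- large[!used[large]]
    if (!length(cand)) break
    dd <- abs(scores[cand] - scores[i])
    j <- cand[which.min(dd)]
    if (abs(scores[j] - scores[i]) <= caliper) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  pr <- data.frame(
    treated = if (swap) pairs[, 2] else pairs[, 1],
    control = if (swap) pairs[, 1] else pairs[, 2])
  pr$treated_score <- scores[pr$treated]
  pr$control_score <- scores[pr$control]
  out <- list(pairs = pr, scores = scores, caliper = caliper,
              match_rate = nrow(pr) / length(small))
  class(out) <- "match_result"
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat("1:1 nearest-neighbour matching (caliper ", format(x$caliper),
      "): ", nrow(x$pairs), " pairs, match rate ",
      round(100 * x$match_rate, 1), "%\n", sep = "")
  invisible(x)
}

#' Predictive-mean-matching multiple imputation
#'
#' For each target column and each of `m` imputations: fit the linear
#' model of the target on the predictors over the observed rows, draw
#' regression parameters from their normal-inverse-gamma posterior,
#' predict all rows (observed rows with the posterior mean, missing rows
#' with the drawn parameters), and fill each missing cell with the
#' observed value of a donor drawn uniformly from the `k_donors` nearest
#' observed rows by predicted value.  Every imputed value is therefore an
#' observed donor value.
#'
#' @param table data frame with missing target cells
#' @param target_columns columns to impute
#' @param predictors fully observed predictor columns
#' @param m number of imputations (default 40)
#' @param k_donors donor pool size (default 5)
#' @param draw_params set FALSE to skip the Bayesian parameter draw
#'   (with `k_donors = 1` this reduces to deterministic
#'   nearest-predicted-value imputation)
#' @param seed optional base seed; imputation i uses `seed + i`
#' @return object of class `imputation_set`: `imputations` (list of m
#'   completed tables), `m`, `k_donors`, `seed`
#' @export
impute_pmm <- function(table, target_columns, predictors, m = 40L,
                       k_donors = 5L, draw_params = TRUE, seed = NULL) {
  stopifnot(m >= 1, k_donors >= 1)
  miss_c <- setdiff(c(target_columns, predictors), names(table))
  if (length(miss_c))
    stop("unknown column(s): ", paste(miss_c, collapse = ", "))
  if (anyNA(table[, predictors]))
    stop("predictors must be observed everywhere")
  X <- cbind(1, as.matrix(table[, predictors, drop = FALSE]))
  imputations <- vector("list", m)
  for (i in seq_len(m)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + i)
    filled <- table
    for (tc in target_columns) {
      yy <- table[[tc]]
      obs <- which(!is.na(yy)); mis <- which(is.na(yy))
      if (!length(mis)) next
      if (length(obs) <= ncol(X))
        stop("fewer observed rows (", length(obs), ") than parameters (",
             ncol(X), ") for '", tc, "'")
      Xo <- X[obs, , drop = FALSE]
      XtX <- crossprod(Xo)
      V <- solve(XtX)
      bhat <- drop(V %*% crossprod(Xo, yy[obs]))
      res <- yy[obs] - drop(Xo %*% bhat)
      nu <- length(obs) - ncol(X)
      s2 <- sum(res^2) / nu
      if (draw_params) {
        s2_star <- s2 * nu / stats::rchisq(1, nu)
        bstar <- bhat + drop(chol(V) %*% stats::rnorm(ncol(X))) *
          sqrt(s2_star)
      } else {
        bstar <- bhat
      }
      yhat_obs <- drop(X[obs, , drop = FALSE] %*% bhat)
      yhat_mis <- drop(X[mis, , drop = FALSE] %*% bstar)
      k <- min(k_donors, length(obs))
      for (jj in seq_along(mis)) {
        dd <- abs(yhat_obs - yhat_mis[jj])
        donors <- obs[order(dd)[seq_len(k)]]
        pick <- if (k == 1) donors else donors[sample.int(k, 1)]
        filled[[tc]][mis[jj]] <- yy[pick]
      }
    }
    imputations[[i]] <- filled
  }
  out <- list(imputations = imputations, m = m, k_donors = k_donors,
              seed = seed)
  class(out) <- "imputation_set"
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and
#' `B` the between-imputation variance; degrees of freedom by
#' Barnard-Rubin (reducing to the classical `(m-1)/lambda^2` when the
#' complete-data df are infinite).
#'
#' @param estimates_per_imputation numeric vector (one parameter) or
#'   matrix/data frame (rows = imputations, columns = parameters)
#' @param variances_per_imputation squared standard errors, same shape
#' @param dfcom complete-data degrees of freedom (default `Inf`)
#' @return data frame with columns parameter, estimate, se, df, p
#'   (two-sided t test of zero), within_var, between_var
#' @export
pool_rubin <- function(estimates_per_imputation, variances_per_imputation,
                       dfcom = Inf) {
  Q <- as.matrix(estimates_per_imputation)
  U <- as.matrix(variances_per_imputation)
  if (!identical(dim(Q), dim(U)))
    stop("estimates and variances have mismatched shapes")
  if (!is.null(colnames(Q)) && !is.null(colnames(U)) &&
      !identical(colnames(Q), colnames(U)))
    stop("estimates and variances have mismatched labels")
  m <- nrow(Q)
  stopifnot(m >= 1)
  qbar <- colMeans(Q)
  W <- colMeans(U)
  B <- if (m > 1) apply(Q, 2, stats::var) else rep(0, ncol(Q))
  Tv <- W + (1 + 1 / m) * B
  lambda <- (1 + 1 / m) * B / Tv
  lambda <- pmin(pmax(lambda, 1e-12), 1 - 1e-12)
  nu_old <- (m - 1) / lambda^2
  if (is.finite(dfcom)) {
    nu_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- nu_old * nu_obs / (nu_old + nu_obs)
  } else {
    df <- nu_old
  }
  se <- sqrt(Tv)
  data.frame(
    parameter = colnames(Q) %||% paste0("par", seq_along(qbar)),
    estimate = unname(qbar), se = unname(se), df = unname(df),
    p = unname(2 * stats::pt(-abs(qbar / se), df = df)),
    within_var = unname(W), between_var = unname(B),
    stringsAsFactors = FALSE)
}

#' Fit an LCS model on every imputed dataset and pool a set of labels
#'
#' @param imputation_set an [impute_pmm()] result
#' @param spec an `lcs_spec`
#' @param labels parameter labels to pool (default all)
#' @return list with `pooled` (Rubin-rules table) and `fits`
#' @export
pool_lcs_fits <- function(imputation_set, spec, labels = NULL) {
  stopifnot(inherits(imputation_set, "imputation_set"))
  fits <- lapply(imputation_set$imputations, function(d)
    fit_ml(spec, d))
  labels <- labels %||% spec$labels
  Q <- t(vapply(fits, function(f) f$estimates[labels],
                numeric(length(labels))))
  U <- t(vapply(fits, function(f) f$ses[labels]^2,
                numeric(length(labels))))
  colnames(Q) <- colnames(U) <- labels
  list(pooled = pool_rubin(Q, U), fits = fits)
}

#' Attrition comparison of two cohorts
#'
#' Means (or proportions for 0/1 columns) of shared covariates in each
#' cohort, with the standardized mean difference.
#'
#' @param full,subset data frames (e.g. the cross-sectional sample and
#'   the longitudinal subsample)
#' @param columns covariate columns present in both
#' @return data frame with per-column summaries
#' @export
attrition_table <- function(full, subset, columns) {
  rows <- lapply(columns, function(cl) {
    a <- full[[cl]]; b <- subset[[cl]]
    sd_pool <- sqrt((stats::var(a, na.rm = TRUE) +
                       stats::var(b, na.rm = TRUE)) / 2)
    data.frame(column = cl,
               mean_full = mean(a, na.rm = TRUE),
               mean_subset = mean(b, na.rm = TRUE),
               smd = (mean(b, na.rm = TRUE) - mean(a, na.rm = TRUE)) /
                 sd_pool,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
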