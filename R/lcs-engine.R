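# Maximum-likelihood fitting of latent change score models: closed-form
# starting values, quasi-Newton refinement on an unconstrained
# reparameterization (log scale for variances), casewise and
# pattern-grouped (FIML) likelihoods, multigroup fitting and
# observed-information standard errors.

# transform between the natural parameter space and the unconstrained
# optimizer space: variances are optimized on the log scale.
theta_to_free <- function(spec_kinds, theta) {
  v <- spec_kinds == "variance"
  out <- theta
  out[v] <- log(pmax(theta[v], 1e-12))
  out
}
free_to_theta <- function(spec_kinds, tpar) {
  v <- spec_kinds == "variance"
  out <- tpar
  out[v] <- exp(tpar[v])
  out
}

sample_moments <- function(data, observed) {
  y <- as.matrix(data[, observed, drop = FALSE])
  storage.mode(y) <- "double"
  cc <- stats::complete.cases(y)
  y <- y[cc, , drop = FALSE]
  n <- nrow(y)
  list(mean = colMeans(y), cov = stats::cov(y), n = n, y = y)
}

# Closed-form (difference-score regression) solution for the LCS family:
# exogenous moments are the sample moments, paths/intercepts come from the
# multivariate OLS of the observed change scores on each change's parents,
# residual (co)variances from the OLS residual covariance, and free
# exogenous-to-residual covariances from the residual cross-moments.  For
# just-identified specs of this family (the bivariate, multigroup and
# age-augmented models) this is the exact ML solution.
lcs_closed_form <- function(spec, xbar, S) {
  ch <- spec$changes
  if (is.null(ch) || !length(spec$exog)) return(spec$start)
  ex <- spec$exog
  p_obs <- spec$observed
  # transform observed moments to (exog, D) moments
  TT <- matrix(0, length(ex) + nrow(ch), length(p_obs),
               dimnames = list(c(ex, ch$change), p_obs))
  for (e in ex) TT[e, e] <- 1
  for (i in seq_len(nrow(ch))) {
    TT[ch$change[i], ch$baseline[i]] <- -ch$sign[i]
    TT[ch$change[i], ch$followup[i]] <- ch$sign[i]
  }
  m2 <- drop(TT %*% xbar[p_obs])
  S2 <- TT %*% S[p_obs, p_obs] %*% t(TT)
  f <- spec$free
  # parents of each change = observed vars with a free path into it
  parents <- lapply(ch$change, function(d)
    f$col[f$matrix == "A" & f$row == d & f$col %in% p_obs])
  names(parents) <- ch$change
  est <- spec$start
  coefs <- list(); icepts <- numeric(nrow(ch)); names(icepts) <- ch$change
  for (d in ch$change) {
    pa <- parents[[d]]
    if (length(pa)) {
      b <- solve(S2[pa, pa, drop = FALSE], S2[pa, d])
    } else b <- numeric(0)
    names(b) <- pa
    coefs[[d]] <- b
    icepts[d] <- m2[d] - sum(b * m2[pa])
  }
  resid_cov <- function(d1, d2) {
    b1 <- coefs[[d1]]; b2 <- coefs[[d2]]
    S2[d1, d2] -
      (if (length(b1)) sum(b1 * S2[names(b1), d2]) else 0) -
      (if (length(b2)) sum(b2 * S2[names(b2), d1]) else 0) +
      (if (length(b1) && length(b2))
        drop(t(b1) %*% S2[names(b1), names(b2), drop = FALSE] %*% b2) else 0)
  }
  for (r in seq_len(nrow(f))) {
    lab <- f$label[r]; mi <- f$matrix[r]; i <- f$row[r]; j <- f$col[r]
    if (mi == "A" && i %in% ch$change && j %in% p_obs) {
      est[lab] <- coefs[[i]][[j]]
    } else if (mi == "M" && i %in% ex) {
      est[lab] <- m2[i]
    } else if (mi == "M" && i %in% ch$change) {
      est[lab] <- icepts[i]
    } else if (mi == "S" && i %in% ex && j %in% ex) {
      est[lab] <- S2[i, j]
    } else if (mi == "S" && i %in% ch$change && j %in% ch$change) {
      est[lab] <- resid_cov(i, j)
    } else if (mi == "S" && xor(i %in% ex, j %in% ex)) {
      e <- if (i %in% ex) i else j
      d <- if (i %in% ex) j else i
      b <- coefs[[d]]
      est[lab] <- S2[e, d] - (if (length(b)) sum(b * S2[names(b), e]) else 0)
    }
  }
  # guard: variances must start strictly positive
  v <- spec$kinds[names(est)] == "variance"
  est[v] <- pmax(est[v], 1e-8)
  est
}

penalized_objective <- function(fn) {
  function(par) {
    val <- tryCatch(fn(par), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
}

num_grad <- function(fn, par, eps = 1e-6) {
  g <- numeric(length(par))
  for (i in seq_along(par)) {
    h <- eps * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    g[i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  g
}

# casewise Gaussian log-likelihood from complete-data moments
gauss_loglik_moments <- function(mu, Sigma, xbar, S, n) {
  p <- length(mu)
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  Sn <- S * (n - 1) / n
  d <- xbar - mu
  quad <- drop(crossprod(backsolve(ch, d, transpose = TRUE)))
  -0.5 * n * (p * log(2 * pi) + logdet +
                sum(diag(chol2inv(ch) %*% Sn)) + quad)
}

make_fit_result <- function(spec, est, se, loglik, chi2, df, n, converged,
                            missing_method, negloglik_fn, grad_norm,
                            per_group = NULL) {
  out <- list(estimates = est, ses = se, loglik = loglik,
              chi_square = chi2, df = df, n_used = n,
              converged = converged, missing_method = missing_method,
              per_group = per_group, spec = spec,
              negloglik_fn = negloglik_fn, grad_norm = grad_norm)
  class(out) <- "lcs_fit"
  out
}

#' Fit a latent change score model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy [ml_discrepancy()] over the free
#' parameters, starting from the closed-form difference-score regression
#' solution (exact for just-identified members of the LCS family) and
#' refining by BFGS on an unconstrained reparameterization.  The sample
#' covariance uses the n-1 denominator and `chi_square = (n-1) F_min`.
#'
#' @param spec an `lcs_spec` object
#' @param data data frame containing the observed variables; incomplete
#'   rows are dropped (see [fit_fiml()] for incomplete data)
#' @param se compute observed-information standard errors (default TRUE)
#' @param max_iter BFGS iteration cap
#' @return an `lcs_fit` object with estimates, standard errors,
#'   log-likelihood, chi-square, df and convergence metadata
#' @export
fit_ml <- function(spec, data, se = TRUE, max_iter = 500L) {
  sm <- sample_moments(data, spec$observed)
  if (sm$n < n_free_params(spec))
    stop("only ", sm$n, " complete cases for ", n_free_params(spec),
         " free parameters")
  df <- n_sample_moments(spec) - n_free_params(spec)
  if (df < 0) stop("under-identified model: ", n_free_params(spec),
                   " free parameters exceed ", n_sample_moments(spec),
                   " sample moments")
  start <- lcs_closed_form(spec, sm$mean, sm$cov)
  kinds <- spec$kinds
  objective <- penalized_objective(function(tpar) {
    theta <- free_to_theta(kinds, tpar)
    names(theta) <- spec$labels
    ml_discrepancy(spec, theta, sm$mean, sm$cov, sm$n)
  })
  t0 <- theta_to_free(kinds, start[spec$labels])
  opt <- stats::optim(t0, objective, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  # keep the better of start and optimizer output (monotonicity guarantee)
  if (objective(t0) < opt$value) {
    opt$par <- t0; opt$value <- objective(t0); opt$convergence <- 0L
  }
  est <- free_to_theta(kinds, opt$par)
  names(est) <- spec$labels
  gn <- sqrt(sum(num_grad(objective, opt$par)^2))
  imp <- implied_moments(spec, est)
  ll <- gauss_loglik_moments(imp$mean, imp$cov, sm$mean, sm$cov, sm$n)
  negll <- function(theta) {
    names(theta) <- spec$labels
    impl <- implied_moments(spec, theta)
    -gauss_loglik_moments(impl$mean, impl$cov, sm$mean, sm$cov, sm$n)
  }
  fit <- make_fit_result(
    spec, est, se = setNames(rep(NA_real_, length(est)), names(est)),
    loglik = ll, chi2 = max(0, (sm$n - 1) * opt$value), df = df, n = sm$n,
    converged = opt$convergence == 0L && is.finite(opt$value),
    missing_method = "complete", negloglik_fn = negll, grad_norm = gn)
  if (se) fit <- standard_errors(fit)
  fit
}

missingness_patterns <- function(y) {
  obs <- !is.na(y)
  if (any(rowSums(obs) == 0))
    stop("rows with no observed variables are not allowed")
  key <- apply(obs, 1L, paste, collapse = "")
  lapply(split(seq_len(nrow(y)), key), function(idx) {
    vars <- which(obs[idx[1], ])
    yk <- y[idx, vars, drop = FALSE]
    nk <- nrow(yk)
    xb <- colMeans(yk)
    Sn <- if (nk > 1) stats::cov(yk) * (nk - 1) / nk else
      matrix(0, length(vars), length(vars))
    list(vars = vars, n = nk, mean = xb, Sn = Sn)
  })
}

fiml_negloglik_factory <- function(spec, patterns) {
  labels <- spec$labels
  function(theta) {
    names(theta) <- labels
    imp <- implied_moments(spec, theta)
    total <- 0
    for (pt in patterns) {
      mu <- imp$mean[pt$vars]
      Sg <- imp$cov[pt$vars, pt$vars, drop = FALSE]
      ch <- chol(Sg)
      logdet <- 2 * sum(log(diag(ch)))
      d <- pt$mean - mu
      quad <- drop(crossprod(backsolve(ch, d, transpose = TRUE)))
      trc <- sum(diag(chol2inv(ch) %*% pt$Sn))
      total <- total + 0.5 * pt$n *
        (length(pt$vars) * log(2 * pi) + logdet + trc + quad)
    }
    total
  }
}

#' Fit a latent change score model by full-information maximum likelihood
#'
#' Each row contributes the marginal multivariate-normal log-density over
#' its observed variables; rows are grouped by missingness pattern for
#' efficiency.  Reduces exactly to [fit_ml()] when the data are complete.
#'
#' @inheritParams fit_ml
#' @param data data frame; rows may have missing cells but every row must
#'   observe at least one model variable, and every variable must be
#'   observed in at least one row
#' @return an `lcs_fit` object with `missing_method = "fiml"`;
#'   `chi_square` is `NA` (no saturated-model comparison is computed)
#' @export
fit_fiml <- function(spec, data, se = TRUE, max_iter = 500L) {
  y <- as.matrix(data[, spec$observed, drop = FALSE])
  storage.mode(y) <- "double"
  if (any(colSums(!is.na(y)) == 0))
    stop("variable(s) missing in every row: ",
         paste(spec$observed[colSums(!is.na(y)) == 0], collapse = ", "))
  patterns <- missingness_patterns(y)
  cc <- stats::complete.cases(y)
  # start from complete-case closed form when enough complete rows exist,
  # otherwise from available-case (pairwise) moments
  if (sum(cc) > length(spec$observed) + 1) {
    xbar <- colMeans(y[cc, , drop = FALSE])
    S <- stats::cov(y[cc, , drop = FALSE])
  } else {
    xbar <- colMeans(y, na.rm = TRUE)
    S <- stats::cov(y, use = "pairwise.complete.obs")
    S[!is.finite(S)] <- 0
    diag(S)[diag(S) <= 0] <- 1
  }
  start <- lcs_closed_form(spec, xbar, S)
  kinds <- spec$kinds
  negll <- fiml_negloglik_factory(spec, patterns)
  n_tot <- nrow(y)
  # optimize the per-row negative log-likelihood so the relative-change
  # stopping rule is sample-size invariant
  objective <- penalized_objective(function(tpar)
    negll(free_to_theta(kinds, tpar)) / n_tot)
  t0 <- theta_to_free(kinds, start[spec$labels])
  opt <- stats::optim(t0, objective, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  if (objective(t0) < opt$value) {
    opt$par <- t0; opt$value <- objective(t0); opt$convergence <- 0L
  }
  est <- free_to_theta(kinds, opt$par)
  names(est) <- spec$labels
  gn <- sqrt(sum(num_grad(objective, opt$par)^2))
  fit <- make_fit_result(
    spec, est, se = setNames(rep(NA_real_, length(est)), names(est)),
    loglik = -negll(est), chi2 = NA_real_,
    df = n_sample_moments(spec) - n_free_params(spec),
    n = nrow(y), converged = opt$convergence == 0L,
    missing_method = "fiml", negloglik_fn = negll, grad_norm = gn)
  if (se) fit <- standard_errors(fit)
  fit
}

#' Fit a multigroup latent change score model
#'
#' The joint objective is the group-size-weighted sum of per-group
#' discrepancies, `sum_g (n_g - 1) F_g`.  By default every parameter is
#' free per group (labels are suffixed `"|<group>"`); labels listed in
#' `equal` are constrained equal across groups.
#'
#' @inheritParams fit_ml
#' @param group_column name of the grouping column in `data`
#' @param equal character vector of parameter labels constrained equal
#'   across groups (default none)
#' @return an `lcs_fit` object whose `per_group` element holds per-group
#'   estimate/SE blocks under the original labels
#' @export
fit_multigroup <- function(spec, data, group_column, equal = character(),
                           se = TRUE, max_iter = 500L) {
  g <- data[[group_column]]
  if (is.null(g)) stop("group column '", group_column, "' not found")
  g <- factor(g)
  groups <- levels(g)
  if (length(groups) < 2) stop("need at least two groups")
  bad <- setdiff(equal, spec$labels)
  if (length(bad)) stop("unknown labels in equality constraints: ",
                        paste(bad, collapse = ", "))
  sms <- lapply(groups, function(gr) {
    d <- data[g == gr, , drop = FALSE]
    if (!nrow(d)) stop("empty group: ", gr)
    sm <- sample_moments(d, spec$observed)
    if (sm$n < length(spec$observed) + 1)
      stop("group ", gr, " has too few complete cases (", sm$n, ")")
    sm
  })
  names(sms) <- groups
  maps <- lapply(groups, function(gr) {
    lab <- spec$labels
    ifelse(lab %in% equal, lab, paste0(lab, "|", gr))
  })
  names(maps) <- groups
  glabels <- unique(unlist(maps))
  gkinds <- setNames(rep(NA_character_, length(glabels)), glabels)
  for (gr in groups) gkinds[maps[[gr]]] <- spec$kinds
  # start: per-group closed form; shared labels get the n-weighted mean
  num <- setNames(numeric(length(glabels)), glabels)
  den <- setNames(numeric(length(glabels)), glabels)
  for (gr in groups) {
    st <- lcs_closed_form(spec, sms[[gr]]$mean, sms[[gr]]$cov)
    num[maps[[gr]]] <- num[maps[[gr]]] + st * sms[[gr]]$n
    den[maps[[gr]]] <- den[maps[[gr]]] + sms[[gr]]$n
  }
  start <- num / den
  joint_disc <- function(gtheta) {
    names(gtheta) <- glabels
    total <- 0
    for (gr in groups) {
      th <- gtheta[maps[[gr]]]
      names(th) <- spec$labels
      total <- total +
        (sms[[gr]]$n - 1) *
        ml_discrepancy(spec, th, sms[[gr]]$mean, sms[[gr]]$cov, sms[[gr]]$n)
    }
    total
  }
  objective <- penalized_objective(function(tpar)
    joint_disc(free_to_theta(gkinds, tpar)))
  t0 <- theta_to_free(gkinds, start)
  opt <- stats::optim(t0, objective, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  if (objective(t0) < opt$value) {
    opt$par <- t0; opt$value <- objective(t0); opt$convergence <- 0L
  }
  est <- free_to_theta(gkinds, opt$par)
  names(est) <- glabels
  gn <- sqrt(sum(num_grad(objective, opt$par)^2))
  n_tot <- sum(vapply(sms, `[[`, 0, "n"))
  negll <- function(gtheta) {
    names(gtheta) <- glabels
    total <- 0
    for (gr in groups) {
      th <- gtheta[maps[[gr]]]
      names(th) <- spec$labels
      imp <- implied_moments(spec, th)
      total <- total - gauss_loglik_moments(imp$mean, imp$cov,
                                            sms[[gr]]$mean, sms[[gr]]$cov,
                                            sms[[gr]]$n)
    }
    total
  }
  df <- length(groups) * n_sample_moments(spec) - length(glabels)
  fit <- make_fit_result(
    spec, est, se = setNames(rep(NA_real_, length(est)), names(est)),
    loglik = -negll(est), chi2 = max(0, opt$value), df = df, n = n_tot,
    converged = opt$convergence == 0L,
    missing_method = "complete", negloglik_fn = negll, grad_norm = gn)
  if (se) fit <- standard_errors(fit)
  # per-group blocks under original labels
  fit$per_group <- lapply(groups, function(gr) {
    idx <- maps[[gr]]
    list(group = gr,
         estimates = setNames(fit$estimates[idx], spec$labels),
         ses = setNames(fit$ses[idx], spec$labels),
         n = sms[[gr]]$n)
  })
  names(fit$per_group) <- groups
  fit
}

#' Observed-information standard errors for a fitted model
#'
#' Inverts the numerically differentiated Hessian of the negative
#' log-likelihood at the estimates.  A singular information matrix leaves
#' the standard errors flagged as `NA` while the fit is retained.
#'
#' @param fit an `lcs_fit` object
#' @param method currently `"observed_information"` only
#' @return the fit with its `ses` field populated
#' @export
standard_errors <- function(fit, method = "observed_information") {
  method <- match.arg(method)
  est <- fit$estimates
  H <- tryCatch(
    stats::optimHess(est, function(th) fit$negloglik_fn(th)),
    error = function(e) NULL)
  ses <- setNames(rep(NA_real_, length(est)), names(est))
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      ok <- is.finite(dv) & dv >= 0
      ses[ok] <- sqrt(dv[ok])
      fit$vcov <- V
    }
  }
  fit$ses <- ses
  fit
}

#' Tidy parameter table from a fitted model
#'
#' @param fit an `lcs_fit` object
#' @return data frame with columns label, estimate, se, z, p (two-sided
#'   Wald), and group where applicable
#' @export
tidy_lcs_fit <- function(fit) {
  if (!is.null(fit$per_group)) {
    out <- do.call(rbind, lapply(fit$per_group, function(b) {
      z <- b$estimates / b$ses
      data.frame(label = names(b$estimates), estimate = unname(b$estimates),
                 se = unname(b$ses), z = unname(z),
                 p = unname(2 * stats::pnorm(-abs(z))),
                 group = b$group, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  z <- fit$estimates / fit$ses
  data.frame(label = names(fit$estimates), estimate = unname(fit$estimates),
             se = unname(fit$ses), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             group = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.lcs_fit <- function(x, ...) {
  cat("LCS model fit (", x$missing_method, " likelihood)\n", sep = "")
  cat("  n =", x$n_used, " loglik =", format(x$loglik),
      " chi-square =", format(x$chi_square), " df =", x$df, "\n")
  cat("  converged:", x$converged,
      " |grad| =", format(x$grad_norm, digits = 3), "\n")
  tab <- tidy_lcs_fit(x)
  print(tab, digits = 4, row.names = FALSE)
  invisible(x)
}
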