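# Cognitive composite: column standardization, the closed-form
# one-factor (Spearman) solution for three indicators, and
# regression-method (Thomson) factor scores with an orientation flip so
# that higher scores mean better performance.

#' Standardize numeric columns to mean 0, SD 1
#'
#' @param table a data frame
#' @param columns columns to standardize (SD denominator n-1)
#' @return the table with the named columns standardized
#' @export
standardize <- function(table, columns) {
  missing_c <- setdiff(columns, names(table))
  if (length(missing_c))
    stop("unknown column(s): ", paste(missing_c, collapse = ", "))
  for (cl in columns) {
    x <- table[[cl]]
    if (!is.numeric(x)) stop("column '", cl, "' is not numeric")
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s <= 0)
      stop("column '", cl, "' has zero variance")
    table[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' One-factor exploratory factor analysis of three indicators
#'
#' With exactly three indicators the single-factor model is
#' just-identified and has the Spearman closed form
#' `lambda_1 = sqrt(r12 r13 / r23)` (cyclically), with signs assigned
#' relative to the anchor indicator.  The solution is flipped so the
#' anchor's loading is positive (higher anchor score = higher factor),
#' mirroring the convention of orienting a cognitive composite so larger
#' values mean better performance.
#'
#' @param corr3 3x3 correlation matrix of the standardized indicators
#' @param anchor index (or name) of the indicator given a positive
#'   loading; default the first (e.g. a correct-matches count)
#' @return object of class `factor_solution` with `loadings`,
#'   `uniquenesses`, `variance_explained`, `orientation` and the input
#'   correlation matrix
#' @export
efa_one_factor <- function(corr3, anchor = 1L) {
  corr3 <- as.matrix(corr3)
  stopifnot(nrow(corr3) == 3, ncol(corr3) == 3)
  if (!isSymmetric(unname(corr3), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(corr3) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal")
  r12 <- corr3[1, 2]; r13 <- corr3[1, 3]; r23 <- corr3[2, 3]
  rad <- c(r12 * r13 / r23, r12 * r23 / r13, r13 * r23 / r12)
  if (any(!is.finite(rad)) || any(rad < 0))
    stop("inadmissible triad structure: a loading radicand is negative ",
         "or undefined (", paste(format(rad, digits = 3), collapse = ", "),
         ")")
  lam <- sqrt(pmin(rad, 1 + 1e-8))
  # signs relative to indicator 1, then orient to the anchor
  lam <- lam * c(1, sign(r12), sign(r13))
  if (is.character(anchor)) anchor <- match(anchor, colnames(corr3))
  orientation <- if (lam[anchor] < 0) -1 else 1
  lam <- orientation * lam
  nm <- colnames(corr3) %||% paste0("indicator", 1:3)
  loadings <- setNames(lam, nm)
  out <- list(loadings = loadings,
              uniquenesses = setNames(1 - lam^2, nm),
              variance_explained = mean(lam^2),
              orientation = orientation,
              corr = corr3)
  class(out) <- "factor_solution"
  out
}

#' Regression-method factor scores
#'
#' Thomson scores `f = z' R^-1 lambda` computed from standardized
#' indicators, oriented so higher scores mean better performance (per the
#' solution's orientation).  Rows with a missing indicator get a missing
#' score.
#'
#' @param table data frame containing the indicator columns
#' @param solution a `factor_solution` from [efa_one_factor()]
#' @param columns indicator columns, in the order of the solution's
#'   loadings; default the loading names
#' @param standardized set FALSE to standardize the columns first
#' @return numeric vector of per-row scores
#' @export
composite_scores <- function(table, solution, columns = NULL,
                             standardized = TRUE) {
  stopifnot(inherits(solution, "factor_solution"))
  columns <- columns %||% names(solution$loadings)
  missing_c <- setdiff(columns, names(table))
  if (length(missing_c))
    stop("missing indicator column(s): ", paste(missing_c, collapse = ", "))
  if (!standardized) table <- standardize(table, columns)
  z <- as.matrix(table[, columns, drop = FALSE])
  w <- solve(solution$corr, solution$loadings)
  drop(z %*% w)
}

#' Build the cognitive composite from raw indicator columns
#'
#' Standardizes the indicators, fits the closed-form one-factor solution
#' to their correlation matrix, and appends regression-method factor
#' scores as `cog_composite_efa` (oriented so higher = better via the
#' anchor indicator).
#'
#' @param table a data frame
#' @param columns three indicator columns (anchor first)
#' @param anchor indicator oriented positive (default the first)
#' @return list with `table` (scores appended) and `solution`
#' @export
build_composite <- function(table, columns, anchor = 1L) {
  zt <- standardize(table, columns)
  R <- stats::cor(as.matrix(zt[, columns]), use = "complete.obs")
  sol <- efa_one_factor(R, anchor = anchor)
  zt2 <- table
  zt2$cog_composite_efa <- composite_scores(zt, sol, columns)
  list(table = zt2, solution = sol)
}

#' Serialize a factor solution to JSON
#' @param solution a `factor_solution`
#' @param path optional output file
#' @return JSON string (invisibly when `path` given)
#' @export
factor_solution_to_json <- function(solution, path = NULL) {
  js <- jsonlite::toJSON(list(
    loadings = as.list(solution$loadings),
    uniquenesses = as.list(solution$uniquenesses),
    variance_explained = solution$variance_explained,
    orientation = solution$orientation), digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("One-factor solution (closed form, 3 indicators)\n")
  print(round(rbind(loading = x$loadings, uniqueness = x$uniquenesses), 4))
  cat("variance explained:", round(x$variance_explained, 4),
      " orientation:", x$orientation, "\n")
  invisible(x)
}
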