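# Bland-Altman agreement between paired volume estimates from two
# measurement pipelines.

#' Bland-Altman agreement summary
#'
#' Differences are `b - a` (second pipeline minus first) plotted against
#' pairwise means; limits of agreement are `bias +/- 1.96 SD` of the
#' differences.  When all differences are identical the limits collapse
#' onto the bias and the within-LOA fraction is 1 by convention.
#'
#' @param values_a,values_b equal-length paired measurements (first and
#'   second pipeline)
#' @param loa_sd LOA half-width in SD units (default 1.96, the 95% LOA)
#' @return object of class `agreement_summary` with `bias`, `sd_diff`,
#'   `loa` (lower, upper), `fraction_within`, `n` and plot-ready `data`
#'   (mean, difference)
#' @export
bland_altman <- function(values_a, values_b, loa_sd = 1.96) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length (", length(values_a),
         " vs ", length(values_b), ")")
  ok <- is.finite(values_a) & is.finite(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  d <- b - a
  m <- (a + b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- c(lower = bias - loa_sd * s, upper = bias + loa_sd * s)
  frac <- if (s == 0) 1 else mean(d >= loa[1] & d <= loa[2])
  out <- list(bias = bias, sd_diff = s, loa = loa,
              fraction_within = frac, n = n,
              data = data.frame(mean = m, difference = d))
  class(out) <- "agreement_summary"
  out
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: n = %d, bias = %.4f, SD = %.4f, LOA [%.4f, %.4f], %.1f%% within\n",
    x$n, x$bias, x$sd_diff, x$loa[1], x$loa[2], 100 * x$fraction_within))
  invisible(x)
}

#' Draw a Bland-Altman plot
#'
#' @param x an `agreement_summary`
#' @param ... passed to [plot()]
#' @export
plot.agreement_summary <- function(x, ...) {
  plot(x$data$mean, x$data$difference,
       xlab = "Mean of pipelines (mL)",
       ylab = "Difference (pipeline 2 - pipeline 1, mL)", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Export agreement results (plot data CSV + summary JSON)
#'
#' @param summary an `agreement_summary`
#' @param csv_path,json_path output paths (either may be NULL)
#' @return the summary, invisibly
#' @export
export_agreement <- function(summary, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(summary$data, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(list(
      bias = summary$bias, sd_diff = summary$sd_diff,
      loa_lower = unname(summary$loa[1]), loa_upper = unname(summary$loa[2]),
      fraction_within = summary$fraction_within, n = summary$n),
      digits = NA, auto_unbox = TRUE), json_path)
  invisible(summary)
}
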