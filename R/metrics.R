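#' Percentage of estimates within a fraction of the reference
#'
#' The field's standard accuracy summary: P30 is `p_within(est, ref, 0.30)`,
#' the percentage of estimates within ±30% of the measured reference GFR.
#' The boundary counts as within (|est − ref| ≤ fraction × ref); published
#' values are sensitive to this convention, so it is fixed and documented.
#'
#' @param estimates Numeric vector of estimated GFR (mL/min/1.73 m²).
#' @param reference Numeric vector of reference (measured) GFR, same length,
#'   all > 0.
#' @param fraction Dimensionless tolerance fraction (0.30 for P30).
#' @return Percentage in \[0, 100\].
#' @examples
#' p_within(c(100, 131, 70, 129), rep(100, 4), 0.30)  # 75
#' @export
p_within <- function(estimates, reference, fraction = 0.30) {
  check_metric_args(estimates, reference)
  if (!is_scalar_number(fraction) || fraction < 0)
    err_domain("fraction must be a non-negative number")
  100 * mean(abs(estimates - reference) <= fraction * reference)
}

#' Accuracy report for a set of GFR estimates
#'
#' Aggregates the standard validation summaries: P30, P10, median bias
#' (estimate − reference, mL/min/1.73 m²) and median absolute relative error.
#'
#' @inheritParams p_within
#' @return An object of class `accuracy_report`: list with `n`, `p30`, `p10`,
#'   `median_bias`, `median_absolute_relative_error`.
#' @export
accuracy_report <- function(estimates, reference) {
  check_metric_args(estimates, reference)
  structure(
    list(
      n = length(estimates),
      p30 = p_within(estimates, reference, 0.30),
      p10 = p_within(estimates, reference, 0.10),
      median_bias = stats::median(estimates - reference),
      median_absolute_relative_error =
        stats::median(abs(estimates - reference) / reference)
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> n =", x$n, "\n")
  cat(sprintf("  P30 %.1f%% | P10 %.1f%% | median bias %+.2f mL/min/1.73m2 | median |rel err| %.3f\n",
              x$p30, x$p10, x$median_bias, x$median_absolute_relative_error))
  invisible(x)
}

check_metric_args <- function(estimates, reference) {
  if (length(estimates) == 0L)
    err_domain("empty input: at least one estimate/reference pair is required")
  if (length(estimates) != length(reference))
    err_domain("estimates and reference must have equal length")
  if (any(!is.finite(estimates)) || any(!is.finite(reference)))
    err_domain("estimates and reference must be finite")
  if (any(reference <= 0))
    err_domain("reference GFR values must be positive")
  invisible(TRUE)
}
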