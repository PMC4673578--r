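#' Body surface area
#'
#' Computes body surface area from height and weight with a pluggable
#' formula. The default is DuBois–DuBois,
#' BSA = 0.007184 × height^0.725 × weight^0.425 (height in cm, weight in kg);
#' Mosteller (sqrt(height × weight / 3600)) is also built in, and further
#' formulas can be supplied as a function of `(height, weight)`.
#'
#' @param height Height in cm, > 0. Vectorised.
#' @param weight Weight in kg, > 0. Vectorised.
#' @param formula `"dubois"` (default), `"mosteller"`, or a function
#'   `function(height, weight)` returning m².
#' @return BSA in m² with attribute `formula_id`.
#' @examples
#' bsa(180, 75)  # about 1.94 m2
#' @export
bsa <- function(height, weight, formula = "dubois") {
  if (any(!is.finite(height)) || any(height <= 0) ||
      any(!is.finite(weight)) || any(weight <= 0))
    err_domain("height and weight must be positive")
  if (is.function(formula)) {
    value <- formula(height, weight)
    id <- "custom"
  } else {
    id <- match.arg(formula, c("dubois", "mosteller"))
    value <- switch(id,
      dubois = 0.007184 * height^0.725 * weight^0.425,
      mosteller = sqrt(height * weight / 3600)
    )
  }
  if (any(!is.finite(value)) || any(value <= 0))
    err_domain("BSA formula produced a non-positive or non-finite value")
  structure(value, formula_id = id)
}

#' Convert between relative and absolute GFR
#'
#' Relative GFR is normalised to a body surface area of 1.73 m². Absolute
#' GFR (mL/min), needed e.g. for dosing of drugs cleared by the kidneys, is
#' `gfr_rel × bsa / 1.73`; the two functions are exact inverses.
#'
#' @param gfr_rel Relative GFR in mL/min/1.73 m² (≥ 0). Vectorised.
#' @param gfr_abs Absolute GFR in mL/min (≥ 0). Vectorised.
#' @param bsa Body surface area in m², > 0 (see [bsa()]).
#' @return Absolute GFR in mL/min (`relative_to_absolute`) or relative GFR in
#'   mL/min/1.73 m² (`absolute_to_relative`).
#' @examples
#' relative_to_absolute(60, bsa(180, 75))
#' @export
relative_to_absolute <- function(gfr_rel, bsa) {
  check_conversion_args(gfr_rel, bsa)
  as.numeric(gfr_rel) * as.numeric(bsa) / 1.73
}

#' @rdname relative_to_absolute
#' @export
absolute_to_relative <- function(gfr_abs, bsa) {
  check_conversion_args(gfr_abs, bsa)
  as.numeric(gfr_abs) * 1.73 / as.numeric(bsa)
}

check_conversion_args <- function(gfr, bsa) {
  if (any(!is.finite(gfr)) || any(gfr < 0))
    err_domain("GFR must be finite and >= 0")
  if (any(!is.finite(bsa)) || any(bsa <= 0))
    err_domain("BSA must be positive")
  invisible(TRUE)
}
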