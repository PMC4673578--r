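#' Concordance policy for the dual-marker quality check
#'
#' The internal quality check compares the cystatin C- and creatinine-based
#' estimates and accepts their arithmetic mean only when they agree within a
#' specified limit. Agreement is measured as the symmetric relative
#' difference |a − b| / mean(a, b). A tighter limit applies in the dosing
#' context, where a higher degree of agreement (and thus accuracy) is
#' required than for evaluating the level of GFR.
#'
#' @param context `"general"` (default) or `"dosing"`; selects which limit is
#'   active.
#' @param relative_limit_general Agreement limit for general evaluation
#'   (default 0.30).
#' @param relative_limit_dosing Agreement limit for medication dosing
#'   (default 0.10); must not exceed the general limit.
#' @param strict_flags If `TRUE`, clinical flags veto the mean even when the
#'   two estimates are concordant (default `FALSE`: concordance is treated as
#'   self-validating and flags are consulted only on discordance).
#' @return An object of class `concordance_policy`.
#' @export
concordance_policy <- function(context = c("general", "dosing"),
                               relative_limit_general = 0.30,
                               relative_limit_dosing = 0.10,
                               strict_flags = FALSE) {
  context <- match.arg(context)
  if (!is_scalar_number(relative_limit_general) ||
      relative_limit_general <= 0 || relative_limit_general >= 1 ||
      !is_scalar_number(relative_limit_dosing) ||
      relative_limit_dosing <= 0 || relative_limit_dosing >= 1)
    err_domain("concordance limits must lie strictly between 0 and 1")
  if (relative_limit_dosing > relative_limit_general)
    err_domain("the dosing limit must not exceed the general limit")
  structure(
    list(context = context,
         relative_limit_general = relative_limit_general,
         relative_limit_dosing = relative_limit_dosing,
         strict_flags = isTRUE(strict_flags)),
    class = "concordance_policy"
  )
}

active_limit <- function(policy) {
  if (policy$context == "dosing") policy$relative_limit_dosing
  else policy$relative_limit_general
}

est_value <- function(x) if (inherits(x, "gfr_estimate")) x$value else as.numeric(x)

#' Check agreement between two GFR estimates
#'
#' @param e_cys,e_crea The two estimates (`gfr_estimate` objects or bare
#'   positive numbers, mL/min/1.73 m²).
#' @param policy A [concordance_policy()].
#' @return A list with `concordant` (logical) and `relative_difference`
#'   (|a − b| / mean(a, b)); concordant iff the relative difference is at
#'   most the active limit (boundary counts as concordant).
#' @examples
#' check_concordance(80, 60, concordance_policy())          # concordant
#' check_concordance(80, 60, concordance_policy("dosing"))  # not
#' @export
check_concordance <- function(e_cys, e_crea, policy = concordance_policy()) {
  a <- est_value(e_cys); b <- est_value(e_crea)
  if (!is_scalar_number(a) || !is_scalar_number(b) || a <= 0 || b <= 0)
    err_domain("both estimates must be positive to check concordance")
  rd <- abs(a - b) / ((a + b) / 2)
  list(concordant = rd <= active_limit(policy), relative_difference = rd)
}

#' Arithmetic-mean combination of the two estimates
#'
#' When the two single-marker estimates agree, their arithmetic mean is used
#' as the final estimate; it has been found to perform at least as well as
#' more complex combinations.
#'
#' @inheritParams check_concordance
#' @return A `gfr_estimate` with `marker_basis = "combined"` and
#'   `equation_id = "mean"`.
#' @export
combine_mean <- function(e_cys, e_crea) {
  a <- est_value(e_cys); b <- est_value(e_crea)
  if (a < 0 || b < 0) err_domain("estimates must be non-negative")
  gfr_estimate((a + b) / 2, "combined", "mean")
}

CREA_INVALIDATING <- c("MUSCLE_MASS_LOW", "MUSCLE_MASS_HIGH")
CYS_INVALIDATING <- "GLUCOCORTICOID_MODERATE_HIGH_DOSE"

#' Arbitrate a discordant pair of estimates from clinical flags
#'
#' When the two estimates disagree, the clinical context is consulted for
#' obvious reasons not to trust one of them. Abnormal muscle mass
#' (`MUSCLE_MASS_LOW`/`MUSCLE_MASS_HIGH`) invalidates the creatinine-based
#' estimate; moderate-to-high-dose glucocorticoid therapy invalidates the
#' cystatin-based estimate. Exactly one class present routes to the other
#' marker; both classes present, or no explanatory flag at all, routes to an
#' invasive gold-standard measurement (fail-safe).
#'
#' @param flags Character vector of clinical flags ([CLINICAL_FLAGS]).
#' @return One of `"USE_CYSTATIN"`, `"USE_CREATININE"`,
#'   `"GOLD_STANDARD_REQUIRED"`.
#' @export
resolve_discordance <- function(flags) {
  flags <- validate_flags(flags)
  crea_bad <- any(flags %in% CREA_INVALIDATING)
  cys_bad <- any(flags %in% CYS_INVALIDATING)
  if (crea_bad && !cys_bad) "USE_CYSTATIN"
  else if (cys_bad && !crea_bad) "USE_CREATININE"
  else "GOLD_STANDARD_REQUIRED"
}

#' Run the dual-marker decision strategy for one patient
#'
#' Computes the cystatin C-based and creatinine-based relative GFR estimates,
#' checks their concordance under `policy`, and routes:
#'
#' * concordant → `USE_MEAN`, final estimate = arithmetic mean;
#' * discordant → [resolve_discordance()] on the patient's flags, with the
#'   surviving single-marker estimate as final (or no final estimate when a
#'   gold-standard measurement is required).
#'
#' Flags are consulted only when the estimates are discordant, unless the
#' policy sets `strict_flags = TRUE`, in which case an invalidating flag
#' overrides even a concordant mean.
#'
#' @param patient A [patient_record()].
#' @param registry An [equation_registry()] resolving both equation ids.
#' @param cys_id Id of the cystatin C-based equation.
#' @param crea_id Id of the creatinine-based equation.
#' @param policy A [concordance_policy()].
#' @return An object of class `lund_decision` with fields `route`,
#'   `final_estimate` (`NULL` iff route is `GOLD_STANDARD_REQUIRED`),
#'   `e_cystatin`, `e_creatinine`, `relative_difference`, `limit`,
#'   `flags_consulted`, `rationale`.
#' @examples
#' reg <- default_registry()
#' p <- patient_record("p1", age = 50, sex = "male",
#'                     creatinine = 90, cystatin_c = 1.2)
#' lund_decide(p, reg)
#' @export
lund_decide <- function(patient, registry,
                        cys_id = "grubb_cystatin", crea_id = "mdrd_idms",
                        policy = concordance_policy()) {
  e_cys <- egfr_cystatin(patient, get_equation(registry, cys_id))
  e_crea <- egfr_creatinine(patient, get_equation(registry, crea_id))
  cc <- check_concordance(e_cys, e_crea, policy)
  limit <- active_limit(policy)
  rationale <- c(
    sprintf("relative difference %.4f vs %s limit %.2f (%s)",
            cc$relative_difference, policy$context, limit,
            if (cc$concordant) "concordant" else "discordant")
  )

  flags_consulted <- FALSE
  if (cc$concordant && !(policy$strict_flags && length(patient$flags) > 0L &&
                         any(patient$flags %in% c(CREA_INVALIDATING, CYS_INVALIDATING)))) {
    route <- "USE_MEAN"
    final <- combine_mean(e_cys, e_crea)
    rationale <- c(rationale, "estimates agree: arithmetic mean accepted")
  } else {
    flags_consulted <- TRUE
    route <- resolve_discordance(patient$flags)
    rationale <- c(rationale,
      if (cc$concordant) "strict flag policy: flags override concordant mean",
      sprintf("flags consulted: {%s} -> %s",
              paste(patient$flags, collapse = ";"), route))
    final <- switch(route,
      USE_CYSTATIN = {
        rationale <- c(rationale,
          "creatinine estimate invalidated by abnormal muscle mass")
        e_cys
      },
      USE_CREATININE = {
        rationale <- c(rationale,
          "cystatin estimate invalidated by glucocorticoid therapy")
        e_crea
      },
      GOLD_STANDARD_REQUIRED = {
        rationale <- c(rationale,
          "no acceptable non-invasive estimate: gold-standard measurement required")
        NULL
      })
  }

  structure(
    list(patient_id = patient$patient_id,
         route = route,
         final_estimate = final,
         e_cystatin = e_cys,
         e_creatinine = e_crea,
         relative_difference = cc$relative_difference,
         limit = limit,
         context = policy$context,
         flags_consulted = flags_consulted,
         flags = patient$flags,
         rationale = rationale),
    class = "lund_decision"
  )
}

#' @export
print.lund_decision <- function(x, ...) {
  cat("<lund_decision> patient ", x$patient_id, ": ", x$route, "\n", sep = "")
  cat(sprintf("  cystatin %.1f | creatinine %.1f | rel.diff %.3f (limit %.2f, %s)\n",
              x$e_cystatin$value, x$e_creatinine$value,
              x$relative_difference, x$limit, x$context))
  if (!is.null(x$final_estimate))
    cat(sprintf("  final estimate: %.1f mL/min/1.73m2 (%s)\n",
                x$final_estimate$value, x$final_estimate$marker_basis))
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Anchor a reliable GFR value to a patient's creatinine level
#'
#' After a concordant (`USE_MEAN`) decision, the accepted GFR is tied to the
#' patient's creatinine level so that follow-up monitoring can proceed from
#' creatinine alone. Anchoring after any other route is refused: only the
#' concordant case validates the creatinine–GFR link.
#'
#' @param decision A [lund_decide()] result with route `USE_MEAN`.
#' @param patient The [patient_record()] the decision was made for.
#' @param crea_id Id of the creatinine equation to use for follow-up scaling.
#' @return An object of class `gfr_anchor` holding the reference creatinine,
#'   reference GFR, equation id, reference age and the demographic fields the
#'   equation needs.
#' @seealso [monitor_gfr()]
#' @export
make_anchor <- function(decision, patient, crea_id = "mdrd_idms") {
  stopifnot(inherits(decision, "lund_decision"))
  if (decision$route != "USE_MEAN")
    err_anchor_refused(paste0(
      "monitoring anchor requires a concordant USE_MEAN decision; route was ",
      decision$route))
  if (!has_field(patient, "creatinine"))
    err_missing_marker("patient has no creatinine value to anchor")
  structure(
    list(creatinine_ref = patient$creatinine,
         gfr_ref = decision$final_estimate$value,
         equation_id = crea_id,
         age_ref = patient$age,
         sex = patient$sex,
         population = patient$population,
         height = patient$height,
         patient_id = patient$patient_id,
         valid = TRUE),
    class = "gfr_anchor"
  )
}

#' @export
print.gfr_anchor <- function(x, ...) {
  cat(sprintf(
    "<gfr_anchor> patient %s: GFR %.1f mL/min/1.73m2 at creatinine %.1f umol/L (age %.1f, %s)\n",
    x$patient_id, x$gfr_ref, x$creatinine_ref, x$age_ref, x$equation_id))
  invisible(x)
}

#' Follow-up GFR monitoring from creatinine alone
#'
#' Scales the anchored GFR by the anchored creatinine equation's own
#' dependence on creatinine and age:
#' `gfr_ref × f(new_creatinine, new_age) / f(creatinine_ref, age_ref)`,
#' where `f` is the anchored equation evaluated with the patient's sex and
#' population. For MDRD-like forms this reduces to a pure power law in
#' creatinine. If the patient's muscle mass has changed
#' (`MUSCLE_MASS_CHANGED` flag), the anchor is no longer trustworthy and a
#' re-evaluation-required error is signalled: the full dual-marker strategy
#' must be repeated.
#'
#' @param anchor A [make_anchor()] result.
#' @param new_creatinine Follow-up plasma creatinine in μmol/L.
#' @param new_age Patient age at follow-up, years (defaults to the anchor
#'   age).
#' @param flags Clinical flags at follow-up.
#' @param registry An [equation_registry()] resolving the anchored equation.
#' @return A `gfr_estimate` (marker basis `"creatinine"`) with a note
#'   recording the anchor provenance.
#' @export
monitor_gfr <- function(anchor, new_creatinine, new_age = anchor$age_ref,
                        flags = character(), registry = default_registry()) {
  stopifnot(inherits(anchor, "gfr_anchor"))
  if (!isTRUE(anchor$valid))
    err_reeval_required("anchor is invalid: repeat the dual-marker strategy")
  if ("MUSCLE_MASS_CHANGED" %in% validate_flags(flags))
    err_reeval_required(paste0(
      "muscle mass changed for patient ", anchor$patient_id,
      ": anchor invalidated, repeat the dual-marker strategy"))
  if (!is_scalar_number(new_creatinine) || new_creatinine <= 0)
    err_domain("new_creatinine must be positive")
  spec <- get_equation(registry, anchor$equation_id)
  proxy <- function(age) {
    structure(
      list(patient_id = anchor$patient_id, age = age, sex = anchor$sex,
           height = anchor$height, weight = NA_real_,
           population = anchor$population,
           creatinine = NA_real_, cystatin_c = NA_real_,
           flags = character(), measured_gfr = NA_real_),
      class = "patient_record")
  }
  f_new <- eval_equation(spec, proxy(new_age), new_creatinine)
  f_ref <- eval_equation(spec, proxy(anchor$age_ref), anchor$creatinine_ref)
  gfr_estimate(anchor$gfr_ref * f_new / f_ref, "creatinine", anchor$equation_id,
               notes = sprintf(
                 "anchored follow-up: ref GFR %.2f at creatinine %.1f umol/L, age %.1f",
                 anchor$gfr_ref, anchor$creatinine_ref, anchor$age_ref))
}
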