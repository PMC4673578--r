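#' Clinical flags understood by the decision engine
#'
#' Flags carry the "knowledge of the clinical context" the decision engine
#' consults when the cystatin C- and creatinine-based estimates disagree:
#'
#' * `MUSCLE_MASS_LOW`, `MUSCLE_MASS_HIGH` — the patient's muscle mass deviates
#'   from the population mean implicit in creatinine-based equations
#'   (paralysis, malnutrition, body-building ...); they invalidate the
#'   creatinine-based estimate.
#' * `GLUCOCORTICOID_MODERATE_HIGH_DOSE` — moderate-to-high-dose glucocorticoid
#'   therapy increases cystatin C synthesis and invalidates the cystatin-based
#'   estimate.
#' * `MUSCLE_MASS_CHANGED` — the patient's muscle mass has changed since a
#'   monitoring anchor was set; it does not affect routing but forces
#'   re-evaluation during follow-up monitoring (see [monitor_gfr()]).
#'
#' @format Character vector of the four recognised flag names.
#' @seealso [resolve_discordance()], [lund_decide()], [monitor_gfr()]
#' @export
CLINICAL_FLAGS <- c(
  "MUSCLE_MASS_LOW",
  "MUSCLE_MASS_HIGH",
  "GLUCOCORTICOID_MODERATE_HIGH_DOSE",
  "MUSCLE_MASS_CHANGED"
)

validate_flags <- function(flags) {
  if (is.null(flags)) return(character())
  flags <- as.character(flags)
  unknown <- setdiff(flags, CLINICAL_FLAGS)
  if (length(unknown) > 0L)
    err_domain(paste0("unknown clinical flag(s): ", paste(unknown, collapse = ", ")))
  flags <- unique(flags)
  if (all(c("MUSCLE_MASS_LOW", "MUSCLE_MASS_HIGH") %in% flags))
    err_domain("MUSCLE_MASS_LOW and MUSCLE_MASS_HIGH are mutually exclusive")
  flags
}

#' Construct a patient record
#'
#' A `patient_record` holds one patient's demographics, plasma marker levels
#' and clinical flags. Marker units are fixed at the interface: plasma
#' creatinine in μmol/L, plasma cystatin C in mg/L; `measured_gfr` (a
#' gold-standard result, when available) and all estimates are relative GFR in
#' mL/min/1.73 m². Optional fields left `NA` never default silently — an
#' equation that needs them is simply not applicable (see [applicable()]).
#'
#' @param patient_id Opaque identifier string.
#' @param age Age in years, > 0.
#' @param sex `"female"` or `"male"`.
#' @param height Height in cm (optional).
#' @param weight Weight in kg (optional).
#' @param population Optional population tag (e.g. `"japanese"`, `"black"`)
#'   matched against equation population coefficients.
#' @param creatinine Plasma creatinine in μmol/L (optional).
#' @param cystatin_c Plasma cystatin C in mg/L (optional).
#' @param flags Character vector of clinical flags; see [CLINICAL_FLAGS].
#' @param measured_gfr Gold-standard GFR in mL/min/1.73 m² (optional).
#' @return An object of class `patient_record`.
#' @examples
#' patient_record("p1", age = 40, sex = "female", creatinine = 80,
#'                cystatin_c = 1.1)
#' @export
patient_record <- function(patient_id, age, sex,
                           height = NA_real_, weight = NA_real_,
                           population = NA_character_,
                           creatinine = NA_real_, cystatin_c = NA_real_,
                           flags = character(),
                           measured_gfr = NA_real_) {
  if (!is_scalar_number(age) || age <= 0)
    err_domain("age must be a positive number (years)")
  sex <- match.arg(sex, c("female", "male"))
  for (nm in c("height", "weight", "creatinine", "cystatin_c", "measured_gfr")) {
    v <- get(nm)
    if (!is.na(v) && (!is_scalar_number(v) || v <= 0))
      err_domain(paste0(nm, " must be positive when supplied"))
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      age = as.numeric(age),
      sex = sex,
      height = as.numeric(height),
      weight = as.numeric(weight),
      population = if (is.na(population)) NA_character_ else as.character(population),
      creatinine = as.numeric(creatinine),
      cystatin_c = as.numeric(cystatin_c),
      flags = validate_flags(flags),
      measured_gfr = as.numeric(measured_gfr)
    ),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> ", x$patient_id, ": ", x$age, " y ", x$sex, sep = "")
  if (!is.na(x$creatinine)) cat(", crea ", x$creatinine, " umol/L", sep = "")
  if (!is.na(x$cystatin_c)) cat(", cysC ", x$cystatin_c, " mg/L", sep = "")
  if (length(x$flags)) cat(", flags: ", paste(x$flags, collapse = ";"), sep = "")
  cat("\n")
  invisible(x)
}

# field present = non-NA (markers/anthropometrics) or always-present core field
has_field <- function(patient, field) {
  v <- patient[[field]]
  if (is.null(v)) return(FALSE)
  if (field == "flags") return(TRUE)
  !is.na(v)
}
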