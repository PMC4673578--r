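# Shared fixtures: built in code, no binary files.

adult_f <- function(...) {
  patient_record("af", age = 40, sex = "female", creatinine = 80,
                 cystatin_c = 1.2, height = 165, weight = 68, ...)
}

adult_m <- function(...) {
  patient_record("am", age = 50, sex = "male", creatinine = 90,
                 cystatin_c = 1.1, height = 180, weight = 80, ...)
}

# Synthetic piecewise log-linear (Lund-Malmoe-style) creatinine equation.
# Coefficients are SYNTHETIC (chosen for the tests, not from any publication):
# two creatinine segments continuous at 150 umol/L, both decreasing, with a
# linear age term and an additive female term on the log scale.
pwll_synthetic <- function() {
  a1 <- 7.35
  gfr_equation(
    "pwll_synthetic", "creatinine", "piecewise_loglinear",
    params = c(break_1 = 150,
               seg1_intercept = a1, seg1_lncrea = -0.6,
               seg2_intercept = a1 + 0.6 * log(150), seg2_lncrea = -1.2,
               age_lin = -0.01, female_add = -0.124),
    age_range = c(1, 120))
}

test_registry <- function() {
  register_equation(default_registry(), pwll_synthetic())
}

# Patient whose two estimates sit at chosen GFR values, manufactured by
# inverting the two equations (decision-path control).
patient_at <- function(gfr_cys, gfr_crea, flags = character(),
                       registry = default_registry(),
                       cys_id = "grubb_cystatin", crea_id = "mdrd_idms") {
  base <- patient_record("px", age = 50, sex = "male", height = 178)
  cys <- invert_equation(gfr_cys, base, get_equation(registry, cys_id))
  crea <- invert_equation(gfr_crea, base, get_equation(registry, crea_id))
  patient_record("px", age = 50, sex = "male", height = 178,
                 creatinine = crea, cystatin_c = cys, flags = flags)
}

# Independent brute-force truth table for the routing logic (written against
# the strategy's textual description, not against the engine).
truth_table_route <- function(flags, concordant) {
  if (concordant) return("USE_MEAN")
  muscle <- any(c("MUSCLE_MASS_LOW", "MUSCLE_MASS_HIGH") %in% flags)
  steroid <- "GLUCOCORTICOID_MODERATE_HIGH_DOSE" %in% flags
  if (muscle && !steroid) "USE_CYSTATIN"
  else if (steroid && !muscle) "USE_CREATININE"
  else "GOLD_STANDARD_REQUIRED"
}

# All valid clinical flag subsets (LOW and HIGH are mutually exclusive).
valid_flag_subsets <- function() {
  subsets <- list(character(0))
  for (f in CLINICAL_FLAGS)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, f)))
  Filter(function(s) !all(c("MUSCLE_MASS_LOW", "MUSCLE_MASS_HIGH") %in% s),
         subsets)
}
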