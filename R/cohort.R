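#' Configuration for a synthetic validation cohort
#'
#' Describes a cohort with known ground truth: true GFR values, mechanistic
#' confounders (muscle-mass deviation acting multiplicatively on creatinine,
#' glucocorticoid-induced inflation acting on cystatin C), multiplicative
#' lognormal assay noise, and gold-standard measurement imprecision. Marker
#' levels are manufactured by exact inversion of the registered prediction
#' equations, so with all noise and confounders switched off the estimates
#' recover true GFR identically.
#'
#' All multiplicative noise uses lognormal(meanlog 0, sdlog `log(1 + cv)`);
#' see the package vignette for why this parameterisation was chosen and how
#' it behaves at the CVs used here.
#'
#' @param n Number of patients (≥ 1).
#' @param seed Integer seed; the cohort is bitwise reproducible from it.
#' @param true_gfr_range True relative GFR drawn uniformly from this range
#'   (default `c(10, 120)` mL/min/1.73 m²).
#' @param age_range Ages drawn uniformly (default `c(20, 80)` years, inside
#'   the adult validity range of the default creatinine equation).
#' @param sex_ratio Fraction female (default 0.5).
#' @param sigma_muscle sdlog of the background lognormal muscle-mass factor M
#'   multiplying creatinine (default 0.15).
#' @param p_muscle_abnormal Probability a patient has clinically abnormal
#'   muscle mass, in which case M is forced to `muscle_abnormal_factor`
#'   (default 0).
#' @param muscle_abnormal_factor The forced abnormal M (default 0.5, i.e.
#'   halved muscle mass; 2.0 models abnormally high muscle mass).
#' @param p_glucocorticoid Probability of moderate-to-high-dose
#'   glucocorticoid treatment (default 0).
#' @param steroid_factor Multiplicative cystatin C inflation G for treated
#'   patients, ≥ 1 (default 2.0).
#' @param cv_creatinine_assay,cv_cystatin_assay Assay coefficients of
#'   variation (default 0.05 each).
#' @param cv_gold_standard CV of the gold-standard procedure (default 0.10).
#' @param flags_observed If `TRUE` (default) the confounder flags are
#'   recorded on the generated patients; if `FALSE` the confounders act but
#'   the clinician cannot see them (unexplained-discordance scenario).
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n, seed,
                          true_gfr_range = c(10, 120),
                          age_range = c(20, 80),
                          sex_ratio = 0.5,
                          sigma_muscle = 0.15,
                          p_muscle_abnormal = 0,
                          muscle_abnormal_factor = 0.5,
                          p_glucocorticoid = 0,
                          steroid_factor = 2.0,
                          cv_creatinine_assay = 0.05,
                          cv_cystatin_assay = 0.05,
                          cv_gold_standard = 0.10,
                          flags_observed = TRUE) {
  if (!is_scalar_number(n) || n < 1) err_domain("n must be >= 1")
  if (!is_scalar_number(seed)) err_domain("seed is mandatory and must be a number")
  ord <- function(r) is.numeric(r) && length(r) == 2L && r[1] < r[2] && r[1] > 0
  if (!ord(true_gfr_range) || !ord(age_range))
    err_domain("true_gfr_range and age_range must be ordered positive pairs")
  for (p in c(sex_ratio, p_muscle_abnormal, p_glucocorticoid))
    if (p < 0 || p > 1) err_domain("probabilities must lie in [0, 1]")
  for (cv in c(cv_creatinine_assay, cv_cystatin_assay, cv_gold_standard))
    if (cv < 0) err_domain("CVs must be >= 0")
  if (steroid_factor < 1) err_domain("steroid_factor must be >= 1")
  if (muscle_abnormal_factor <= 0) err_domain("muscle_abnormal_factor must be > 0")
  if (sigma_muscle < 0) err_domain("sigma_muscle must be >= 0")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         true_gfr_range = true_gfr_range, age_range = age_range,
         sex_ratio = sex_ratio, sigma_muscle = sigma_muscle,
         p_muscle_abnormal = p_muscle_abnormal,
         muscle_abnormal_factor = muscle_abnormal_factor,
         p_glucocorticoid = p_glucocorticoid,
         steroid_factor = steroid_factor,
         cv_creatinine_assay = cv_creatinine_assay,
         cv_cystatin_assay = cv_cystatin_assay,
         cv_gold_standard = cv_gold_standard,
         flags_observed = isTRUE(flags_observed)),
    class = "cohort_config"
  )
}

# run code under a private RNG stream, restoring the caller's state
with_cohort_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# multiplicative lognormal noise factor; cv = 0 gives exactly 1
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, log(1 + cv)))
}

#' Simulate one gold-standard GFR measurement
#'
#' Gold-standard (invasive clearance) procedures have non-zero imprecision:
#' repeated on the same patient they do not reproduce each other exactly, so
#' even a perfect prediction equation cannot reach 100% P30 against a
#' measured reference. This models one measurement as
#' `true_gfr × lognormal(0, log(1 + cv))`; `cv = 0` returns `true_gfr`
#' exactly.
#'
#' @param true_gfr True GFR (mL/min/1.73 m²), > 0. Vectorised.
#' @param cv Coefficient of variation of the procedure, ≥ 0 (typical 0.10).
#' @return Simulated measured GFR, same length as `true_gfr`.
#' @export
measure_gold_standard <- function(true_gfr, cv = 0.10) {
  if (any(!is.finite(true_gfr)) || any(true_gfr <= 0))
    err_domain("true_gfr must be positive")
  if (!is_scalar_number(cv) || cv < 0) err_domain("cv must be >= 0")
  true_gfr * noise_factor(length(true_gfr), cv)
}

#' Generate a synthetic patient cohort with known ground truth
#'
#' For each patient: draws true GFR, age and sex; applies the confounder
#' mechanism (muscle factor M on creatinine, steroid factor G on cystatin C);
#' manufactures marker levels by exact inversion of the chosen prediction
#' equations at the true GFR, multiplied by the confounder factor and
#' lognormal assay noise; and simulates a gold-standard measurement. The
#' ground truth (true GFR, M, G, true flags, and the route the deterministic
#' confounders imply under the given policy, ignoring assay noise) is
#' returned alongside, enabling exact recovery tests.
#'
#' @param config A [cohort_config()].
#' @param registry An [equation_registry()].
#' @param cys_id,crea_id Equation ids used for inversion (and expected
#'   routing).
#' @param policy [concordance_policy()] used only to compute the expected
#'   route in the truth table.
#' @return An object of class `synthetic_cohort`: list with `panel` (a
#'   patient data frame, see [read_panel()] for the column contract), `truth`
#'   (data frame: `patient_id`, `true_gfr`, `muscle_factor`, `steroid_factor`,
#'   `flags_true`, `expected_route`) and `config`.
#' @examples
#' reg <- default_registry()
#' coh <- generate_cohort(cohort_config(n = 5, seed = 42), reg)
#' coh$panel
#' @export
generate_cohort <- function(config, registry,
                            cys_id = "grubb_cystatin", crea_id = "mdrd_idms",
                            policy = concordance_policy()) {
  stopifnot(inherits(config, "cohort_config"))
  cys <- get_equation(registry, cys_id)
  crea <- get_equation(registry, crea_id)
  n <- config$n

  with_cohort_rng(config$seed, {
    true_gfr <- stats::runif(n, config$true_gfr_range[1], config$true_gfr_range[2])
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
    height <- pmax(stats::rnorm(n, ifelse(sex == "female", 165, 178), 7), 140)
    weight <- pmax(stats::rnorm(n, ifelse(sex == "female", 68, 82), 12), 40)

    muscle_abnormal <- stats::runif(n) < config$p_muscle_abnormal
    M <- exp(stats::rnorm(n, 0, config$sigma_muscle))
    M[muscle_abnormal] <- config$muscle_abnormal_factor
    steroid <- stats::runif(n) < config$p_glucocorticoid
    G <- ifelse(steroid, config$steroid_factor, 1)

    pop <- rep(NA_character_, n)
    crea_clean <- invert_equation_v(crea, true_gfr, age, sex, pop, height) * M
    cys_clean <- invert_equation_v(cys, true_gfr, age, sex, pop, height) * G
    creatinine <- crea_clean * noise_factor(n, config$cv_creatinine_assay)
    cystatin_c <- cys_clean * noise_factor(n, config$cv_cystatin_assay)
    measured <- measure_gold_standard(true_gfr, config$cv_gold_standard)
  })

  flags_true <- character(n)
  flags_true[muscle_abnormal & M < 1] <- "MUSCLE_MASS_LOW"
  flags_true[muscle_abnormal & M >= 1] <- "MUSCLE_MASS_HIGH"
  flags_true[steroid] <- ifelse(flags_true[steroid] == "", CYS_INVALIDATING,
                                paste(flags_true[steroid], CYS_INVALIDATING, sep = ";"))

  # route implied by the deterministic confounders, before assay noise
  e_crea_det <- eval_equation_v(crea, crea_clean, age, sex, pop, height)
  e_cys_det <- eval_equation_v(cys, cys_clean, age, sex, pop, height)
  rd_det <- abs(e_cys_det - e_crea_det) / ((e_cys_det + e_crea_det) / 2)
  obs_flags <- if (config$flags_observed) flags_true else character(n)
  crea_bad <- grepl("MUSCLE_MASS_LOW|MUSCLE_MASS_HIGH", obs_flags)
  cys_bad <- grepl(CYS_INVALIDATING, obs_flags, fixed = TRUE)
  expected_route <- ifelse(
    rd_det <= active_limit(policy), "USE_MEAN",
    ifelse(crea_bad & !cys_bad, "USE_CYSTATIN",
           ifelse(cys_bad & !crea_bad, "USE_CREATININE",
                  "GOLD_STANDARD_REQUIRED")))

  ids <- sprintf("S%0*d", nchar(as.character(n)), seq_len(n))
  panel <- data.frame(
    patient_id = ids,
    age = age, sex = sex, height = height, weight = weight,
    population = NA_character_,
    creatinine = creatinine, cystatin_c = cystatin_c,
    flags = obs_flags,
    measured_gfr = measured,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = ids, true_gfr = true_gfr,
    muscle_factor = M, steroid_factor = G,
    flags_true = flags_true, expected_route = expected_route,
    stringsAsFactors = FALSE
  )
  structure(list(panel = panel, truth = truth, config = config,
                 cys_id = cys_id, crea_id = crea_id),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", nrow(x$panel),
      "| seed =", x$config$seed, "\n")
  cat("  confounders: p(muscle abnormal) =", x$config$p_muscle_abnormal,
      "(M =", x$config$muscle_abnormal_factor, "),",
      "p(glucocorticoid) =", x$config$p_glucocorticoid,
      "(G =", x$config$steroid_factor, ")\n")
  cat("  assay CVs:", x$config$cv_creatinine_assay, "(crea),",
      x$config$cv_cystatin_assay, "(cysC),",
      x$config$cv_gold_standard, "(gold standard)\n")
  cat("  expected routes:\n")
  print(table(x$truth$expected_route))
  invisible(x)
}

#' @export
as.data.frame.synthetic_cohort <- function(x, ...) x$panel
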