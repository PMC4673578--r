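# Vectorised forward/inverse evaluation over patient vectors. These are the
# batch workhorses behind lund_gfr() and the cohort generator; they agree
# with the scalar eval_equation()/invert_equation() path (tested) but avoid
# constructing one patient_record per row.

vec_sex_coeff <- function(spec, sex) {
  fc <- if ("female_coeff" %in% names(spec$params))
    unname(spec$params[["female_coeff"]]) else 1
  ifelse(sex == "female", fc, 1)
}

vec_pop_coeff <- function(spec, population) {
  out <- rep(1, length(population))
  pop_params <- grep("^pop_", names(spec$params), value = TRUE)
  for (nm in pop_params) {
    tag <- sub("^pop_", "", nm)
    out[!is.na(population) & population == tag] <- unname(spec$params[[nm]])
  }
  out
}

vec_pediatric_mult <- function(spec, age) {
  p <- spec$params
  if (!("pediatric_multiplier" %in% names(p))) return(rep(1, length(age)))
  cutoff <- if ("pediatric_cutoff" %in% names(p)) p[["pediatric_cutoff"]] else 14
  ifelse(age < cutoff, unname(p[["pediatric_multiplier"]]), 1)
}

eval_equation_v <- function(spec, marker, age, sex,
                            population = rep(NA_character_, length(age)),
                            height = rep(NA_real_, length(age))) {
  p <- spec$params
  switch(spec$form,
    power_law_cystatin =
      unname(p[["A"]]) * marker^(-unname(p[["B"]])) * vec_pediatric_mult(spec, age),
    mdrd_like =
      unname(p[["c0"]]) * (marker / CREA_UMOL_PER_MGDL)^unname(p[["e1"]]) *
        age^unname(p[["e2"]]) * vec_sex_coeff(spec, sex) *
        vec_pop_coeff(spec, population),
    height_over_creatinine =
      unname(p[["k"]]) * height / (marker / CREA_UMOL_PER_MGDL),
    piecewise_loglinear = {
      vapply(seq_along(marker), function(i) {
        proxy <- structure(
          list(patient_id = "", age = age[i], sex = sex[i],
               height = height[i], weight = NA_real_,
               population = population[i], creatinine = NA_real_,
               cystatin_c = NA_real_, flags = character(),
               measured_gfr = NA_real_),
          class = "patient_record")
        eval_equation(spec, proxy, marker[i])
      }, numeric(1))
    }
  )
}

invert_equation_v <- function(spec, target, age, sex,
                              population = rep(NA_character_, length(age)),
                              height = rep(NA_real_, length(age))) {
  p <- spec$params
  switch(spec$form,
    power_law_cystatin =
      (target / (unname(p[["A"]]) * vec_pediatric_mult(spec, age)))^(-1 / unname(p[["B"]])),
    mdrd_like = {
      base <- unname(p[["c0"]]) * age^unname(p[["e2"]]) *
        vec_sex_coeff(spec, sex) * vec_pop_coeff(spec, population)
      CREA_UMOL_PER_MGDL * (target / base)^(1 / unname(p[["e1"]]))
    },
    height_over_creatinine =
      CREA_UMOL_PER_MGDL * unname(p[["k"]]) * height / target,
    piecewise_loglinear = {
      vapply(seq_along(target), function(i) {
        proxy <- structure(
          list(patient_id = "", age = age[i], sex = sex[i],
               height = height[i], weight = NA_real_,
               population = population[i], creatinine = NA_real_,
               cystatin_c = NA_real_, flags = character(),
               measured_gfr = NA_real_),
          class = "patient_record")
        invert_equation(target[i], proxy, spec)
      }, numeric(1))
    }
  )
}

vec_age_ok <- function(spec, age) {
  age >= spec$age_range[1] & age < spec$age_range[2]
}
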