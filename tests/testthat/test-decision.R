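test_that("concordance check computes the symmetric relative difference", {
  pol <- concordance_policy()
  cc <- check_concordance(60, 60, pol)
  expect_true(cc$concordant)
  expect_equal(cc$relative_difference, 0)

  # |80-60| / 70 = 0.285714...: concordant at 0.30, discordant for dosing
  cc <- check_concordance(80, 60, pol)
  expect_equal(cc$relative_difference, 20 / 70, tolerance = 1e-12)
  expect_true(cc$concordant)
  expect_false(check_concordance(80, 60, concordance_policy("dosing"))$concordant)

  # symmetric in its two arguments
  expect_equal(check_concordance(80, 60, pol)$relative_difference,
               check_concordance(60, 80, pol)$relative_difference)
  expect_error(check_concordance(-1, 60, pol), class = "lundgfr_domain_error")
})

test_that("concordance is monotone in the limit and exact on the boundary", {
  for (pair in list(c(55, 70), c(100, 120), c(30, 44))) {
    rd <- check_concordance(pair[1], pair[2])$relative_difference
    lims <- sort(c(rd, 0.05, 0.15, 0.45, 0.9))
    conc <- vapply(lims, function(L)
      check_concordance(pair[1], pair[2],
                        concordance_policy(relative_limit_general = L,
                                           relative_limit_dosing = L))$concordant,
      logical(1))
    # once concordant at some limit, concordant at every larger limit
    expect_true(all(diff(conc) >= 0))
    # boundary counts as concordant (limit == relative difference)
    expect_true(conc[which(lims == rd)])
  }
})

test_that("combine_mean is the symmetric arithmetic mean with combined basis", {
  expect_equal(combine_mean(60, 60)$value, 60)
  m <- combine_mean(80, 60)
  expect_equal(m$value, 70)
  expect_identical(m$marker_basis, "combined")
  expect_identical(m$equation_id, "mean")
  expect_equal(combine_mean(43.2, 87.1)$value, combine_mean(87.1, 43.2)$value)
})

test_that("flag arbitration routes to the marker the flags do not invalidate", {
  expect_identical(resolve_discordance("MUSCLE_MASS_LOW"), "USE_CYSTATIN")
  expect_identical(resolve_discordance("MUSCLE_MASS_HIGH"), "USE_CYSTATIN")
  expect_identical(resolve_discordance("GLUCOCORTICOID_MODERATE_HIGH_DOSE"),
                   "USE_CREATININE")
  expect_identical(resolve_discordance(character(0)), "GOLD_STANDARD_REQUIRED")
  expect_identical(
    resolve_discordance(c("MUSCLE_MASS_LOW", "GLUCOCORTICOID_MODERATE_HIGH_DOSE")),
    "GOLD_STANDARD_REQUIRED")
  expect_error(resolve_discordance(c("MUSCLE_MASS_LOW", "MUSCLE_MASS_HIGH")),
               class = "lundgfr_domain_error")
})

test_that("the engine matches an independent truth table over all flag subsets x concordance", {
  reg <- default_registry()
  cases <- 0L
  for (flags in valid_flag_subsets()) {
    for (concordant in c(TRUE, FALSE)) {
      p <- if (concordant) patient_at(60, 60, flags = flags)
           else patient_at(60, 120, flags = flags)
      d <- lund_decide(p, reg)
      expect_identical(d$route, truth_table_route(flags, concordant),
                       label = sprintf("flags={%s} concordant=%s",
                                       paste(flags, collapse = ";"), concordant))
      # final estimate present iff a non-invasive route was found
      expect_identical(is.null(d$final_estimate),
                       d$route == "GOLD_STANDARD_REQUIRED")
      cases <- cases + 1L
    }
  }
  expect_lte(cases, 32L)
})

test_that("concordant patients get the arithmetic mean; flags are only consulted on discordance", {
  reg <- default_registry()
  p <- patient_at(60, 60, flags = "GLUCOCORTICOID_MODERATE_HIGH_DOSE")
  d <- lund_decide(p, reg)
  expect_identical(d$route, "USE_MEAN")
  expect_false(d$flags_consulted)
  expect_equal(d$relative_difference, 0, tolerance = 1e-9)
  expect_equal(d$final_estimate$value,
               (d$e_cystatin$value + d$e_creatinine$value) / 2)

  # strict flag policy lets the flag veto even a concordant mean
  strict <- concordance_policy(strict_flags = TRUE)
  ds <- lund_decide(p, reg, policy = strict)
  expect_identical(ds$route, "USE_CREATININE")

  pd <- patient_at(60, 120, flags = "MUSCLE_MASS_LOW")
  dd <- lund_decide(pd, reg)
  expect_identical(dd$route, "USE_CYSTATIN")
  expect_true(dd$flags_consulted)
  expect_equal(dd$final_estimate$value, dd$e_cystatin$value)
})

test_that("decision errors name the failing guard", {
  reg <- default_registry()
  kid <- patient_record("k", 10, "male", creatinine = 50, cystatin_c = 1)
  expect_error(lund_decide(kid, reg), class = "lundgfr_not_applicable")
  expect_error(lund_decide(kid, reg), "mdrd_idms")
  no_cys <- patient_record("nc", 40, "male", creatinine = 80)
  expect_error(lund_decide(no_cys, reg), class = "lundgfr_missing_marker")
})

test_that("anchors capture the concordant state and are refused otherwise", {
  reg <- default_registry()
  p <- patient_at(70, 70)
  d <- lund_decide(p, reg)
  a <- make_anchor(d, p)
  expect_equal(a$creatinine_ref, p$creatinine)
  expect_equal(a$gfr_ref, d$final_estimate$value)
  expect_true(a$valid)

  gold <- lund_decide(patient_at(60, 120), reg)
  expect_error(make_anchor(gold, patient_at(60, 120)),
               class = "lundgfr_anchor_refused")
  single <- lund_decide(patient_at(60, 120, flags = "MUSCLE_MASS_LOW"), reg)
  expect_error(make_anchor(single, patient_at(60, 120)),
               class = "lundgfr_anchor_refused")
})

test_that("monitoring reproduces the anchor point exactly and scales as the anchored power law", {
  reg <- default_registry()
  p <- patient_at(70, 70)
  a <- make_anchor(lund_decide(p, reg), p)

  same <- monitor_gfr(a, new_creatinine = a$creatinine_ref, registry = reg)
  expect_equal(same$value, a$gfr_ref, tolerance = 1e-15)
  expect_identical(same$marker_basis, "creatinine")

  # MDRD-anchored: doubling creatinine divides the estimate by exactly 2^1.154
  doubled <- monitor_gfr(a, new_creatinine = 2 * a$creatinine_ref, registry = reg)
  expect_equal(a$gfr_ref / doubled$value, 2^1.154, tolerance = 1e-12)

  expect_error(monitor_gfr(a, 80, flags = "MUSCLE_MASS_CHANGED", registry = reg),
               class = "lundgfr_reevaluation_required")
  expect_error(monitor_gfr(a, -3, registry = reg),
               class = "lundgfr_domain_error")
})

test_that("batch lund_gfr agrees with per-patient lund_decide", {
  reg <- default_registry()
  set.seed(3)
  coh <- generate_cohort(cohort_config(n = 40, seed = 99,
                                       p_muscle_abnormal = 0.3,
                                       p_glucocorticoid = 0.2,
                                       cv_creatinine_assay = 0.15,
                                       cv_cystatin_assay = 0.15),
                         reg)
  fit <- lund_gfr(coh)
  recs <- panel_records(coh$panel)
  for (i in seq_along(recs)) {
    d <- lund_decide(recs[[i]], reg)
    expect_identical(fit$decisions$route[i], d$route)
    expect_equal(fit$decisions$e_cystatin[i], d$e_cystatin$value)
    expect_equal(fit$decisions$e_creatinine[i], d$e_creatinine$value)
    if (d$route != "GOLD_STANDARD_REQUIRED")
      expect_equal(fit$decisions$final_estimate[i], d$final_estimate$value)
  }
})

test_that("batch interface records failures per row instead of aborting", {
  reg <- default_registry()
  panel <- as_panel(list(
    patient_record("ok", 40, "female", creatinine = 80, cystatin_c = 1.2),
    patient_record("kid", 9, "female", creatinine = 40, cystatin_c = 1.0),
    patient_record("nocys", 55, "male", creatinine = 95)
  ))
  fit <- lund_gfr(panel, reg)
  expect_equal(fit$n_failed, 2)
  expect_false(is.na(fit$decisions$route[1]))
  expect_match(fit$decisions$error[2], "age")
  expect_match(fit$decisions$error[3], "cystatin_c")
})
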