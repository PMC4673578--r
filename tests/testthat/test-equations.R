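test_that("registry stores, resolves and enumerates equations in order", {
  reg <- equation_registry()
  pl <- gfr_equation("pl", "cystatin_c", "power_law_cystatin",
                     params = c(A = 84.69, B = 1.680), age_range = c(1, 120))
  reg <- register_equation(reg, pl)
  expect_identical(get_equation(reg, "pl"), pl)

  jp <- gfr_equation("mdrd_japanese2", "creatinine", "mdrd_like",
                     params = c(c0 = 175, e1 = -1.154, e2 = -0.203,
                                female_coeff = 0.742, pop_japanese = 0.763),
                     age_range = c(18, 120))
  reg <- register_equation(reg, jp)
  expect_equal(get_equation(reg, "mdrd_japanese2")$params[["pop_japanese"]], 0.763)
  expect_identical(names(reg), c("pl", "mdrd_japanese2"))

  expect_error(register_equation(reg, pl), class = "lundgfr_duplicate_id")
  expect_error(register_equation(reg, pl), "pl")
  expect_error(get_equation(reg, "nope"), class = "lundgfr_unknown_id")
})

test_that("invalid equation specs are rejected with the violated invariant", {
  expect_error(gfr_equation("x", "cystatin_c", "power_law_cystatin",
                            params = c(A = -1, B = 1.6), age_range = c(1, 120)),
               class = "lundgfr_invalid_spec")
  expect_error(gfr_equation("x", "cystatin_c", "power_law_cystatin",
                            params = c(A = 80, B = 1.6), age_range = c(120, 1)),
               class = "lundgfr_invalid_spec")
  expect_error(gfr_equation("x", "creatinine", "mdrd_like",
                            params = c(c0 = 175, e1 = NaN, e2 = -0.203),
                            age_range = c(18, 120)),
               class = "lundgfr_invalid_spec")
  expect_error(gfr_equation("x", "creatinine", "power_law_cystatin",
                            params = c(A = 80, B = 1.6), age_range = c(1, 120)),
               class = "lundgfr_invalid_spec")
})

test_that("applicability guards: age bounds (inclusive-low, exclusive-high) and required fields", {
  reg <- test_registry()
  mdrd <- get_equation(reg, "mdrd_idms")
  kid <- patient_record("k", age = 10, sex = "male", creatinine = 50)
  expect_false(applicable(mdrd, kid))
  expect_error(egfr_creatinine(kid, mdrd), class = "lundgfr_not_applicable")

  cys <- get_equation(reg, "grubb_cystatin")
  expect_true(applicable(cys, patient_record("b", age = 1.0, sex = "female",
                                             cystatin_c = 1)))
  expect_false(applicable(cys, patient_record("b2", age = 0.9, sex = "female",
                                              cystatin_c = 1)))
  expect_false(applicable(mdrd, patient_record("u", age = 120, sex = "male",
                                               creatinine = 80)))

  cb <- get_equation(reg, "counahan_barratt")
  no_height <- patient_record("nh", age = 8, sex = "male", creatinine = 45)
  expect_false(applicable(cb, no_height))
  expect_error(egfr_creatinine(no_height, cb), class = "lundgfr_not_applicable")

  no_marker <- patient_record("nm", age = 40, sex = "female")
  expect_error(egfr_cystatin(no_marker, cys), class = "lundgfr_missing_marker")
})

test_that("cystatin power law matches hand-evaluated values and scaling identities", {
  reg <- test_registry()
  cys <- get_equation(reg, "grubb_cystatin")

  # x^-B = 1 at x = 1: adult gets A, child below the pediatric cutoff A*1.384
  expect_equal(egfr_cystatin(patient_record("a", 40, "female", cystatin_c = 1),
                             cys)$value, 84.69)
  expect_equal(egfr_cystatin(patient_record("c", 8, "female", cystatin_c = 1),
                             cys)$value, 84.69 * 1.384)
  # frozen hand evaluation of 84.69 * 2^-1.680
  expect_equal(egfr_cystatin(patient_record("a", 40, "female", cystatin_c = 2),
                             cys)$value, 26.43028, tolerance = 1e-6)
  # doubling cystatin divides the estimate by exactly 2^B
  for (x in c(0.5, 1.3, 4)) {
    e1 <- egfr_cystatin(patient_record("a", 40, "female", cystatin_c = x), cys)$value
    e2 <- egfr_cystatin(patient_record("a", 40, "female", cystatin_c = 2 * x), cys)$value
    expect_equal(e1 / e2, 2^1.680, tolerance = 1e-12)
  }
})

test_that("MDRD-like form matches hand evaluation; sex and population coefficients are purely multiplicative", {
  reg <- test_registry()
  mdrd <- get_equation(reg, "mdrd_idms")
  f40 <- patient_record("f", 40, "female", creatinine = 80)
  # frozen hand evaluation of 175*(80/88.4)^-1.154*40^-0.203*0.742
  expect_equal(egfr_creatinine(f40, mdrd)$value, 68.90708, tolerance = 1e-5)

  m40 <- patient_record("m", 40, "male", creatinine = 80)
  expect_equal(egfr_creatinine(f40, mdrd)$value /
                 egfr_creatinine(m40, mdrd)$value, 0.742, tolerance = 1e-12)

  fb <- patient_record("fb", 40, "female", creatinine = 80, population = "black")
  expect_equal(egfr_creatinine(fb, mdrd)$value /
                 egfr_creatinine(f40, mdrd)$value, 1.212, tolerance = 1e-12)

  # the Japanese variant is exactly 0.763 x the non-Japanese result
  fj <- patient_record("fj", 40, "female", creatinine = 80, population = "japanese")
  jp <- get_equation(reg, "mdrd_japanese")
  expect_equal(egfr_creatinine(fj, jp)$value /
                 egfr_creatinine(fj, mdrd)$value, 0.763, tolerance = 1e-12)
  # ... and the tag must match for the coefficient to act
  expect_equal(egfr_creatinine(f40, jp)$value, egfr_creatinine(f40, mdrd)$value)
})

test_that("height-over-creatinine ratio identity holds", {
  # choose inputs so k*height equals creatinine in mg/dL -> value 1.0
  spec <- gfr_equation("h", "creatinine", "height_over_creatinine",
                       params = c(k = 0.43), age_range = c(1, 18))
  h <- 100
  crea_umol <- 0.43 * h * 88.4  # k*height in mg/dL, back to umol/L
  p <- patient_record("c", 10, "male", height = h, creatinine = crea_umol)
  expect_equal(egfr_creatinine(p, spec)$value, 1.0, tolerance = 1e-12)
})

test_that("every registered equation is strictly decreasing in its marker on a 1000-point grid", {
  reg <- test_registry()
  p <- patient_record("g", 50, "female", height = 165)
  grid <- seq(0.2, 2000, length.out = 1000)
  cys_grid <- seq(0.2, 8, length.out = 1000)
  for (id in names(reg)) {
    spec <- get_equation(reg, id)
    marker <- if (spec$marker_basis == "cystatin_c") cys_grid else grid
    v <- eval_equation_v(spec, marker, rep(50, 1000), rep("female", 1000),
                         height = rep(165, 1000))
    expect_true(all(diff(v) < 0), label = paste(id, "strictly decreasing"))
  }
})

test_that("inversion round-trips to 1e-9 relative over GFR 5..150 for every registered equation", {
  reg <- test_registry()
  targets <- seq(5, 150, by = 5)
  patients <- list(
    patient_record("ad", 50, "female", height = 165),
    patient_record("ch", 9, "male", height = 135)
  )
  for (id in names(reg)) {
    spec <- get_equation(reg, id)
    for (p in patients) {
      if (p$age < spec$age_range[1] || p$age >= spec$age_range[2]) next
      for (g in targets) {
        marker <- invert_equation(g, p, spec)
        expect_gt(marker, 0)
        expect_equal(eval_equation(spec, p, marker) / g, 1, tolerance = 1e-9,
                     label = sprintf("%s at g=%g age=%g", id, g, p$age))
      }
    }
  }
  expect_error(invert_equation(-5, patients[[1]],
                               get_equation(reg, "grubb_cystatin")),
               class = "lundgfr_domain_error")
})

test_that("inverting at GFR = A returns cystatin 1.0 for an adult", {
  cys <- get_equation(default_registry(), "grubb_cystatin")
  p <- patient_record("a", 40, "female")
  expect_equal(invert_equation(84.69, p, cys), 1.0, tolerance = 1e-12)
})

test_that("scalar and vectorised evaluation agree on all forms", {
  reg <- test_registry()
  set.seed(11)
  n <- 25
  age <- runif(n, 20, 75); sex <- sample(c("female", "male"), n, TRUE)
  pop <- sample(c(NA, "black", "japanese"), n, TRUE)
  height <- runif(n, 150, 190)
  for (id in names(reg)) {
    spec <- get_equation(reg, id)
    marker <- if (spec$marker_basis == "cystatin_c") runif(n, 0.6, 4)
              else runif(n, 40, 400)
    vv <- eval_equation_v(spec, marker, age, sex, pop, height)
    sv <- vapply(seq_len(n), function(i) {
      p <- patient_record("i", age[i], sex[i], height = height[i],
                          population = if (is.na(pop[i])) NA_character_ else pop[i])
      eval_equation(spec, p, marker[i])
    }, numeric(1))
    expect_equal(vv, sv, tolerance = 1e-12, label = id)
  }
})

test_that("equation config round-trips through YAML and JSON, canonically", {
  reg <- test_registry()
  for (ext in c("yaml", "json")) {
    f1 <- withr::local_tempfile(fileext = paste0(".", ext))
    f2 <- withr::local_tempfile(fileext = paste0(".", ext))
    write_equations(reg, f1)
    reg2 <- read_equations(f1)
    expect_identical(names(reg2), names(reg))
    for (id in names(reg))
      expect_equal(get_equation(reg2, id)$params, get_equation(reg, id)$params)
    # canonical dump: write(read(write(x))) is byte-identical
    write_equations(reg2, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})
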