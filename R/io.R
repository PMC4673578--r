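PANEL_COLUMNS <- c("patient_id", "age", "sex", "height", "weight",
                   "population", "creatinine", "cystatin_c", "flags",
                   "measured_gfr")
PANEL_REQUIRED <- c("patient_id", "age", "sex")
PANEL_NUMERIC <- c("age", "height", "weight", "creatinine", "cystatin_c",
                   "measured_gfr")

#' Read and write patient panels
#'
#' A patient panel is a CSV (UTF-8, header, "." decimal separator) with
#' columns `patient_id`, `age`, `sex` (required) and optionally `height`,
#' `weight`, `population`, `creatinine` (μmol/L), `cystatin_c` (mg/L),
#' `flags` (semicolon-separated [CLINICAL_FLAGS] names) and `measured_gfr`
#' (mL/min/1.73 m²). Unknown columns are rejected by name; empty cells become
#' missing optionals; invalid cells are reported with their row number.
#' `read_panel()` returns a data frame with all canonical columns present (in
#' canonical order), so read → write → read is the identity on valid panels.
#'
#' @param path File path.
#' @param panel A panel data frame (as returned by `read_panel()` or
#'   [generate_cohort()]).
#' @return `read_panel()`: validated panel data frame. `write_panel()`: the
#'   path, invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) err_io(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  validate_panel(df, source = path)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_panel <- function(df, source = "panel") {
  unknown <- setdiff(names(df), PANEL_COLUMNS)
  if (length(unknown) > 0L)
    err_io(paste0(source, ": unknown column(s): ", paste(unknown, collapse = ", ")))
  missing <- setdiff(PANEL_REQUIRED, names(df))
  if (length(missing) > 0L)
    err_io(paste0(source, ": missing required column(s): ",
                  paste(missing, collapse = ", ")))
  n <- nrow(df)
  out <- data.frame(patient_id = as.character(df$patient_id),
                    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  for (col in PANEL_NUMERIC) {
    if (col %in% names(df)) {
      raw <- df[[col]]
      if (is.character(raw)) raw[!nzchar(trimws(raw))] <- NA
      v <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(v))
      if (length(bad) > 0L)
        err_io(sprintf("%s: unparseable value in column '%s', row %d: '%s'",
                       source, col, bad[1], raw[bad[1]]))
      pos <- which(!is.na(v) & v <= 0)
      if (length(pos) > 0L)
        err_io(sprintf("%s: non-positive value in column '%s', row %d",
                       source, col, pos[1]))
      out[[col]] <- v
    } else out[[col]] <- rep(NA_real_, n)
  }
  sex <- trimws(tolower(as.character(df$sex)))
  bad <- which(!(sex %in% c("female", "male")))
  if (length(bad) > 0L)
    err_io(sprintf("%s: sex must be 'female' or 'male', row %d: '%s'",
                   source, bad[1], df$sex[bad[1]]))
  out$sex <- sex
  if ("population" %in% names(df)) {
    p <- trimws(as.character(df$population))
    p[!nzchar(p)] <- NA_character_
    out$population <- p
  } else out$population <- rep(NA_character_, n)
  if ("flags" %in% names(df)) {
    fl <- as.character(df$flags)
    fl[is.na(fl)] <- ""
    for (i in which(nzchar(fl))) {
      parts <- strsplit(fl[i], ";", fixed = TRUE)[[1]]
      tryCatch(validate_flags(parts[nzchar(parts)]),
               lundgfr_domain_error = function(e)
                 err_io(sprintf("%s: invalid flags in row %d: %s",
                                source, i, conditionMessage(e))))
    }
    out$flags <- fl
  } else out$flags <- rep("", n)
  out[, PANEL_COLUMNS]
}

#' Convert between a panel data frame and patient records
#'
#' @param panel A validated panel data frame.
#' @param records A list of [patient_record()] objects.
#' @return `panel_records()`: list of `patient_record`s; `as_panel()`: a
#'   canonical panel data frame.
#' @export
panel_records <- function(panel) {
  panel <- validate_panel(panel)
  lapply(seq_len(nrow(panel)), function(i) {
    fl <- strsplit(panel$flags[i], ";", fixed = TRUE)[[1]]
    patient_record(panel$patient_id[i], panel$age[i], panel$sex[i],
                   height = panel$height[i], weight = panel$weight[i],
                   population = panel$population[i],
                   creatinine = panel$creatinine[i],
                   cystatin_c = panel$cystatin_c[i],
                   flags = fl[nzchar(fl)],
                   measured_gfr = panel$measured_gfr[i])
  })
}

#' @rdname panel_records
#' @export
as_panel <- function(records) {
  if (inherits(records, "patient_record")) records <- list(records)
  df <- do.call(rbind, lapply(records, function(p) {
    data.frame(patient_id = p$patient_id, age = p$age, sex = p$sex,
               height = p$height, weight = p$weight,
               population = p$population, creatinine = p$creatinine,
               cystatin_c = p$cystatin_c,
               flags = paste(p$flags, collapse = ";"),
               measured_gfr = p$measured_gfr, stringsAsFactors = FALSE)
  }))
  validate_panel(df)
}

EQ_FIELD_ORDER <- c("equation_id", "marker_basis", "form", "params",
                    "age_range", "required_fields")

#' Read and write equation registries as configuration files
#'
#' Equation definitions live in YAML (`.yaml`/`.yml`) or JSON (`.json`)
#' files: a list of records, each with `equation_id`, `marker_basis`, `form`,
#' `params` (named map), `age_range` and `required_fields`. `write_equations()`
#' emits records with exactly that key order, so write → read → write is
#' byte-identical (a canonical dump).
#'
#' @param path Config file path; format chosen by extension.
#' @param registry An [equation_registry()].
#' @return `read_equations()`: an `equation_registry` (registration order =
#'   file order). `write_equations()`: the path, invisibly.
#' @export
read_equations <- function(path) {
  if (!file.exists(path)) err_io(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  records <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    err_io(paste0("unsupported config format: .", ext)))
  if (is.null(records) || length(records) == 0L)
    err_io(paste0(path, ": no equation records found"))
  reg <- equation_registry()
  for (r in records) {
    spec <- gfr_equation(
      equation_id = r$equation_id, marker_basis = r$marker_basis,
      form = r$form, params = unlist(r$params),
      age_range = as.numeric(unlist(r$age_range)),
      required_fields = as.character(unlist(r$required_fields)))
    reg <- register_equation(reg, spec)
  }
  reg
}

#' @rdname read_equations
#' @export
write_equations <- function(registry, path) {
  stopifnot(inherits(registry, "equation_registry"))
  records <- lapply(registry$equations, function(s) {
    list(equation_id = s$equation_id, marker_basis = s$marker_basis,
         form = s$form, params = as.list(s$params),
         age_range = s$age_range, required_fields = as.list(s$required_fields))
  })
  names(records) <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(records, path, precision = 12)
  } else if (ext == "json") {
    writeLines(jsonlite::toJSON(records, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  } else err_io(paste0("unsupported config format: .", ext))
  invisible(path)
}

#' Export age-sweep eGFR curves at a fixed creatinine level
#'
#' Evaluates creatinine-based equations over an age grid at a constant plasma
#' creatinine, one row per (age, equation). Equations emit rows only inside
#' their own age range, so pediatric and adult curves cover complementary
#' age spans. Height-based equations require a height-for-age table
#' (`data.frame(age, height)`, linearly interpolated; clamped at the table
#' ends).
#'
#' @param registry An [equation_registry()].
#' @param equation_ids Ids of creatinine-based equations to sweep.
#' @param sex `"female"` or `"male"`.
#' @param creatinine Constant plasma creatinine in μmol/L (e.g. 80).
#' @param age_grid Numeric vector of ages in years.
#' @param height_table Optional `data.frame(age, height)` for height-based
#'   equations.
#' @param population Optional population tag.
#' @return Data frame with columns `age`, `equation_id`, `egfr`.
#' @examples
#' curves <- export_age_curve(default_registry(), c("mdrd_idms"),
#'                            sex = "female", creatinine = 80,
#'                            age_grid = 18:90)
#' head(curves)
#' @export
export_age_curve <- function(registry, equation_ids, sex, creatinine,
                             age_grid, height_table = NULL,
                             population = NA_character_) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is_scalar_number(creatinine) || creatinine <= 0)
    err_domain("creatinine must be positive")
  out <- list()
  for (id in equation_ids) {
    spec <- get_equation(registry, id)
    if (spec$marker_basis != "creatinine")
      err_invalid_spec(paste0("age curves are defined for creatinine-based equations; '",
                              id, "' is ", spec$marker_basis, "-based"))
    ages <- age_grid[vec_age_ok(spec, age_grid)]
    if (length(ages) == 0L) next
    if ("height" %in% spec$required_fields) {
      if (is.null(height_table))
        err_not_applicable(paste0(
          "equation '", id, "' needs height: supply a height_table (age, height)"))
      h <- stats::approx(height_table$age, height_table$height,
                         xout = ages, rule = 2)$y
    } else h <- rep(NA_real_, length(ages))
    egfr <- eval_equation_v(spec, rep(creatinine, length(ages)), ages,
                            rep(sex, length(ages)),
                            rep(population, length(ages)), h)
    out[[id]] <- data.frame(age = ages, equation_id = id, egfr = egfr,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(age = numeric(), equation_id = character(),
                      egfr = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write decision reports as JSON lines
#'
#' One JSON object per patient with deterministic field order: `patient_id`,
#' `route`, `e_cystatin`, `e_creatinine`, `relative_difference`, `limit`,
#' `context`, `flags`, `final_estimate` (null when a gold-standard
#' measurement is required), `error` (null unless the record failed).
#'
#' @param x A [lund_gfr()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_decisions <- function(x, path) {
  stopifnot(inherits(x, "lund_gfr"))
  d <- x$decisions
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(d))) {
    rec <- list(
      patient_id = d$patient_id[i],
      route = if (is.na(d$route[i])) NULL else d$route[i],
      e_cystatin = if (is.na(d$e_cystatin[i])) NULL else d$e_cystatin[i],
      e_creatinine = if (is.na(d$e_creatinine[i])) NULL else d$e_creatinine[i],
      relative_difference = if (is.na(d$relative_difference[i])) NULL
                            else d$relative_difference[i],
      limit = x$limit,
      context = x$context,
      flags = d$flags[i],
      final_estimate = if (is.na(d$final_estimate[i])) NULL else d$final_estimate[i],
      error = if (is.na(d$error[i])) NULL else d$error[i]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}
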