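#' Apply the dual-marker GFR decision strategy to a patient panel
#'
#' The top-level entry point. For every patient it estimates relative GFR
#' with a cystatin C-based and a creatinine-based prediction equation,
#' checks agreement within the policy limit (the internal quality check),
#' and routes each patient to the arithmetic mean (concordant), a
#' single-marker estimate (discordant but explained by a clinical flag), or
#' an invasive gold-standard measurement (discordant and unexplained).
#' Records that fail (equation not applicable, marker missing) are kept with
#' an error message rather than aborting the batch.
#'
#' @param x A patient panel data frame (see [read_panel()]), a
#'   [generate_cohort()] result, a list of [patient_record()]s, or a single
#'   `patient_record`.
#' @param registry An [equation_registry()] (default [default_registry()]).
#' @param cys_id,crea_id Ids of the cystatin C- and creatinine-based
#'   equations to use.
#' @param policy A [concordance_policy()].
#' @return An object of class `lund_gfr` with a `decisions` data frame
#'   (columns `patient_id`, `age`, `sex`, `flags`, `e_cystatin`,
#'   `e_creatinine`, `relative_difference`, `concordant`, `route`,
#'   `final_estimate`, `measured_gfr`, `error`) plus the policy and equation
#'   ids used. Methods: `print`, `summary`, `as.data.frame`, `plot`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 50, seed = 7), default_registry())
#' fit <- lund_gfr(coh)
#' summary(fit)
#' @export
lund_gfr <- function(x, registry = default_registry(),
                     cys_id = "grubb_cystatin", crea_id = "mdrd_idms",
                     policy = concordance_policy()) {
  if (inherits(x, "synthetic_cohort")) x <- x$panel
  if (inherits(x, "patient_record")) x <- list(x)
  if (is.list(x) && !is.data.frame(x)) x <- as_panel(x)
  panel <- validate_panel(x)
  n <- nrow(panel)
  cys <- get_equation(registry, cys_id)
  crea <- get_equation(registry, crea_id)
  limit <- active_limit(policy)

  check_eq <- function(spec) {
    errs <- rep(NA_character_, n)
    ok_age <- vec_age_ok(spec, panel$age)
    errs[!ok_age] <- paste0(spec$equation_id, ": age outside [",
                            spec$age_range[1], ", ", spec$age_range[2], ")")
    for (f in spec$required_fields) {
      present <- if (f %in% c("age", "sex", "patient_id")) rep(TRUE, n)
                 else !is.na(panel[[f]])
      errs[is.na(errs) & !present] <-
        paste0(spec$equation_id, ": missing required field '", f, "'")
    }
    errs
  }
  err <- check_eq(cys)
  e2 <- check_eq(crea)
  err[is.na(err)] <- e2[is.na(err)]
  ok <- is.na(err)

  e_cys <- e_crea <- rep(NA_real_, n)
  if (any(ok)) {
    e_cys[ok] <- eval_equation_v(cys, panel$cystatin_c[ok], panel$age[ok],
                                 panel$sex[ok], panel$population[ok],
                                 panel$height[ok])
    e_crea[ok] <- eval_equation_v(crea, panel$creatinine[ok], panel$age[ok],
                                  panel$sex[ok], panel$population[ok],
                                  panel$height[ok])
  }
  rd <- abs(e_cys - e_crea) / ((e_cys + e_crea) / 2)
  concordant <- ifelse(ok, rd <= limit, NA)

  crea_bad <- grepl("MUSCLE_MASS_LOW|MUSCLE_MASS_HIGH", panel$flags)
  cys_bad <- grepl(CYS_INVALIDATING, panel$flags, fixed = TRUE)
  flag_route <- ifelse(crea_bad & !cys_bad, "USE_CYSTATIN",
                ifelse(cys_bad & !crea_bad, "USE_CREATININE",
                       "GOLD_STANDARD_REQUIRED"))
  use_mean <- concordant &
    !(policy$strict_flags & (crea_bad | cys_bad))
  route <- ifelse(!ok, NA_character_,
           ifelse(use_mean, "USE_MEAN", flag_route))
  final <- ifelse(is.na(route), NA_real_,
           ifelse(route == "USE_MEAN", (e_cys + e_crea) / 2,
           ifelse(route == "USE_CYSTATIN", e_cys,
           ifelse(route == "USE_CREATININE", e_crea, NA_real_))))

  decisions <- data.frame(
    patient_id = panel$patient_id, age = panel$age, sex = panel$sex,
    flags = panel$flags,
    e_cystatin = e_cys, e_creatinine = e_crea,
    relative_difference = rd, concordant = concordant, route = route,
    final_estimate = final, measured_gfr = panel$measured_gfr,
    error = err, stringsAsFactors = FALSE
  )
  structure(
    list(decisions = decisions, policy = policy, limit = limit,
         context = policy$context, cys_id = cys_id, crea_id = crea_id,
         n = n, n_failed = sum(!ok)),
    class = "lund_gfr"
  )
}

#' @export
print.lund_gfr <- function(x, ...) {
  cat("<lund_gfr> ", x$n, " patient(s); equations: ", x$cys_id, " + ",
      x$crea_id, "; limit ", x$limit, " (", x$context, ")\n", sep = "")
  tab <- table(factor(x$decisions$route,
                      levels = c("USE_MEAN", "USE_CYSTATIN", "USE_CREATININE",
                                 "GOLD_STANDARD_REQUIRED")))
  for (nm in names(tab)) cat(sprintf("  %-24s %d\n", nm, tab[[nm]]))
  if (x$n_failed > 0) cat("  failed records:", x$n_failed, "\n")
  invisible(x)
}

#' @export
as.data.frame.lund_gfr <- function(x, ...) x$decisions

#' @export
summary.lund_gfr <- function(object, ...) {
  d <- object$decisions
  ok <- !is.na(d$route)
  routes <- table(factor(d$route[ok],
                         levels = c("USE_MEAN", "USE_CYSTATIN",
                                    "USE_CREATININE", "GOLD_STANDARD_REQUIRED")))
  acc <- NULL
  have_ref <- ok & !is.na(d$final_estimate) & !is.na(d$measured_gfr)
  if (any(have_ref))
    acc <- accuracy_report(d$final_estimate[have_ref], d$measured_gfr[have_ref])
  structure(
    list(n = object$n, n_failed = object$n_failed, routes = routes,
         concordance_rate = mean(d$concordant[ok]),
         median_relative_difference = stats::median(d$relative_difference[ok]),
         limit = object$limit, context = object$context,
         accuracy_vs_measured = acc,
         cys_id = object$cys_id, crea_id = object$crea_id),
    class = "summary.lund_gfr"
  )
}

#' @export
print.summary.lund_gfr <- function(x, ...) {
  cat("Dual-marker GFR decision summary\n")
  cat("  equations: ", x$cys_id, " (cystatin C) + ", x$crea_id,
      " (creatinine)\n", sep = "")
  cat(sprintf("  agreement limit %.2f (%s context)\n", x$limit, x$context))
  cat(sprintf("  n = %d (%d failed)\n", x$n, x$n_failed))
  cat(sprintf("  concordance rate %.1f%%; median relative difference %.3f\n",
              100 * x$concordance_rate, x$median_relative_difference))
  cat("  routes:\n")
  for (nm in names(x$routes))
    cat(sprintf("    %-24s %d\n", nm, x$routes[[nm]]))
  if (!is.null(x$accuracy_vs_measured)) {
    cat("  accuracy of final estimates vs measured GFR:\n  ")
    print(x$accuracy_vs_measured)
  }
  invisible(x)
}

#' Plot the internal quality check
#'
#' Scatter of the creatinine-based versus cystatin C-based estimate, with
#' the identity line and the concordance band implied by the policy limit
#' (|a − b| / mean ≤ L corresponds to slopes (2−L)/(2+L) and (2+L)/(2−L)).
#' Points are coloured by route.
#'
#' @param x A [lund_gfr()] result.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.lund_gfr <- function(x, ...) {
  d <- x$decisions[!is.na(x$decisions$route), ]
  cols <- c(USE_MEAN = "#2b8cbe", USE_CYSTATIN = "#31a354",
            USE_CREATININE = "#d95f0e", GOLD_STANDARD_REQUIRED = "#de2d26")
  L <- x$limit
  lim <- range(c(d$e_cystatin, d$e_creatinine), na.rm = TRUE)
  graphics::plot(d$e_cystatin, d$e_creatinine, col = cols[d$route],
                 pch = 16, cex = 0.6, xlim = lim, ylim = lim,
                 xlab = "cystatin C-based eGFR (mL/min/1.73m2)",
                 ylab = "creatinine-based eGFR (mL/min/1.73m2)", ...)
  graphics::abline(0, 1, lty = 1, col = "grey40")
  graphics::abline(0, (2 - L) / (2 + L), lty = 2, col = "grey60")
  graphics::abline(0, (2 + L) / (2 - L), lty = 2, col = "grey60")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(x)
}
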