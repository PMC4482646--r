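#' @title Gestational-age dating from fetal biometry
#' @name dating
#' @description
#' Dating curves map a single fetal biometric (mm) to gestational age.
#' Coefficients live in a versioned YAML registry
#' (`inst/extdata/dating_formulas.yaml`), each entry carrying its citation,
#' functional form, output units and validity range, so the transcription
#' from the primary references is auditable and swappable. All curves are
#' strictly increasing over their validity range.
NULL

.pkg_cache <- new.env(parent = emptyenv())

#' Construct a dating formula
#'
#' @param name Identifier.
#' @param input_biometric One of `"crl_mm"`, `"hc_mm"`, `"bpd_mm"`.
#' @param type Functional form: `"sqrt_linear"` (`ga = b0 + b1*sqrt(x)`),
#'   `"log_cubic"` (`ga = exp(b0 + b1*x + b2*x^2 + b3*x^3)`) or
#'   `"quadratic_cm"` (`ga = b0 + b1*(x/10) + b2*(x/10)^2`).
#' @param coefficients Named list/vector of reals (`b0`, `b1`, ...).
#' @param output_units `"days"` or `"weeks"`.
#' @param valid_input_range Length-2 numeric, mm.
#' @param citation Free-text provenance of the coefficients.
#' @return Object of class `dating_formula`.
#' @export
dating_formula <- function(name, input_biometric, type, coefficients,
                           output_units = c("weeks", "days"),
                           valid_input_range, citation = "") {
  output_units <- match.arg(output_units)
  stopifnot(length(valid_input_range) == 2,
            valid_input_range[1] < valid_input_range[2])
  f <- structure(
    list(name = name, input_biometric = input_biometric, type = type,
         coefficients = as.list(coefficients), output_units = output_units,
         valid_input_range = as.numeric(valid_input_range),
         citation = citation),
    class = "dating_formula"
  )
  ends <- evaluate_dating(f, f$valid_input_range)
  if (!all(is.finite(ends)) || ends[1] >= ends[2]) {
    stop("dating formula '", name,
         "' is not finite and increasing over its validity range")
  }
  f
}

#' @export
print.dating_formula <- function(x, ...) {
  cat("<dating_formula> ", x$name, ": ", x$input_biometric, " ",
      x$valid_input_range[1], "-", x$valid_input_range[2],
      " mm -> GA (", x$output_units, ")\n  ", x$citation, "\n", sep = "")
  invisible(x)
}

.eval_curve <- function(f, x) {
  b <- f$coefficients
  switch(f$type,
    sqrt_linear = b$b0 + b$b1 * sqrt(x),
    log_cubic = exp(b$b0 + b$b1 * x + b$b2 * x^2 + b$b3 * x^3),
    quadratic_cm = {
      cm <- x / 10
      b$b0 + b$b1 * cm + b$b2 * cm^2
    },
    stop("unknown dating formula type: ", f$type)
  )
}

#' Evaluate a dating formula (always returns decimal weeks)
#'
#' @param formula A [dating_formula()].
#' @param x Biometric values, mm (no range check; see [ga_from_crl()] etc.
#'   for the range-checked user entry points).
#' @return GA in decimal weeks.
#' @export
evaluate_dating <- function(formula, x) {
  ga <- .eval_curve(formula, x)
  if (formula$output_units == "days") ga <- ga / 7 else ga
}

#' Invert a dating formula: biometric value at a given GA
#'
#' Closed-form for the sqrt-linear and quadratic forms; damped Newton on the
#' log-cubic form (monotone over the validity range, converges in a handful
#' of steps from a linear-interpolation start).
#'
#' @param formula A [dating_formula()].
#' @param ga_weeks GA in decimal weeks.
#' @return Biometric values in mm (may fall outside the validity range; the
#'   caller decides how to handle that).
#' @export
invert_dating <- function(formula, ga_weeks) {
  target <- if (formula$output_units == "days") ga_weeks * 7 else ga_weeks
  b <- formula$coefficients
  switch(formula$type,
    sqrt_linear = ((target - b$b0) / b$b1)^2,
    quadratic_cm = {
      disc <- b$b1^2 - 4 * b$b2 * (b$b0 - target)
      disc[disc < 0] <- NA_real_
      10 * (-b$b1 + sqrt(disc)) / (2 * b$b2)
    },
    log_cubic = {
      lt <- log(target)
      rng <- formula$valid_input_range
      grid <- seq(rng[1] - 40, rng[2] + 60, length.out = 400)
      gy <- b$b0 + b$b1 * grid + b$b2 * grid^2 + b$b3 * grid^3
      x <- stats::approx(gy, grid, xout = lt, rule = 2)$y
      for (i in seq_len(30)) {
        fx <- b$b0 + b$b1 * x + b$b2 * x^2 + b$b3 * x^3 - lt
        dfx <- b$b1 + 2 * b$b2 * x + 3 * b$b3 * x^2
        step <- fx / dfx
        x <- x - step
        if (max(abs(step)) < 1e-12) break
      }
      x
    },
    stop("unknown dating formula type: ", formula$type)
  )
}

#' Load the dating-formula registry
#'
#' @param path Optional path to a registry YAML; defaults to the registry
#'   shipped with the package.
#' @return Named list of [dating_formula()] objects.
#' @export
dating_formulas <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.pkg_cache$formulas)) return(.pkg_cache$formulas)
  if (default) {
    path <- system.file("extdata", "dating_formulas.yaml",
                        package = "gestagree", mustWork = TRUE)
  }
  reg <- yaml::read_yaml(path)
  out <- lapply(reg$formulas, function(e) {
    dating_formula(e$name, e$input_biometric, e$type, e$coefficients,
                   e$output_units, unlist(e$valid_input_range),
                   e$citation %||% "")
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  if (default) .pkg_cache$formulas <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_range <- function(x, formula, what) {
  rng <- formula$valid_input_range
  bad <- which(!is.na(x) & (x < rng[1] | x > rng[2]))
  if (length(bad) > 0) {
    stop(what, " value ", x[bad[1]], " mm outside the validity range ",
         rng[1], "-", rng[2], " mm of formula '", formula$name, "'")
  }
}

#' GA from crown-rump length (reference dating)
#'
#' @param crl_mm CRL in mm; must lie in the formula's validity range
#'   (10-80 mm for the default registry entry).
#' @param formula Dating formula; default is the registry's square-root CRL
#'   curve (output in days, converted to weeks).
#' @return GA in decimal weeks.
#' @examples
#' ga_from_crl(10) # ~7.03 weeks
#' @export
ga_from_crl <- function(crl_mm, formula = dating_formulas()$robinson_fleming_crl) {
  .check_range(crl_mm, formula, "CRL")
  evaluate_dating(formula, crl_mm)
}

#' GA from head circumference
#'
#' @param hc_mm HC in mm, within the formula's validity range.
#' @param formula Dating formula; default is the registry's log-cubic HC
#'   curve.
#' @return GA in decimal weeks.
#' @export
ga_from_hc <- function(hc_mm, formula = dating_formulas()$chitty_altman_hc) {
  .check_range(hc_mm, formula, "HC")
  evaluate_dating(formula, hc_mm)
}

#' GA from biparietal diameter
#'
#' @param bpd_mm BPD in mm, within the formula's validity range.
#' @param formula Dating formula; default is the registry's quadratic BPD
#'   curve.
#' @return GA in decimal weeks.
#' @export
ga_from_bpd <- function(bpd_mm, formula = dating_formulas()$hadlock_bpd) {
  .check_range(bpd_mm, formula, "BPD")
  evaluate_dating(formula, bpd_mm)
}

#' Default parameters of the serial-SFH dating model
#'
#' A synthetic population-specific model: expected fundal height is linear in
#' GA, `height_cm = intercept + slope * ga_weeks`, with independent
#' measurement noise. The published population-specific formula can be
#' substituted by passing different parameters (or a different `curve`
#' closure) to [ga_from_sfh()].
#'
#' @return List with `intercept` (cm), `slope` (cm/week) and `noise_sd` (cm).
#' @export
sfh_default_params <- function() {
  list(intercept = -2.0, slope = 1.0, noise_sd = 1.0)
}

#' Expected fundal height at a given GA
#'
#' @param ga_weeks GA in decimal weeks.
#' @param params See [sfh_default_params()].
#' @return Height in cm.
#' @export
sfh_height <- function(ga_weeks, params = sfh_default_params()) {
  params$intercept + params$slope * ga_weeks
}

#' GA from serial symphysis-fundal height measurements
#'
#' Requires at least three timed measurements; with fewer, dating is declared
#' insufficient rather than attempted. Under the linear height-GA model the
#' least-squares estimate of GA at the first measurement date is the mean of
#' the per-measurement implied GAs shifted back by the elapsed time.
#'
#' @param series `data.frame` (or list coercible to one) with columns `days`
#'   (days since the first SFH visit, non-decreasing, first element 0 by
#'   convention) and `height_cm`.
#' @param params SFH model parameters, see [sfh_default_params()].
#' @return GA in decimal weeks at the first measurement date, with attribute
#'   `status = "ok"`; or `NA` with `status = "insufficient"` when fewer than
#'   three measurements are available.
#' @export
ga_from_sfh <- function(series, params = sfh_default_params()) {
  series <- as.data.frame(series)
  if (nrow(series) < 3) {
    return(structure(NA_real_, status = "insufficient"))
  }
  if (is.unsorted(series$days, strictly = TRUE)) {
    stop("SFH measurement dates must be strictly increasing")
  }
  implied_ga0 <- (series$height_cm - params$intercept) / params$slope -
    series$days / 7
  structure(mean(implied_ga0), status = "ok")
}
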