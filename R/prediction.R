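#' @title The bias-and-LOA calculator
#' @name prediction
#' @description
#' Evaluates a fitted or published bias surface at given covariate values
#' and returns the mean bias with 95% limits of agreement,
#' `bias +/- 2 * SD`, where SD is the standard deviation of a single future
#' measurement's difference. Published parameter sets ship with the package
#' so the calculator works without refitting.
NULL

#' 95% limits of agreement around a bias
#'
#' @param bias Mean bias, weeks.
#' @param sd SD of a single-measurement difference, weeks (>= 0).
#' @param k Multiplier; the reported intervals use exactly 2.
#' @return Numeric `c(low, high)`.
#' @examples
#' loa_interval(2.57, 1.04) # c(0.49, 4.65)
#' @export
loa_interval <- function(bias, sd, k = 2) {
  if (any(sd < 0)) stop("sd must be non-negative")
  c(low = bias - k * sd, high = bias + k * sd)
}

#' Check covariates against a fit's observed ranges
#'
#' A surface should not be evaluated silently outside the covariate region
#' that produced it. Returns `TRUE`/`FALSE` with a `messages` attribute
#' naming each out-of-range covariate, and `NA` when the fit carries no
#' observed-range metadata.
#'
#' @param fit A [bias_fit()].
#' @param z,newborn_ga,ga_us Covariate values (ga_us only for fits with a
#'   scan-GA slope).
#' @return Logical scalar with attribute `messages`.
#' @export
check_observed_range <- function(fit, z, newborn_ga, ga_us = NULL) {
  rng <- fit$observed_range
  if (is.null(rng)) {
    return(structure(NA, messages = "fit carries no observed-range metadata"))
  }
  msgs <- character(0)
  chk <- function(val, r, name) {
    if (!is.null(r) && !is.null(val) && !is.na(val) &&
        (val < r[1] || val > r[2])) {
      sprintf("%s = %g outside observed range [%g, %g]", name, val, r[1], r[2])
    } else character(0)
  }
  msgs <- c(chk(z, rng$z, "z"),
            chk(newborn_ga, rng$newborn_ga, "newborn_ga"),
            chk(ga_us, rng$ga_us, "ga_us"))
  structure(length(msgs) == 0, messages = msgs)
}

#' Predict bias and 95% limits of agreement
#'
#' `bias = beta0 + beta1_z*(z - c_z) + beta2_ga*(newborn_ga - c_ga)
#' [+ beta3_us*(ga_us - c_us)]`, with LOA `bias +/- 2 * sd_single`.
#' Evaluation outside the fit's observed covariate range warns (never
#' silently extrapolates) and is flagged in the result.
#'
#' @param fit A [bias_fit()] -- fitted by this package or one of
#'   [published_fits()].
#' @param z Birthweight-for-GA Z-score.
#' @param newborn_ga Newborn GA, weeks.
#' @param ga_us Scan GA, weeks; required iff the fit has a `beta3_us` slope.
#' @return Object of class `agreement_estimate`: list with `method`,
#'   `bias_weeks`, `loa_low_weeks`, `loa_high_weeks`, `sd_weeks`, `inputs`,
#'   `in_observed_range`.
#' @examples
#' fits <- published_fits()
#' predict_bias(fits$hc, z = 0, newborn_ga = 34, ga_us = 25) # bias -1.77
#' @export
predict_bias <- function(fit, z, newborn_ga, ga_us = NULL) {
  co <- fit$coefficients
  has_us <- "beta3_us" %in% names(co)
  if (has_us && is.null(ga_us)) {
    stop("this ", fit$method, " fit requires ga_us (GA at ultrasound)")
  }
  cen <- fit$centering
  bias <- co[["beta0"]] +
    co[["beta1_z"]] * (z - cen$z) +
    co[["beta2_ga"]] * (newborn_ga - cen$newborn_ga)
  if (has_us) bias <- bias + co[["beta3_us"]] * (ga_us - cen$ga_us)
  loa <- loa_interval(bias, fit$sd_single)
  in_range <- check_observed_range(fit, z, newborn_ga,
                                   if (has_us) ga_us else NULL)
  if (isFALSE(in_range)) {
    warning("evaluating ", fit$method, " bias surface outside its observed ",
            "covariate range: ",
            paste(attr(in_range, "messages"), collapse = "; "))
  }
  structure(
    list(method = fit$method, bias_weeks = as.numeric(bias),
         loa_low_weeks = as.numeric(loa[["low"]]),
         loa_high_weeks = as.numeric(loa[["high"]]),
         sd_weeks = fit$sd_single,
         inputs = list(z = z, newborn_ga = newborn_ga, ga_us = ga_us),
         in_observed_range = as.logical(in_range),
         messages = attr(in_range, "messages")),
    class = "agreement_estimate")
}

#' @export
print.agreement_estimate <- function(x, ...) {
  cat(sprintf("%s vs CRL: bias %.2f weeks (95%% LOA: %.2f, %.2f)\n",
              x$method, x$bias_weeks, x$loa_low_weeks, x$loa_high_weeks))
  if (isFALSE(x$in_observed_range)) {
    cat("  [outside observed covariate range]\n")
  }
  invisible(x)
}

#' Published bias-surface parameter sets
#'
#' The parameter sets shipped with the package: the calculator
#' (method-covariate) surfaces for the newborn exam, serial SFH, HC and BPD
#' -- the form usable when no CRL dating exists -- plus the
#' reference-covariate surfaces at their reported anchor points, and the
#' malaria-unexposed sub-group surface. See
#' `inst/extdata/published_fits.json` for provenance notes.
#'
#' @param path Optional path to an alternative fixture file.
#' @return Named list of [bias_fit()] objects (`dubowitz`, `sfh`, `hc`,
#'   `bpd`, `dubowitz_crl`, `sfh_crl`, `hc_crl`, `hc_crl_late`, `bpd_crl`,
#'   `dubowitz_crl_subgroup`).
#' @export
published_fits <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.pkg_cache$published)) return(.pkg_cache$published)
  if (default) {
    path <- system.file("extdata", "published_fits.json",
                        package = "gestagree", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw$fits, function(e) {
    rng <- e$observed_range
    if (!is.null(rng)) rng <- lapply(rng, function(r) unlist(r))
    bias_fit(e$method, e$covariate_source,
             unlist(e$coefficients), e$centering, e$sd_single,
             n_women = e$n_women, observed_range = rng, design = e$design)
  })
  names(out) <- vapply(raw$fits, `[[`, character(1), "name")
  if (default) .pkg_cache$published <- out
  out
}
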