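#' @title Bias surfaces and limits of agreement on the difference scale
#' @name agreement
#' @description
#' The analysis target is the within-woman difference between an alternative
#' method's newborn GA and the CRL-derived newborn GA (positive = the method
#' overestimates). Bias surfaces are linear in birthweight-for-GA Z-score,
#' newborn GA (centred at 39 weeks) and, for antenatal biometry, scan GA
#' (centred at 25 weeks). Estimation is by closed-form moment steps on the
#' difference scale -- algebraically equivalent, for these paired and
#' balanced replicated designs, to the corresponding linear mixed-effects
#' model, and matching the "single future measurement" contract: for
#' duplicated measurements the reported SD is that of one future
#' measurement's difference, not of the average of two.
NULL

# method newborn-GA estimates, one row per (woman, replicate)
.method_newborn_ga <- function(records, method, sfh_params = sfh_default_params()) {
  n <- nrow(records)
  if (method == "dubowitz") {
    return(data.frame(woman_id = records$woman_id, replicate = 1L,
                      method_newborn_ga = records$dubowitz_ga_at_birth,
                      method_scan_ga = NA_real_))
  }
  if (method == "sfh") {
    ga <- vapply(seq_len(n), function(i) {
      s <- sfh_series(records[i, ])
      if (nrow(s) < 3 || is.na(records$sfh_days_to_birth[i])) return(NA_real_)
      est <- ga_from_sfh(s, sfh_params)
      as.numeric(est) + records$sfh_days_to_birth[i] / 7
    }, numeric(1))
    return(data.frame(woman_id = records$woman_id, replicate = 1L,
                      method_newborn_ga = ga, method_scan_ga = NA_real_))
  }
  if (!method %in% c("hc", "bpd")) stop("unknown method: ", method)
  date_fn <- switch(method, hc = ga_from_hc, bpd = ga_from_bpd)
  cols <- paste0(method, 1:2, "_mm")
  elapsed <- records$newborn_ga_crl - records$ga_at_study_scan
  do.call(rbind, lapply(1:2, function(k) {
    scan_ga <- rep(NA_real_, n)
    ok <- !is.na(records[[cols[k]]])
    scan_ga[ok] <- date_fn(records[[cols[k]]][ok])
    data.frame(woman_id = records$woman_id, replicate = k,
               method_newborn_ga = scan_ga + elapsed,
               method_scan_ga = scan_ga)
  }))
}

#' Build the within-woman difference table for one method
#'
#' One row per replicate measurement, carrying the difference
#' `method GA - CRL GA` (weeks) and the covariates of the bias surface. The
#' `covariate_source` toggle decides whether Z-score, newborn GA and scan GA
#' are computed from the reference CRL dating (`"crl"`) or from the
#' method's own GA estimates (`"method"`, the parameterization usable when
#' no CRL is available). Rows lacking the method's GA, the reference GA, or
#' the Z-score inputs are excluded; the count is logged in the
#' `n_dropped` attribute.
#'
#' @param records Cohort `data.frame`.
#' @param method `"dubowitz"`, `"sfh"`, `"hc"` or `"bpd"`.
#' @param covariate_source `"crl"` or `"method"`.
#' @param standard Growth standard used for the Z-scores.
#' @param sfh_params Serial-SFH model parameters.
#' @return A `difference_table`: `data.frame` with columns `woman_id`,
#'   `method`, `replicate`, `difference`, `z`, `newborn_ga`, `ga_us`,
#'   `covariate_source`.
#' @export
build_differences <- function(records, method,
                              covariate_source = c("crl", "method"),
                              standard = synthetic_growth_standard(),
                              sfh_params = sfh_default_params()) {
  covariate_source <- match.arg(covariate_source)
  est <- .method_newborn_ga(records, method, sfh_params)
  idx <- match(est$woman_id, records$woman_id)
  ref_ga <- records$newborn_ga_crl[idx]
  difference <- est$method_newborn_ga - ref_ga

  # per-woman method summaries for the method-covariate parameterization
  mean_by_woman <- tapply(est$method_newborn_ga, est$woman_id, mean)
  mean_scan_by_woman <- tapply(est$method_scan_ga, est$woman_id, mean)
  if (covariate_source == "crl") {
    newborn_ga <- ref_ga
    ga_us <- records$ga_at_study_scan[idx]
  } else {
    newborn_ga <- as.numeric(mean_by_woman[as.character(est$woman_id)])
    ga_us <- as.numeric(mean_scan_by_woman[as.character(est$woman_id)])
  }
  z <- zscore_birthweight(records$birthweight_g[idx], newborn_ga,
                          records$sex[idx], standard)
  tab <- data.frame(woman_id = est$woman_id, method = method,
                    replicate = est$replicate, difference = difference,
                    z = as.numeric(z), newborn_ga = newborn_ga, ga_us = ga_us,
                    covariate_source = covariate_source,
                    stringsAsFactors = FALSE)
  keep <- !is.na(tab$difference) & !is.na(ref_ga) & !is.na(tab$z)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("difference_table", "data.frame")
  out
}

.obs_range <- function(tab) {
  r <- list(z = range(tab$z), newborn_ga = range(tab$newborn_ga))
  if (!all(is.na(tab$ga_us))) r$ga_us <- range(tab$ga_us, na.rm = TRUE)
  r
}

#' Construct a bias-surface fit object
#'
#' Container for a fitted (or published) bias surface: intercept `beta0` at
#' the centering point, covariate slopes, the SD of a single-measurement
#' difference, and variance components. Used both by the fitting routines
#' and to hold published parameter sets for the calculator.
#'
#' @param method Method name.
#' @param covariate_source `"crl"` or `"method"`.
#' @param coefficients Named numeric: `beta0`, `beta1_z`, `beta2_ga` and
#'   optionally `beta3_us`.
#' @param centering List with `z`, `newborn_ga` and optionally `ga_us`.
#' @param sd_single SD (weeks) of a single future measurement's difference.
#' @param var_components Numeric `c(v_mean =, v_replicate =)`; must satisfy
#'   `sd_single^2 = v_mean + v_replicate/2`.
#' @param n_women Number of women behind the fit.
#' @param ses Optional named coefficient standard errors.
#' @param observed_range Optional list of observed covariate ranges
#'   (`z`, `newborn_ga`, `ga_us`) used by [check_observed_range()].
#' @param design `"single"` or `"replicated"`.
#' @return Object of class `bias_fit`.
#' @export
bias_fit <- function(method, covariate_source, coefficients, centering,
                     sd_single, var_components = NULL, n_women = NA_integer_,
                     ses = NULL, observed_range = NULL,
                     design = c("single", "replicated")) {
  design <- match.arg(design)
  stopifnot(sd_single >= 0,
            all(c("beta0", "beta1_z", "beta2_ga") %in% names(coefficients)))
  if (is.null(var_components)) {
    var_components <- c(v_mean = sd_single^2, v_replicate = 0)
  }
  stopifnot(abs(sd_single^2 -
                  (var_components[["v_mean"]] +
                     var_components[["v_replicate"]] / 2)) < 1e-8)
  structure(
    list(method = method, covariate_source = covariate_source,
         coefficients = unlist(coefficients), centering = centering,
         sd_single = sd_single, var_components = var_components,
         n_women = n_women, ses = ses, observed_range = observed_range,
         design = design),
    class = "bias_fit")
}

#' @export
print.bias_fit <- function(x, ...) {
  cat("<bias_fit> ", x$method, " vs CRL (", x$covariate_source,
      " covariates, ", x$design, " design, n = ", x$n_women, ")\n", sep = "")
  cat("  bias at centering point:", round(x$coefficients[["beta0"]], 3),
      "weeks;  SD(single difference):", round(x$sd_single, 3), "\n")
  sl <- x$coefficients[setdiff(names(x$coefficients), "beta0")]
  cat("  slopes:", paste(names(sl), round(sl, 3), sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Fit a bias surface for a single-measurement method
#'
#' Ordinary least squares of the one-per-woman difference on
#' `(z - c_z, newborn_ga - 39)`. The residual SD (denominator `n - p`) is
#' the SD of a single-measurement difference. For paired data this is the
#' same bias contrast a two-measurement mixed model with a woman random
#' effect estimates.
#'
#' @param table A [build_differences()] table with one row per woman.
#' @param centering Centering constants (`z`, `newborn_ga`).
#' @return A [bias_fit()].
#' @export
fit_bias_surface_single <- function(table,
                                    centering = list(z = 0, newborn_ga = 39)) {
  if (anyDuplicated(table$woman_id)) {
    stop("single-measurement fit requires one row per woman; ",
         "use fit_bias_surface_replicated() for duplicated measurements")
  }
  n <- nrow(table)
  if (n < 5) stop("insufficient data: need at least 5 women, have ", n)
  zc <- table$z - centering$z
  gac <- table$newborn_ga - centering$newborn_ga
  fit <- stats::lm(difference ~ zc + gac, data = table)
  sm <- summary(fit)
  co <- stats::coef(fit)
  names(co) <- c("beta0", "beta1_z", "beta2_ga")
  ses <- sm$coefficients[, "Std. Error"]
  names(ses) <- names(co)
  bias_fit(method = table$method[1], covariate_source = table$covariate_source[1],
           coefficients = co, centering = centering, sd_single = sm$sigma,
           var_components = c(v_mean = sm$sigma^2, v_replicate = 0),
           n_women = n, ses = ses, observed_range = .obs_range(table),
           design = "single")
}

#' Fit a bias surface for a duplicated-measurement method
#'
#' Three moment steps on the difference scale:
#' (i) OLS of the per-woman mean difference on
#' `(z - c_z, newborn_ga - 39, ga_us - 25)` gives the betas and the
#' mean-level residual variance `v_mean`;
#' (ii) the pooled within-woman replicate variance
#' `v_replicate = sum_i sum_k (d_ik - dbar_i)^2 / sum_i (m_i - 1)`;
#' (iii) `sd_single = sqrt(v_mean + v_replicate / 2)`, the SD of a *single*
#' future measurement's difference (the `- v_replicate/2` inside `v_mean`
#' is the averaging gain of the duplicate, which a single measurement does
#' not enjoy). On balanced data the betas equal those of the REML fit of
#' the stacked mixed model with a woman-by-method random effect.
#'
#' @param table A [build_differences()] table with exactly two replicates
#'   per woman.
#' @param centering Centering constants (`z`, `newborn_ga`, `ga_us`).
#' @return A [bias_fit()].
#' @export
fit_bias_surface_replicated <- function(table,
                                        centering = list(z = 0, newborn_ga = 39,
                                                         ga_us = 25)) {
  m_i <- table(table$woman_id)
  bad <- names(m_i)[m_i != 2]
  if (length(bad) > 0) {
    stop("replicated fit requires exactly 2 replicates per woman; offending ",
         "woman ids: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  ord <- order(table$woman_id, table$replicate)
  tab <- table[ord, ]
  agg <- stats::aggregate(
    cbind(difference, z, newborn_ga, ga_us) ~ woman_id, data = tab, FUN = mean)
  n <- nrow(agg)
  if (n < 6) stop("insufficient data: need at least 6 women, have ", n)
  zc <- agg$z - centering$z
  gac <- agg$newborn_ga - centering$newborn_ga
  usc <- agg$ga_us - centering$ga_us
  fit <- stats::lm(agg$difference ~ zc + gac + usc)
  sm <- summary(fit)
  co <- stats::coef(fit)
  names(co) <- c("beta0", "beta1_z", "beta2_ga", "beta3_us")
  ses <- sm$coefficients[, "Std. Error"]
  names(ses) <- names(co)
  dbar <- stats::setNames(agg$difference, agg$woman_id)
  dev <- tab$difference - dbar[as.character(tab$woman_id)]
  v_rep <- sum(dev^2) / sum(m_i - 1)
  v_mean <- sm$sigma^2
  bias_fit(method = tab$method[1], covariate_source = tab$covariate_source[1],
           coefficients = co, centering = centering,
           sd_single = sqrt(v_mean + v_rep / 2),
           var_components = c(v_mean = v_mean, v_replicate = v_rep),
           n_women = n, ses = ses, observed_range = .obs_range(tab),
           design = "replicated")
}

.lrt_formula <- function(terms, centering) {
  rhs <- c("1",
           if ("z" %in% terms) sprintf("I(z - %g)", centering$z),
           if ("newborn_ga" %in% terms)
             sprintf("I(newborn_ga - %g)", centering$newborn_ga),
           if ("ga_us" %in% terms)
             sprintf("I(ga_us - %g)", centering$ga_us %||% 25))
  stats::as.formula(paste("difference ~", paste(rhs, collapse = " + ")))
}

#' Likelihood-ratio test for bias-surface interaction terms
#'
#' Compares nested Gaussian models of the difference scale (per-woman means
#' when replicates are present): `2 * (logLik_full - logLik_reduced)`
#' referred to a chi-square with degrees of freedom equal to the number of
#' added terms. Log-likelihoods are maximum-likelihood (not REML), as
#' required for comparing mean structures.
#'
#' @param table A [build_differences()] table.
#' @param full_terms Character subset of `c("z", "newborn_ga", "ga_us")`.
#' @param reduced_terms Subset of `full_terms`.
#' @param centering Centering constants.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
interaction_lrt <- function(table, full_terms, reduced_terms = character(0),
                            centering = list(z = 0, newborn_ga = 39, ga_us = 25)) {
  allowed <- c("z", "newborn_ga", "ga_us")
  stopifnot(all(full_terms %in% allowed), all(reduced_terms %in% allowed))
  if (!all(reduced_terms %in% full_terms)) {
    stop("models are not nested: reduced terms must be a subset of full terms")
  }
  dat <- as.data.frame(table)
  if (anyDuplicated(dat$woman_id)) {
    dat <- stats::aggregate(
      cbind(difference, z, newborn_ga, ga_us) ~ woman_id, data = dat, FUN = mean)
  }
  df <- length(setdiff(full_terms, reduced_terms))
  if (df == 0) return(list(statistic = 0, df = 0L, p_value = 1.0))
  ll_full <- stats::logLik(stats::lm(.lrt_formula(full_terms, centering), dat))
  ll_red <- stats::logLik(stats::lm(.lrt_formula(reduced_terms, centering), dat))
  stat <- as.numeric(2 * (ll_full - ll_red))
  list(statistic = stat, df = as.integer(df),
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Serialise a bias fit to JSON
#'
#' @param fit A [bias_fit()].
#' @param path Output path.
#' @param provenance Optional named list (seed, input hash, ...) stored
#'   alongside the fit; the package version is always included.
#' @return `path`, invisibly.
#' @export
write_bias_fit <- function(fit, path, provenance = list()) {
  provenance$package_version <- as.character(utils::packageVersion("gestagree"))
  x <- unclass(fit)
  # keep names through JSON: named vectors go out as objects, not arrays
  x$coefficients <- as.list(x$coefficients)
  x$var_components <- as.list(x$var_components)
  if (!is.null(x$ses)) x$ses <- as.list(x$ses)
  x$provenance <- provenance
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a bias fit from JSON
#'
#' @param path Path written by [write_bias_fit()].
#' @return A [bias_fit()].
#' @export
read_bias_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rng <- x$observed_range
  if (!is.null(rng)) rng <- lapply(rng, unlist)
  bias_fit(x$method, x$covariate_source, unlist(x$coefficients),
           as.list(x$centering), x$sd_single, unlist(x$var_components),
           x$n_women, unlist(x$ses), rng, x$design)
}
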