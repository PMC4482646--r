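#' @title Preterm classification agreement
#' @name classification
#' @description
#' Agreement between an alternative method and CRL dating in classifying
#' preterm birth (GA < 37 weeks), with CRL as the reference standard:
#' 2x2 contingency tables, percent agreement, Cohen's kappa, sensitivity
#' and specificity with exact (Clopper-Pearson) intervals, and the
#' misclassification rates the biases induce. Also provides an
#' integer-feasibility reconstruction of a 2x2 table from published
#' marginals and rounded percentages.
NULL

#' 2x2 contingency table of preterm classification
#'
#' @param tp,fp,fn,tn Non-negative counts; reference (CRL) status in
#'   columns of the implied table, test method in rows: `tp` = both
#'   preterm, `fp` = method preterm / reference term, `fn` = method term /
#'   reference preterm, `tn` = both term.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), n = sum(counts), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(reference = c("preterm", "term"),
                              test = c("preterm", "term")))
  print(m)
  invisible(x)
}

#' Round half away from zero
#'
#' Report tables print integer percentages rounded half-up (0.5 -> 1),
#' not banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build the preterm 2x2 table for one method
#'
#' Preterm is GA < 37 weeks on both axes. For duplicated HC/BPD
#' measurements the method classification uses the *average* of the two
#' replicate-derived newborn GA estimates. Records missing either
#' classification are excluded and counted in the `n_excluded` attribute.
#'
#' @param records Cohort `data.frame`.
#' @param method `"dubowitz"`, `"sfh"`, `"hc"` or `"bpd"`.
#' @param cutoff_weeks Preterm cut-off (default 37).
#' @param sfh_params Serial-SFH model parameters.
#' @return A [contingency_2x2()].
#' @export
build_preterm_table <- function(records, method, cutoff_weeks = 37,
                                sfh_params = sfh_default_params()) {
  est <- .method_newborn_ga(records, method, sfh_params)
  mean_ga <- tapply(est$method_newborn_ga, est$woman_id, mean)
  method_ga <- as.numeric(mean_ga[records$woman_id])
  ref_ga <- records$newborn_ga_crl
  ok <- !is.na(method_ga) & !is.na(ref_ga)
  test_pre <- method_ga[ok] < cutoff_weeks
  ref_pre <- ref_ga[ok] < cutoff_weeks
  out <- contingency_2x2(tp = sum(test_pre & ref_pre),
                         fp = sum(test_pre & !ref_pre),
                         fn = sum(!test_pre & ref_pre),
                         tn = sum(!test_pre & !ref_pre))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement. Degenerate marginals (`p_e = 1`)
#' yield `NA`.
#'
#' @param tab A [contingency_2x2()].
#' @return Numeric kappa in [-1, 1], or `NA`.
#' @export
kappa_statistic <- function(tab) {
  n <- attr(tab, "n")
  if (n == 0) stop("empty table")
  po <- (tab$tp + tab$tn) / n
  pe <- ((tab$tp + tab$fn) / n) * ((tab$tp + tab$fp) / n) +
    ((tab$fp + tab$tn) / n) * ((tab$fn + tab$tn) / n)
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Percent agreement
#'
#' @param tab A [contingency_2x2()].
#' @return Percent of concordant classifications.
#' @export
percent_agreement <- function(tab) {
  100 * (tab$tp + tab$tn) / attr(tab, "n")
}

#' Sensitivity and specificity with exact binomial intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, each with a
#' Clopper-Pearson 95% CI, as percentages. `display` carries the
#' half-up-rounded integers used in report tables.
#'
#' @param tab A [contingency_2x2()].
#' @return List with `sensitivity_pct`, `sensitivity_ci`,
#'   `specificity_pct`, `specificity_ci` (percent scale) and `display`.
#' @export
sens_spec <- function(tab) {
  if (tab$tp + tab$fn == 0 || tab$fp + tab$tn == 0) {
    stop("empty reference margin: sensitivity/specificity undefined")
  }
  se <- stats::binom.test(tab$tp, tab$tp + tab$fn)
  sp <- stats::binom.test(tab$tn, tab$fp + tab$tn)
  sens <- 100 * tab$tp / (tab$tp + tab$fn)
  spec <- 100 * tab$tn / (tab$fp + tab$tn)
  list(
    sensitivity_pct = sens,
    sensitivity_ci = 100 * as.numeric(se$conf.int),
    specificity_pct = spec,
    specificity_ci = 100 * as.numeric(sp$conf.int),
    display = c(sensitivity = round_half_up(sens),
                specificity = round_half_up(spec))
  )
}

#' Misclassification rates
#'
#' The two clinically meaningful error rates: preterm newborns classified
#' term (`fn / (tp + fn)`) and term newborns classified preterm
#' (`fp / (fp + tn)`), as percentages.
#'
#' @param tab A [contingency_2x2()].
#' @return Named numeric `c(preterm_as_term, term_as_preterm)`.
#' @export
misclassification_rates <- function(tab) {
  if (tab$tp + tab$fn == 0 || tab$fp + tab$tn == 0) {
    stop("empty reference margin: misclassification rates undefined")
  }
  c(preterm_as_term = 100 * tab$fn / (tab$tp + tab$fn),
    term_as_preterm = 100 * tab$fp / (tab$fp + tab$tn))
}

#' Reconstruct a 2x2 table from published marginals
#'
#' Given a report row's total `n`, reference-positive and test-positive
#' counts, and the printed integer sensitivity and specificity, enumerates
#' every integer-feasible `tp` and keeps those whose implied sensitivity
#' and specificity both round (half-up) to the printed values. Exactly one
#' solution must survive; zero or several raise an error listing the
#' candidates.
#'
#' @param n Total count.
#' @param ref_positive Reference-positive (preterm by CRL) count.
#' @param test_positive Test-positive count.
#' @param printed_sens_pct,printed_spec_pct Printed integer percentages.
#' @return A [contingency_2x2()].
#' @examples
#' reconstruct_from_marginals(250, 70, 45, 61, 99)
#' @export
reconstruct_from_marginals <- function(n, ref_positive, test_positive,
                                       printed_sens_pct, printed_spec_pct) {
  stopifnot(ref_positive >= 0, ref_positive <= n,
            test_positive >= 0, test_positive <= n)
  tp_range <- seq(max(0, ref_positive + test_positive - n),
                  min(ref_positive, test_positive))
  cand <- list()
  for (tp in tp_range) {
    fp <- test_positive - tp
    fn <- ref_positive - tp
    tn <- n - tp - fp - fn
    sens <- 100 * tp / ref_positive
    spec <- 100 * tn / (fp + tn)
    if (isTRUE(round_half_up(sens) == printed_sens_pct) &&
        isTRUE(round_half_up(spec) == printed_spec_pct)) {
      cand[[length(cand) + 1]] <- contingency_2x2(tp, fp, fn, tn)
    }
  }
  if (length(cand) == 0) {
    stop("no integer table is consistent with the printed marginals and ",
         "percentages")
  }
  if (length(cand) > 1) {
    tps <- vapply(cand, function(x) x$tp, numeric(1))
    stop("ambiguous reconstruction: ", length(cand),
         " feasible tables (tp = ", paste(tps, collapse = ", "), ")")
  }
  cand[[1]]
}

#' Classification report table
#'
#' One row per method, mirroring the columns of the published agreement
#' table: preterm count and percent, kappa, sensitivity and specificity
#' with exact CIs (displayed as half-up-rounded integers).
#'
#' @param records Cohort `data.frame`.
#' @param methods Character vector of methods.
#' @param sfh_params Serial-SFH model parameters.
#' @return `data.frame` with a leading reference (CRL) row.
#' @export
classification_report <- function(records, methods,
                                  sfh_params = sfh_default_params()) {
  ref_pre <- sum(records$newborn_ga_crl < 37, na.rm = TRUE)
  n_all <- sum(!is.na(records$newborn_ga_crl))
  rows <- list(data.frame(
    method = "crl", n = n_all, preterm_n = ref_pre,
    preterm_pct = round_half_up(100 * ref_pre / n_all),
    kappa = NA_real_, sensitivity = NA_real_, sens_lo = NA_real_,
    sens_hi = NA_real_, specificity = NA_real_, spec_lo = NA_real_,
    spec_hi = NA_real_))
  for (m in methods) {
    tab <- build_preterm_table(records, m, sfh_params = sfh_params)
    ss <- sens_spec(tab)
    n_m <- attr(tab, "n")
    rows[[length(rows) + 1]] <- data.frame(
      method = m, n = n_m, preterm_n = tab$tp + tab$fp,
      preterm_pct = round_half_up(100 * (tab$tp + tab$fp) / n_m),
      kappa = round(kappa_statistic(tab), 2),
      sensitivity = ss$display[["sensitivity"]],
      sens_lo = round_half_up(ss$sensitivity_ci[1]),
      sens_hi = round_half_up(ss$sensitivity_ci[2]),
      specificity = ss$display[["specificity"]],
      spec_lo = round_half_up(ss$specificity_ci[1]),
      spec_hi = round_half_up(ss$specificity_ci[2]))
  }
  do.call(rbind, rows)
}
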