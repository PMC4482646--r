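#' @title Birthweight-for-GA standards, Z-scores and maturity classification
#' @name growth_standards
NULL

#' Construct a birthweight-for-GA growth standard
#'
#' @param name Identifier.
#' @param median_fn Function `(ga_weeks, sex)` returning the median
#'   birthweight in grams.
#' @param spread_fn Function `(ga_weeks, sex)` returning the SD-equivalent
#'   spread in grams.
#' @param valid_ga_range Length-2 numeric, weeks; Z-scores outside it are
#'   reported missing rather than extrapolated.
#' @return Object of class `growth_standard`.
#' @export
growth_standard <- function(name, median_fn, spread_fn, valid_ga_range) {
  stopifnot(is.function(median_fn), is.function(spread_fn),
            length(valid_ga_range) == 2,
            valid_ga_range[1] < valid_ga_range[2])
  grid <- seq(valid_ga_range[1], valid_ga_range[2], length.out = 100)
  for (sx in c("female", "male")) {
    med <- median_fn(grid, sx)
    if (any(med <= 0) || any(diff(med) <= 0)) {
      stop("growth standard median must be positive and increasing in GA")
    }
  }
  structure(list(name = name, median_fn = median_fn, spread_fn = spread_fn,
                 valid_ga_range = as.numeric(valid_ga_range)),
            class = "growth_standard")
}

# log-quadratic median weight curve; sex ratio multiplicative
.synth_median <- function(ga_weeks, sex) {
  base <- exp(0.578 + 0.332 * ga_weeks - 0.00354 * ga_weeks^2)
  mult <- ifelse(sex == "male", 1.03, ifelse(sex == "female", 0.97, 1.0))
  base * mult
}

.synth_spread <- function(ga_weeks, sex) {
  0.11 * .synth_median(ga_weeks, sex)
}

#' Synthetic default growth standard
#'
#' A documented stand-in standard so the package works with no external
#' coefficient download: a log-quadratic median weight curve (about 1200 g
#' at 28 weeks, 3600 g at 40 weeks), a 3% sex offset, and an 11%
#' coefficient-of-variation spread, valid over 24-43 weeks. International
#' centile coefficients can be supplied through [growth_standard()].
#'
#' @return A `growth_standard`.
#' @export
synthetic_growth_standard <- function() {
  if (is.null(.pkg_cache$standard)) {
    .pkg_cache$standard <- growth_standard(
      "synthetic_lognormalish", .synth_median, .synth_spread, c(24, 43))
  }
  .pkg_cache$standard
}

#' Birthweight-for-GA Z-score
#'
#' `Z = (weight - median(ga, sex)) / spread(ga, sex)`. GAs outside the
#' standard's validity range yield `NA` with attribute
#' `reason = "ga_out_of_standard_range"`, mirroring how cohort reports count
#' missing Z-scores rather than extrapolating the standard.
#'
#' @param weight_g Birthweight in grams.
#' @param ga_weeks GA at birth in decimal weeks.
#' @param sex `"female"`, `"male"` or `"unknown"` (recycled).
#' @param standard A [growth_standard()]; default [synthetic_growth_standard()].
#' @return Numeric Z-scores (unitless).
#' @export
zscore_birthweight <- function(weight_g, ga_weeks, sex = "unknown",
                               standard = synthetic_growth_standard()) {
  n <- max(length(weight_g), length(ga_weeks), length(sex))
  weight_g <- rep_len(weight_g, n)
  ga_weeks <- rep_len(ga_weeks, n)
  sex <- rep_len(sex, n)
  rng <- standard$valid_ga_range
  ok <- !is.na(ga_weeks) & ga_weeks >= rng[1] & ga_weeks <= rng[2] &
    !is.na(weight_g)
  z <- rep(NA_real_, n)
  if (any(ok)) {
    z[ok] <- (weight_g[ok] - standard$median_fn(ga_weeks[ok], sex[ok])) /
      standard$spread_fn(ga_weeks[ok], sex[ok])
  }
  out_of_range <- !is.na(ga_weeks) & !(ga_weeks >= rng[1] & ga_weeks <= rng[2])
  if (any(out_of_range)) attr(z, "reason") <- "ga_out_of_standard_range"
  z
}

#' Small-for-gestational-age classification
#'
#' SGA is a birthweight-for-GA Z-score strictly below -1.28, i.e. below the
#' 10th centile of a normal standard.
#'
#' @param z Z-scores.
#' @return Logical; `NA` where `z` is missing.
#' @export
classify_sga <- function(z) {
  ifelse(is.na(z), NA, z < -1.28)
}

#' Maturity category at birth
#'
#' Cut-offs: very preterm < 34 weeks; preterm 34 to <37; term 37 to <42;
#' post-term >= 42. The preterm-vs-term binarisation used in classification
#' analyses is GA < 37 weeks.
#'
#' @param ga_weeks GA at birth, decimal weeks (> 0).
#' @return Factor with levels `very_preterm`, `preterm`, `term`, `post_term`.
#' @export
classify_maturity <- function(ga_weeks) {
  stopifnot(all(is.na(ga_weeks) | ga_weeks > 0))
  cut(ga_weeks, breaks = c(0, 34, 37, 42, Inf), right = FALSE,
      labels = c("very_preterm", "preterm", "term", "post_term"))
}
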