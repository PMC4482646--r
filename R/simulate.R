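#' @title Synthetic obstetric cohort generator
#' @name synthetic_cohorts
#' @description
#' Generates cohorts with the statistical structure the agreement analysis
#' assumes: a per-method bias surface in birthweight-for-GA Z-score, newborn
#' GA and (for antenatal biometry) GA at the study scan, a woman-by-method
#' random effect, and method-specific replicate residuals. Truth is defined
#' on the CRL scale: the reference newborn GA *is* the CRL-derived GA, so a
#' generated "bias" is bias relative to CRL dating -- the analysis target.
#' Biometric mm values are obtained by inverting the dating curves at the
#' noised scan GA, so re-dating a generated measurement reproduces it.
NULL

#' Default generative bias surfaces
#'
#' Per-method linear bias surfaces (weeks), centred at Z 0, newborn GA 39
#' weeks and scan GA 25 weeks. Defaults are the fitted surfaces of the study
#' population this package models: the newborn-exam and serial-SFH surfaces
#' in their reference-covariate form, the HC/BPD surfaces in their
#' method-covariate (calculator) form.
#'
#' @return Named list (`dubowitz`, `sfh`, `hc`, `bpd`) of lists with
#'   `beta0`, `beta1_z`, `beta2_ga`, `beta3_us` (weeks, weeks/unit,
#'   weeks/week, weeks/week).
#' @export
default_bias_surfaces <- function() {
  list(
    dubowitz = list(beta0 = 0.82, beta1_z = 0.40, beta2_ga = -0.35, beta3_us = 0),
    sfh      = list(beta0 = 0.84, beta1_z = 0.16, beta2_ga = -0.62, beta3_us = 0),
    hc       = list(beta0 = -0.37, beta1_z = -0.07, beta2_ga = 0.28, beta3_us = -0.07),
    bpd      = list(beta0 = 0.39, beta1_z = -0.11, beta2_ga = 0.30, beta3_us = -0.02)
  )
}

#' Default generative variance components
#'
#' Woman-by-method and replicate-residual SDs (weeks). For the replicated
#' biometry methods the single-measurement difference SD is
#' `sqrt(woman^2 + residual^2)`: HC `sqrt(0.50^2 + 0.4755^2) = 0.69`,
#' BPD `sqrt(0.55^2 + 0.48^2) = 0.73`. Single-measurement methods carry the
#' whole SD in the woman component (1.04 newborn exam, 0.72 serial SFH).
#'
#' @return Named list of `c(woman_by_method_sd =, residual_sd =)`.
#' @export
default_variance_components <- function() {
  list(
    dubowitz = c(woman_by_method_sd = 1.04, residual_sd = 0),
    sfh      = c(woman_by_method_sd = 0.72, residual_sd = 0),
    hc       = c(woman_by_method_sd = 0.50, residual_sd = 0.4755),
    bpd      = c(woman_by_method_sd = 0.55, residual_sd = 0.48)
  )
}

#' Simulation configuration
#'
#' @param cohort `"biometry"` (prospective; one study scan at 16-40 weeks
#'   with HC and BPD each measured twice, serial SFH for a subset) or
#'   `"dubowitz"` (newborn exam within 72 h; pre-/post-term oversampled).
#' @param n_women Cohort size; defaults 975 (biometry) / 250 (dubowitz).
#' @param seed Integer seed; recorded in the output.
#' @param oversample_extremes_fraction Fraction of the dubowitz cohort drawn
#'   from the pre-term (<37 weeks) / post-term (>=42 weeks) strata
#'   (default 0.30 there, 0 for the prospective cohort).
#' @param true_ga Truncated-normal parameters of true newborn GA,
#'   `list(mean, sd, min, max)` in weeks; default N(39, 1.5) on [28, 44.4].
#' @param scan_ga_range Uniform bounds of the study-scan GA, weeks.
#' @param centering Centering constants of the bias surfaces,
#'   `list(z, newborn_ga, ga_us)`.
#' @param bias Per-method bias surfaces, see [default_bias_surfaces()].
#' @param varcomp Per-method variance components, see
#'   [default_variance_components()].
#' @param sfh_model Serial-SFH growth-curve parameters,
#'   see [sfh_default_params()].
#' @param sfh_available_fraction Fraction of the biometry cohort with a
#'   usable (>= 3 measurement) SFH series; default 704/975.
#' @param malaria_prevalence Bernoulli malaria-exposure probability
#'   (default 0.21 dubowitz cohort, 0 biometry cohort).
#' @param max_resample Rounds of scan-time resampling allowed before the
#'   generator gives up (scan must precede birth and the noised scan GA must
#'   stay invertible through the dating curves).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(cohort = c("biometry", "dubowitz"),
                       n_women = NULL,
                       seed = NULL,
                       oversample_extremes_fraction = NULL,
                       true_ga = list(mean = 39, sd = 1.5, min = 28, max = 44.4),
                       scan_ga_range = c(16, 40),
                       centering = list(z = 0, newborn_ga = 39, ga_us = 25),
                       bias = default_bias_surfaces(),
                       varcomp = default_variance_components(),
                       sfh_model = sfh_default_params(),
                       sfh_available_fraction = NULL,
                       malaria_prevalence = NULL,
                       max_resample = 100) {
  cohort <- match.arg(cohort)
  n_women <- n_women %||% switch(cohort, biometry = 975, dubowitz = 250)
  oversample_extremes_fraction <- oversample_extremes_fraction %||%
    switch(cohort, biometry = 0, dubowitz = 0.30)
  sfh_available_fraction <- sfh_available_fraction %||%
    switch(cohort, biometry = 704 / 975, dubowitz = 0)
  malaria_prevalence <- malaria_prevalence %||%
    switch(cohort, biometry = 0, dubowitz = 0.21)
  stopifnot(
    n_women >= 1,
    oversample_extremes_fraction >= 0, oversample_extremes_fraction <= 1,
    sfh_available_fraction >= 0, sfh_available_fraction <= 1,
    malaria_prevalence >= 0, malaria_prevalence <= 1,
    true_ga$sd >= 0, true_ga$min < true_ga$max,
    scan_ga_range[1] < scan_ga_range[2],
    all(vapply(varcomp, function(v) all(v >= 0), logical(1))),
    sfh_model$noise_sd >= 0
  )
  structure(
    list(cohort = cohort, n_women = as.integer(n_women), seed = seed,
         oversample_extremes_fraction = oversample_extremes_fraction,
         true_ga = true_ga, scan_ga_range = as.numeric(scan_ga_range),
         centering = centering, bias = bias, varcomp = varcomp,
         sfh_model = sfh_model,
         sfh_available_fraction = sfh_available_fraction,
         malaria_prevalence = malaria_prevalence,
         max_resample = max_resample),
    class = "sim_config")
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# truth draws restricted to the pre-/post-term region (or its complement)
.rtrunc_norm_region <- function(n, mean, sd, lo, hi, extreme) {
  p <- function(x) stats::pnorm(x, mean, sd)
  q <- function(u) stats::qnorm(u, mean, sd)
  pre <- c(lo, min(37, hi)); post <- c(max(42, lo), hi)
  if (extreme) {
    m1 <- max(0, p(pre[2]) - p(pre[1]))
    m2 <- max(0, p(post[2]) - p(post[1]))
    if (m1 + m2 < 1e-12) {
      stop("infeasible oversampling: the configured true-GA distribution ",
           "puts no mass on the pre-/post-term region")
    }
    u <- stats::runif(n, 0, m1 + m2)
    ifelse(u < m1, q(p(pre[1]) + u), q(p(post[1]) + (u - m1)))
  } else {
    lo2 <- max(lo, 37); hi2 <- min(hi, 42 - 1e-9)
    if (p(hi2) - p(lo2) < 1e-12) {
      stop("infeasible sampling: no mass on the term region")
    }
    q(stats::runif(n, p(lo2), p(hi2)))
  }
}

.bias_at <- function(surface, centering, z, newborn_ga, ga_us = NULL) {
  b <- surface$beta0 +
    surface$beta1_z * (z - centering$z) +
    surface$beta2_ga * (newborn_ga - centering$newborn_ga)
  if (!is.null(ga_us) && !is.null(surface$beta3_us)) {
    b <- b + surface$beta3_us * (ga_us - centering$ga_us)
  }
  b
}

#' Draw per-method measurements from true gestational ages
#'
#' The generative contract: a method's GA estimate equals true GA plus the
#' bias surface at the woman's covariates, plus a woman-by-method effect,
#' plus an independent residual per replicate. For HC/BPD the estimate lives
#' at the scan (`ga_us + delta`) and the biometric mm value is the dating
#' curve's inverse at that noised scan GA, so re-dating reproduces it;
#' noised GAs falling outside a curve's validity range yield `NA` mm and are
#' counted in the `n_out_of_validity` attribute (the cohort generator
#' resamples scan times instead).
#'
#' @param true_ga Vector of true (CRL-scale) newborn GAs, weeks.
#' @param config A [sim_config()].
#' @param z Birthweight-for-GA Z-scores (recycled).
#' @param ga_us Scan GAs in weeks, or `NULL` to skip the biometry methods.
#' @return A `data.frame` with per-method deltas (method GA minus true GA),
#'   newborn GA estimates, and -- when `ga_us` is given -- the replicate
#'   scan-GA estimates and biometric values `hc1_mm`, `hc2_mm`, `bpd1_mm`,
#'   `bpd2_mm`. Uses the current RNG stream.
#' @export
measurements_from_truth <- function(true_ga, config, z = 0, ga_us = NULL) {
  n <- length(true_ga)
  z <- rep_len(z, n)
  cen <- config$centering
  draw_delta <- function(method, n_rep) {
    vc <- config$varcomp[[method]]
    u <- stats::rnorm(n, 0, vc[["woman_by_method_sd"]])
    d <- matrix(NA_real_, n, n_rep)
    for (k in seq_len(n_rep)) {
      d[, k] <- .bias_at(config$bias[[method]], cen, z, true_ga,
                         if (method %in% c("hc", "bpd")) ga_us) +
        u + stats::rnorm(n, 0, vc[["residual_sd"]])
    }
    d
  }
  out <- data.frame(true_ga = true_ga, z = z)
  d_dub <- draw_delta("dubowitz", 1)
  d_sfh <- draw_delta("sfh", 1)
  out$delta_dubowitz <- d_dub[, 1]
  out$dubowitz_ga <- true_ga + d_dub[, 1]
  out$delta_sfh <- d_sfh[, 1]
  out$sfh_ga <- true_ga + d_sfh[, 1]
  n_invalid <- 0
  if (!is.null(ga_us)) {
    ga_us <- rep_len(ga_us, n)
    out$ga_us <- ga_us
    fml <- dating_formulas()
    for (m in c("hc", "bpd")) {
      f <- switch(m, hc = fml$chitty_altman_hc, bpd = fml$hadlock_bpd)
      ga_ok <- evaluate_dating(f, f$valid_input_range)
      d <- draw_delta(m, 2)
      for (k in 1:2) {
        g <- ga_us + d[, k]
        mm <- invert_dating(f, g)
        bad <- g < ga_ok[1] | g > ga_ok[2]
        mm[bad] <- NA_real_
        n_invalid <- n_invalid + sum(bad)
        out[[paste0("delta_", m, k)]] <- d[, k]
        out[[paste0("scan_ga_", m, k)]] <- g
        out[[paste0(m, k, "_mm")]] <- mm
      }
    }
  }
  attr(out, "n_out_of_validity") <- n_invalid
  out
}

#' Simulate a cohort
#'
#' Deterministic given `config$seed`: one seeded generator drives every
#' draw, and the seed is recorded in the result's `seed` attribute. For the
#' dubowitz cohort, `round(n * oversample_extremes_fraction)` records are
#' drawn from the pre-/post-term strata (by inverse-CDF sampling of the
#' truncated truth distribution restricted to that region) and the rest from
#' the term stratum, so the realised extreme fraction matches the
#' configuration up to integer rounding.
#'
#' @param config A [sim_config()].
#' @return Cohort `data.frame` in the [cohort_schema()] layout, with
#'   attributes `seed` and `n_scan_resampled` (scan-time redraws needed to
#'   keep biometrics invertible and scans before birth).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_women
  tg <- config$true_ga
  cen <- config$centering

  if (config$cohort == "dubowitz" && config$oversample_extremes_fraction > 0) {
    n_ext <- round(n * config$oversample_extremes_fraction)
    t_ext <- .rtrunc_norm_region(n_ext, tg$mean, tg$sd, tg$min, tg$max, TRUE)
    t_term <- .rtrunc_norm_region(n - n_ext, tg$mean, tg$sd, tg$min, tg$max, FALSE)
    true_ga <- c(t_ext, t_term)
    stratum <- c(rep("extreme", n_ext), rep("term", n - n_ext))
  } else {
    true_ga <- .rtrunc_norm(n, tg$mean, tg$sd, tg$min, tg$max)
    stratum <- rep("prospective", n)
  }

  sex <- sample(c("female", "male"), n, replace = TRUE)
  malaria <- stats::runif(n) < config$malaria_prevalence
  z <- stats::rnorm(n)
  weight <- .synth_median(true_ga, sex) + z * .synth_spread(true_ga, sex)

  fml <- dating_formulas()
  rf <- fml$robinson_fleming_crl
  crl_ga_rng <- evaluate_dating(
    rf, if (config$cohort == "dubowitz") c(10, 41) else c(10, 80))
  ga_at_crl <- stats::runif(n, crl_ga_rng[1] + 1e-6, crl_ga_rng[2] - 1e-6)
  crl_mm <- invert_dating(rf, ga_at_crl)

  rec <- data.frame(
    woman_id = sprintf("W%05d", seq_len(n)),
    cohort = config$cohort,
    crl_mm = crl_mm, ga_at_crl_scan = ga_at_crl,
    hc1_mm = NA_real_, hc2_mm = NA_real_,
    bpd1_mm = NA_real_, bpd2_mm = NA_real_,
    ga_at_study_scan = NA_real_,
    sfh_days = "", sfh_cm = "", sfh_days_to_birth = NA_real_,
    dubowitz_ga_at_birth = NA_real_,
    newborn_ga_crl = true_ga,
    birthweight_g = weight, sex = sex, malaria_exposed = malaria,
    sampling_stratum = stratum,
    stringsAsFactors = FALSE
  )
  n_resampled <- 0

  if (config$cohort == "dubowitz") {
    vc <- config$varcomp$dubowitz
    delta <- .bias_at(config$bias$dubowitz, cen, z, true_ga) +
      stats::rnorm(n, 0, vc[["woman_by_method_sd"]]) +
      stats::rnorm(n, 0, vc[["residual_sd"]])
    rec$dubowitz_ga_at_birth <- true_ga + delta
  } else {
    u_hc <- stats::rnorm(n, 0, config$varcomp$hc[["woman_by_method_sd"]])
    u_bpd <- stats::rnorm(n, 0, config$varcomp$bpd[["woman_by_method_sd"]])
    hc_f <- fml$chitty_altman_hc
    bpd_f <- fml$hadlock_bpd
    hc_ok <- evaluate_dating(hc_f, hc_f$valid_input_range)
    bpd_ok <- evaluate_dating(bpd_f, bpd_f$valid_input_range)
    lo <- config$scan_ga_range[1]; hi <- config$scan_ga_range[2]

    ga_us <- rep(NA_real_, n)
    g_hc <- matrix(NA_real_, n, 2)
    g_bpd <- matrix(NA_real_, n, 2)
    todo <- seq_len(n)
    for (round_i in seq_len(config$max_resample)) {
      if (length(todo) == 0) break
      m <- length(todo)
      u <- stats::runif(m, lo, hi)
      bh <- .bias_at(config$bias$hc, cen, z[todo], true_ga[todo], u)
      bb <- .bias_at(config$bias$bpd, cen, z[todo], true_ga[todo], u)
      gh <- cbind(u + bh + u_hc[todo] +
                    stats::rnorm(m, 0, config$varcomp$hc[["residual_sd"]]),
                  u + bh + u_hc[todo] +
                    stats::rnorm(m, 0, config$varcomp$hc[["residual_sd"]]))
      gb <- cbind(u + bb + u_bpd[todo] +
                    stats::rnorm(m, 0, config$varcomp$bpd[["residual_sd"]]),
                  u + bb + u_bpd[todo] +
                    stats::rnorm(m, 0, config$varcomp$bpd[["residual_sd"]]))
      ok <- u < true_ga[todo] - 0.5 &
        gh[, 1] > hc_ok[1] & gh[, 1] < hc_ok[2] &
        gh[, 2] > hc_ok[1] & gh[, 2] < hc_ok[2] &
        gb[, 1] > bpd_ok[1] & gb[, 1] < bpd_ok[2] &
        gb[, 2] > bpd_ok[1] & gb[, 2] < bpd_ok[2]
      keep <- todo[ok]
      ga_us[keep] <- u[ok]
      g_hc[keep, ] <- gh[ok, , drop = FALSE]
      g_bpd[keep, ] <- gb[ok, , drop = FALSE]
      n_resampled <- n_resampled + sum(!ok)
      todo <- todo[!ok]
    }
    if (length(todo) > 0) {
      stop("could not place a valid study scan for ", length(todo),
           " women within ", config$max_resample, " resampling rounds")
    }
    rec$ga_at_study_scan <- ga_us
    rec$hc1_mm <- invert_dating(hc_f, g_hc[, 1])
    rec$hc2_mm <- invert_dating(hc_f, g_hc[, 2])
    rec$bpd1_mm <- invert_dating(bpd_f, g_bpd[, 1])
    rec$bpd2_mm <- invert_dating(bpd_f, g_bpd[, 2])

    # serial SFH for the available subset
    avail <- stats::runif(n) < config$sfh_available_fraction
    if (any(avail)) {
      vc_s <- config$varcomp$sfh
      delta_sfh <- .bias_at(config$bias$sfh, cen, z, true_ga) +
        stats::rnorm(n, 0, vc_s[["woman_by_method_sd"]])
      sp <- config$sfh_model
      for (i in which(avail)) {
        first_ga <- stats::runif(1, 16, 19)
        visits <- seq(first_ga, true_ga[i] - 1, by = 3)
        visits <- visits[seq_len(min(length(visits), 8))]
        if (length(visits) < 3) next
        heights <- sfh_height(visits + delta_sfh[i], sp) +
          stats::rnorm(length(visits), 0, sp$noise_sd)
        rec$sfh_days[i] <- paste(round((visits - first_ga) * 7), collapse = ";")
        rec$sfh_cm[i] <- paste(sprintf("%.2f", heights), collapse = ";")
        rec$sfh_days_to_birth[i] <- round((true_ga[i] - first_ga) * 7)
      }
    }
  }

  attr(rec, "seed") <- config$seed
  attr(rec, "n_scan_resampled") <- n_resampled
  rec
}
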