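test_that("the dubowitz-cohort generator realises the configured extreme fraction exactly", {
  cfg <- sim_config("dubowitz", n_women = 250,
                    oversample_extremes_fraction = 0.30, seed = 1)
  rec <- simulate_cohort(cfg)
  extreme <- rec$newborn_ga_crl < 37 | rec$newborn_ga_crl >= 42
  expect_equal(sum(extreme), 75)
  expect_equal(sum(rec$sampling_stratum == "extreme"), 75)
  # the strata are label-consistent
  expect_true(all(extreme == (rec$sampling_stratum == "extreme")))
})

test_that("infeasible oversampling raises an explicit error", {
  cfg <- sim_config("dubowitz", n_women = 50, seed = 2,
                    true_ga = list(mean = 39, sd = 0.2, min = 38, max = 41))
  expect_error(simulate_cohort(cfg), "infeasible oversampling")
})

test_that("simulation is deterministic given the seed, to the CSV byte level", {
  cfg <- sim_config("biometry", n_women = 40, seed = 99)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(cfg), f1)
  write_cohort(simulate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the draw
  cfg2 <- sim_config("biometry", n_women = 40, seed = 100)
  f3 <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(cfg2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

zero_noise_config <- function(cohort, n, seed) {
  zero_surface <- list(beta0 = 0, beta1_z = 0, beta2_ga = 0, beta3_us = 0)
  sim_config(cohort, n_women = n, seed = seed,
             bias = list(dubowitz = zero_surface, sfh = zero_surface,
                         hc = zero_surface, bpd = zero_surface),
             varcomp = list(dubowitz = c(woman_by_method_sd = 0, residual_sd = 0),
                            sfh = c(woman_by_method_sd = 0, residual_sd = 0),
                            hc = c(woman_by_method_sd = 0, residual_sd = 0),
                            bpd = c(woman_by_method_sd = 0, residual_sd = 0)))
}

test_that("with zero noise and zero bias every method reproduces the CRL GA", {
  rec <- simulate_cohort(zero_noise_config("dubowitz", 30, 5))
  expect_equal(rec$dubowitz_ga_at_birth, rec$newborn_ga_crl, tolerance = 1e-12)

  recb <- simulate_cohort(zero_noise_config("biometry", 30, 5))
  for (m in c("hc", "bpd")) {
    tab <- build_differences(recb, m, "crl")
    expect_lt(max(abs(tab$difference)), 1e-6)
  }
  # replicates are identical when the residual SD is zero
  expect_equal(recb$hc1_mm, recb$hc2_mm, tolerance = 1e-9)
  expect_equal(recb$bpd1_mm, recb$bpd2_mm, tolerance = 1e-9)
})

test_that("measurements_from_truth applies the configured bias surface exactly at zero noise", {
  cfg <- zero_noise_config("biometry", 1, 1)
  cfg$bias$dubowitz <- list(beta0 = 1.0, beta1_z = 0, beta2_ga = 0, beta3_us = 0)
  set.seed(3)
  m <- measurements_from_truth(c(34, 39, 42), cfg)
  expect_equal(m$delta_dubowitz, c(1, 1, 1))
  expect_equal(m$dubowitz_ga, c(35, 40, 43))
  expect_equal(m$delta_sfh, c(0, 0, 0))
})

test_that("generated single-measurement differences hit the configured surface and variance", {
  # Monte-Carlo oracle at the centering point: mean single-measurement HC
  # difference should equal the configured centred bias (-0.37)
  cfg <- sim_config("biometry", n_women = 1, seed = 1)
  set.seed(202)
  n <- 50000
  m <- measurements_from_truth(rep(39, n), cfg, z = 0, ga_us = rep(25, n))
  expect_equal(mean(m$delta_hc1), -0.37, tolerance = 0.01)
  # and the single-measurement variance matches the configured SD^2
  # (chi-square 99% envelope at n draws)
  v <- var(m$delta_hc1)
  env <- 0.69^2 * qchisq(c(0.005, 0.995), n - 1) / (n - 1)
  expect_gte(v, env[1])
  expect_lte(v, env[2])
  # replicate pairs differ only through the residual component
  v_rep <- mean((m$delta_hc1 - m$delta_hc2)^2) / 2
  env_rep <- 0.4755^2 * qchisq(c(0.005, 0.995), n) / n
  expect_gte(v_rep, env_rep[1])
  expect_lte(v_rep, env_rep[2])
})

test_that("simulated cohorts satisfy the cohort invariants", {
  rec <- simulate_cohort(sim_config("biometry", n_women = 120, seed = 8))
  rep <- validate_inclusion(rec, "biometry")
  expect_equal(rep$n_rejected, 0)
  expect_true(all(rec$ga_at_study_scan >= 16 & rec$ga_at_study_scan <= 40))
  expect_true(all(rec$crl_mm >= 10 & rec$crl_mm <= 80))
  expect_true(all(!is.na(rec$hc1_mm) & !is.na(rec$hc2_mm) &
                    !is.na(rec$bpd1_mm) & !is.na(rec$bpd2_mm)))
  expect_true(all(rec$ga_at_study_scan < rec$newborn_ga_crl))

  red <- simulate_cohort(sim_config("dubowitz", n_women = 60, seed = 8))
  repd <- validate_inclusion(red, "dubowitz")
  expect_equal(repd$n_rejected, 0)
  expect_true(all(red$crl_mm >= 10 & red$crl_mm <= 41))
})

test_that("the SFH subset carries at least three timed measurements", {
  rec <- simulate_cohort(sim_config("biometry", n_women = 80, seed = 21))
  has_sfh <- rec$sfh_days != ""
  expect_gt(sum(has_sfh), 0)
  for (i in which(has_sfh)) {
    s <- sfh_series(rec[i, ])
    expect_gte(nrow(s), 3)
    expect_true(!is.unsorted(s$days, strictly = TRUE))
  }
})
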