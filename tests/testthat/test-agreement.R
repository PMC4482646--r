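test_that("difference tables carry method-minus-CRL differences with declared covariates", {
  rec <- dubowitz_cohort_fixture(10, offset = 0)
  tab <- build_differences(rec, "dubowitz", "crl")
  expect_equal(tab$difference, rep(0, 10))
  expect_s3_class(tab, "difference_table")

  rec2 <- dubowitz_cohort_fixture(10, offset = 1.5)
  crl_tab <- build_differences(rec2, "dubowitz", "crl")
  met_tab <- build_differences(rec2, "dubowitz", "method")
  expect_equal(crl_tab$difference, met_tab$difference)
  # covariates computed from the method's own GA differ whenever GAs differ
  expect_true(all(met_tab$newborn_ga == crl_tab$newborn_ga + 1.5))
  expect_true(all(met_tab$z != crl_tab$z))
})

test_that("replicated methods contribute two rows per woman", {
  rec <- simulate_cohort(sim_config("biometry", n_women = 60, seed = 31))
  tab <- build_differences(rec, "hc", "crl")
  counts <- table(tab$woman_id)
  expect_true(all(counts == 2))
  expect_equal(nrow(tab) + attr(tab, "n_dropped"), 2 * 60)
})

test_that("a constant difference fits as pure intercept with zero residual SD", {
  tab <- difference_table_fixture(sprintf("W%02d", 1:10),
                                  difference = rep(0.7, 10),
                                  z = rnorm(10), newborn_ga = runif(10, 34, 42),
                                  method = "dubowitz")
  fit <- suppressWarnings(fit_bias_surface_single(tab)) # zero-residual lm
  expect_equal(unname(fit$coefficients["beta0"]), 0.7)
  expect_equal(unname(fit$coefficients["beta1_z"]), 0, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["beta2_ga"]), 0, tolerance = 1e-12)
  expect_equal(fit$sd_single, 0, tolerance = 1e-10)
})

test_that("the single-measurement fit equals the normal-equations oracle", {
  set.seed(77)
  n <- 10
  tab <- difference_table_fixture(sprintf("W%02d", 1:n),
                                  difference = rnorm(n, 1, 0.8),
                                  z = rnorm(n), newborn_ga = runif(n, 32, 42),
                                  method = "dubowitz")
  fit <- fit_bias_surface_single(tab)
  X <- cbind(1, tab$z, tab$newborn_ga - 39)
  beta <- solve(crossprod(X), crossprod(X, tab$difference))
  res <- tab$difference - X %*% beta
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
  expect_equal(fit$sd_single, sqrt(sum(res^2) / (n - 3)), tolerance = 1e-8)
})

test_that("identical replicates collapse to the single-measurement fit", {
  set.seed(12)
  n <- 12
  d <- rnorm(n, 0.5, 0.6)
  z <- rnorm(n); ga <- runif(n, 33, 42); us <- runif(n, 16, 40)
  one <- difference_table_fixture(sprintf("W%02d", 1:n), d, z, ga, us)
  two <- difference_table_fixture(rep(sprintf("W%02d", 1:n), each = 2),
                                  rep(d, each = 2), rep(z, each = 2),
                                  rep(ga, each = 2), rep(us, each = 2),
                                  replicate = rep(1:2, n))
  fit2 <- fit_bias_surface_replicated(two)
  expect_equal(unname(fit2$var_components[["v_replicate"]]), 0)
  # degenerate replicates: sd_single equals the residual SD of the mean fit
  ols <- lm(d ~ I(z) + I(ga - 39) + I(us - 25))
  expect_equal(fit2$sd_single, summary(ols)$sigma, tolerance = 1e-10)
  expect_equal(unname(fit2$coefficients), unname(coef(ols)), tolerance = 1e-10)
})

test_that("the pooled replicate variance follows its hand-computed value", {
  # six women, replicate deviations +/-0.2 about each woman's mean:
  # v_replicate = sum(0.08)/sum(m-1) = 0.08, sd_single = sqrt(0 + 0.08/2)
  n <- 6
  set.seed(9)
  z <- rnorm(n)
  ga <- runif(n, 34, 42)
  us <- runif(n, 16, 40)
  tab <- difference_table_fixture(rep(sprintf("W%02d", 1:n), each = 2),
                                  rep(1.0, 2 * n) + rep(c(0.2, -0.2), n),
                                  rep(z, each = 2), rep(ga, each = 2),
                                  rep(us, each = 2),
                                  replicate = rep(1:2, n))
  fit <- suppressWarnings(fit_bias_surface_replicated(tab)) # zero-residual lm
  expect_equal(unname(fit$var_components[["v_replicate"]]), 0.08)
  expect_equal(unname(fit$var_components[["v_mean"]]), 0, tolerance = 1e-12)
  expect_equal(fit$sd_single, sqrt(0.04))
  expect_error(
    fit_bias_surface_replicated(tab[-1, , drop = FALSE]),
    "exactly 2 replicates")
})

test_that("simulated newborn-exam cohorts recover the generative surface", {
  cfg <- sim_config("dubowitz", n_women = 250, seed = 1001)
  rec <- simulate_cohort(cfg)
  fit <- fit_bias_surface_single(build_differences(rec, "dubowitz", "crl"))
  truth <- c(beta0 = 0.82, beta1_z = 0.40, beta2_ga = -0.35)
  for (nm in names(truth)) {
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]) / fit$ses[[nm]], 3,
              label = nm)
  }
  expect_equal(fit$sd_single, 1.04, tolerance = 0.1)
})

test_that("simulated duplicated-biometry cohorts recover surface and single-measurement SD", {
  cfg <- sim_config("biometry", n_women = 975, seed = 1002,
                    sfh_available_fraction = 0)
  rec <- simulate_cohort(cfg)
  fit <- fit_bias_surface_replicated(build_differences(rec, "hc", "crl"))
  truth <- c(beta0 = -0.37, beta1_z = -0.07, beta2_ga = 0.28, beta3_us = -0.07)
  for (nm in names(truth)) {
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]) / fit$ses[[nm]], 3,
              label = nm)
  }
  expect_lt(abs(fit$sd_single - 0.69) / 0.69, 0.10)
})

test_that("sd_single is invariant to re-centering while beta0 shifts linearly", {
  set.seed(55)
  n <- 40
  tab <- difference_table_fixture(sprintf("W%02d", 1:n),
                                  rnorm(n, 1, 0.5), rnorm(n),
                                  runif(n, 32, 42), method = "dubowitz")
  f39 <- fit_bias_surface_single(tab, centering = list(z = 0, newborn_ga = 39))
  f34 <- fit_bias_surface_single(tab, centering = list(z = 0, newborn_ga = 34))
  expect_equal(f39$sd_single, f34$sd_single, tolerance = 1e-12)
  expect_equal(f34$coefficients[["beta0"]],
               f39$coefficients[["beta0"]] - 5 * f39$coefficients[["beta2_ga"]],
               tolerance = 1e-10)
  expect_equal(f34$coefficients[["beta1_z"]], f39$coefficients[["beta1_z"]],
               tolerance = 1e-12)
})

test_that("interaction LRT degenerates and rejects as it should", {
  set.seed(66)
  n <- 100
  tab <- difference_table_fixture(sprintf("W%03d", 1:n),
                                  rnorm(n, 1, 0.5), rnorm(n),
                                  runif(n, 32, 42), method = "dubowitz")
  same <- interaction_lrt(tab, c("z", "newborn_ga"), c("z", "newborn_ga"))
  expect_equal(same$p_value, 1.0)
  expect_equal(same$statistic, 0)
  expect_error(interaction_lrt(tab, "z", "newborn_ga"), "not nested")

  # a true Z-slope of 0.40 at n=250 is detected at p < 0.001 essentially always
  set.seed(67)
  hits <- replicate(200, {
    z <- rnorm(250); ga <- runif(250, 32, 42)
    d <- 0.82 + 0.40 * z - 0.35 * (ga - 39) + rnorm(250, 0, 1.04)
    t2 <- difference_table_fixture(sprintf("W%03d", 1:250), d, z, ga,
                                   method = "dubowitz")
    interaction_lrt(t2, c("z", "newborn_ga"), "newborn_ga")$p_value < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("bias fits serialise to JSON and back unchanged", {
  set.seed(91)
  n <- 20
  tab <- difference_table_fixture(sprintf("W%02d", 1:n),
                                  rnorm(n, 0.5), rnorm(n), runif(n, 33, 42),
                                  method = "dubowitz")
  fit <- fit_bias_surface_single(tab)
  f <- tempfile(fileext = ".json")
  write_bias_fit(fit, f, provenance = list(seed = 91))
  back <- read_bias_fit(f)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$sd_single, fit$sd_single)
  expect_equal(back$var_components, fit$var_components)
  expect_equal(back$observed_range, fit$observed_range)
})
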