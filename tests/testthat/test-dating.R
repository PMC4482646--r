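test_that("CRL dating matches its documented anchor points", {
  # 10 mm ~ 7+0 weeks, 41 mm ~ 10+6 weeks, 80 mm ~ 13+6 weeks
  expect_gte(ga_from_crl(10), 7.0)
  expect_lt(ga_from_crl(10), 7.2)
  expect_gte(ga_from_crl(41), 10.5)
  expect_lt(ga_from_crl(41), 11.0)
  expect_gte(ga_from_crl(80), 13.0)
  expect_lt(ga_from_crl(80), 14.0)
  # frozen transcription checks (evaluated independently from the registry)
  expect_equal(ga_from_crl(10), 7.027523, tolerance = 1e-6)
  expect_equal(ga_from_hc(175), 20.0443, tolerance = 1e-4)
  expect_equal(ga_from_bpd(50), 21.14, tolerance = 1e-10)
})

test_that("all dating curves are strictly increasing over their validity range", {
  for (f in dating_formulas()) {
    grid <- seq(f$valid_input_range[1], f$valid_input_range[2],
                length.out = 500)
    ga <- evaluate_dating(f, grid)
    expect_true(all(is.finite(ga)), label = f$name)
    expect_true(all(diff(ga) > 0), label = f$name)
  }
})

test_that("dating curves invert to the measured biometric", {
  fml <- dating_formulas()
  for (nm in names(fml)) {
    f <- fml[[nm]]
    ga_mid <- evaluate_dating(f, mean(f$valid_input_range))
    expect_equal(evaluate_dating(f, invert_dating(f, ga_mid)), ga_mid,
                 tolerance = 1e-9, label = nm)
  }
  expect_equal(ga_from_hc(invert_dating(fml$chitty_altman_hc, 20)), 20,
               tolerance = 1e-9)
})

test_that("out-of-range biometrics raise errors naming the bound", {
  expect_error(ga_from_crl(85), "10-80")
  expect_error(ga_from_crl(5), "10-80")
  expect_error(ga_from_hc(30), "validity range")
  expect_error(ga_from_bpd(200), "validity range")
})

test_that("serial SFH dating needs three measurements and is self-inverse on clean data", {
  two <- data.frame(days = c(0, 21), height_cm = c(25, 28))
  est <- ga_from_sfh(two)
  expect_true(is.na(est))
  expect_identical(attr(est, "status"), "insufficient")

  p <- sfh_default_params()
  ga0 <- 30
  days <- c(0, 21, 42)
  clean <- data.frame(days = days,
                      height_cm = sfh_height(ga0 + days / 7, p))
  expect_equal(as.numeric(ga_from_sfh(clean, p)), 30, tolerance = 1e-10)

  expect_error(ga_from_sfh(data.frame(days = c(0, 21, 21),
                                      height_cm = c(25, 27, 28))),
               "strictly increasing")
})

test_that("noisy five-point SFH series date within 2 weeks for 95% of pregnancies", {
  set.seed(401)
  p <- sfh_default_params()
  n_sim <- 2000
  days <- seq(0, 84, by = 21)
  err <- replicate(n_sim, {
    ga0 <- runif(1, 22, 32)
    s <- data.frame(days = days,
                    height_cm = sfh_height(ga0 + days / 7, p) +
                      rnorm(length(days), 0, p$noise_sd))
    as.numeric(ga_from_sfh(s, p)) - ga0
  })
  expect_gte(mean(abs(err) <= 2), 0.95)
})

test_that("birthweight Z-scores are affine in weight with the documented anchors", {
  std <- synthetic_growth_standard()
  med <- std$median_fn(39, "female")
  spr <- std$spread_fn(39, "female")
  expect_equal(zscore_birthweight(med, 39, "female"), 0)
  expect_equal(zscore_birthweight(med + 2 * spr, 39, "female"), 2)
  # affine in weight at fixed (GA, sex)
  w <- seq(1500, 4500, length.out = 7)
  z <- zscore_birthweight(w, 39, "male")
  expect_equal(diff(z) / diff(w), rep(1 / std$spread_fn(39, "male"), 6))
  # out-of-range GA: missing with a reason, never extrapolated
  z_out <- zscore_birthweight(3000, 45, "female")
  expect_true(is.na(z_out))
  expect_identical(attr(z_out, "reason"), "ga_out_of_standard_range")
})

test_that("the SGA threshold sits at the 10th centile of a normal standard", {
  # weight at the 10th centile has Z = qnorm(0.10) = -1.2816 < -1.28 -> SGA
  std <- synthetic_growth_standard()
  w10 <- std$median_fn(39, "male") + qnorm(0.10) * std$spread_fn(39, "male")
  expect_true(classify_sga(zscore_birthweight(w10, 39, "male")))
  # strict inequality at the printed threshold
  expect_true(classify_sga(-1.29))
  expect_false(classify_sga(-1.28))
  expect_false(classify_sga(0))
  expect_true(is.na(classify_sga(NA)))
})

test_that("maturity categories follow the printed cut-offs", {
  expect_equal(as.character(classify_maturity(c(33.9, 34, 36.99, 37, 41.99, 42))),
               c("very_preterm", "preterm", "preterm", "term", "term",
                 "post_term"))
  expect_error(classify_maturity(-1))
})

test_that("the growth standard constructor rejects non-increasing medians", {
  expect_error(growth_standard("bad", function(ga, sex) rep(3000, length(ga)),
                               function(ga, sex) rep(300, length(ga)),
                               c(24, 43)),
               "increasing")
})
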