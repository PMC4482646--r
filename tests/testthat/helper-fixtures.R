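# Fixtures are built in code at test time.

# blank cohort data.frame in the canonical schema
blank_cohort <- function(n) {
  if (n == 0) return(blank_cohort(1)[0, , drop = FALSE])
  data.frame(
    woman_id = sprintf("W%03d", seq_len(n)),
    cohort = "dubowitz",
    crl_mm = NA_real_, ga_at_crl_scan = NA_real_,
    hc1_mm = NA_real_, hc2_mm = NA_real_,
    bpd1_mm = NA_real_, bpd2_mm = NA_real_,
    ga_at_study_scan = NA_real_,
    sfh_days = "", sfh_cm = "", sfh_days_to_birth = NA_real_,
    dubowitz_ga_at_birth = NA_real_, newborn_ga_crl = NA_real_,
    birthweight_g = NA_real_, sex = "female", malaria_exposed = FALSE,
    sampling_stratum = NA_character_,
    stringsAsFactors = FALSE
  )
}

# birthweight hitting an exact Z under the synthetic standard
weight_at_z <- function(z, ga, sex = "female",
                        standard = synthetic_growth_standard()) {
  standard$median_fn(ga, sex) + z * standard$spread_fn(ga, sex)
}

# a small newborn-exam cohort where the exam GA is truth plus a known offset
dubowitz_cohort_fixture <- function(n = 10, offset = 0, z = 0) {
  rec <- blank_cohort(n)
  rec$crl_mm <- 30
  rec$ga_at_crl_scan <- ga_from_crl(30)
  rec$newborn_ga_crl <- seq(34, 41, length.out = n)
  rec$dubowitz_ga_at_birth <- rec$newborn_ga_crl + offset
  rec$birthweight_g <- weight_at_z(z, rec$newborn_ga_crl, rec$sex)
  rec
}

# difference table built directly (bypassing record plumbing)
difference_table_fixture <- function(woman_id, difference, z, newborn_ga,
                                     ga_us = NA_real_, replicate = 1L,
                                     method = "hc",
                                     covariate_source = "crl") {
  out <- data.frame(woman_id = woman_id, method = method,
                    replicate = replicate, difference = difference,
                    z = z, newborn_ga = newborn_ga, ga_us = ga_us,
                    covariate_source = covariate_source,
                    stringsAsFactors = FALSE)
  class(out) <- c("difference_table", "data.frame")
  out
}
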