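{
  "comment": "Published bias-surface parameter sets for the gestational-age agreement calculator. Bias sign convention: positive = method overestimates GA relative to CRL dating. Bias = beta0 + beta1_z*(z - c_z) + beta2_ga*(newborn_ga - c_ga) [+ beta3_us*(ga_us - c_us)]; 95% LOA = bias +/- 2*sd_single. Fits with covariate_source 'method' take covariates computed from the alternative method's own GA estimate (the form usable without CRL); fits with covariate_source 'crl' take CRL-derived covariates and are anchored at the evaluation points at which they were reported.",
  "fits": [
    {
      "name": "dubowitz",
      "method": "dubowitz",
      "covariate_source": "method",
      "design": "single",
      "coefficients": { "beta0": 0.52, "beta1_z": -0.29, "beta2_ga": 0.08 },
      "centering": { "z": 0, "newborn_ga": 39 },
      "sd_single": 1.34,
      "n_women": 250,
      "observed_range": { "z": [-3.0, 1.3], "newborn_ga": [32, 42] }
    },
    {
      "name": "sfh",
      "method": "sfh",
      "covariate_source": "method",
      "design": "single",
      "coefficients": { "beta0": 0.16, "beta1_z": -0.35, "beta2_ga": 0.20 },
      "centering": { "z": 0, "newborn_ga": 39 },
      "sd_single": 1.06,
      "n_women": 704,
      "observed_range": { "z": [-3.0, 3.2], "newborn_ga": [33, 42] }
    },
    {
      "name": "hc",
      "method": "hc",
      "covariate_source": "method",
      "design": "replicated",
      "coefficients": { "beta0": -0.37, "beta1_z": -0.07, "beta2_ga": 0.28, "beta3_us": -0.07 },
      "centering": { "z": 0, "newborn_ga": 39, "ga_us": 25 },
      "sd_single": 0.69,
      "n_women": 975,
      "observed_range": { "z": [-3.0, 3.0], "newborn_ga": [28, 42], "ga_us": [16, 40] }
    },
    {
      "name": "bpd",
      "method": "bpd",
      "covariate_source": "method",
      "design": "replicated",
      "coefficients": { "beta0": 0.39, "beta1_z": -0.11, "beta2_ga": 0.30, "beta3_us": -0.02 },
      "centering": { "z": 0, "newborn_ga": 39, "ga_us": 25 },
      "sd_single": 0.73,
      "n_women": 975,
      "observed_range": { "z": [-3.0, 2.2], "newborn_ga": [28, 42], "ga_us": [16, 40] }
    },
    {
      "name": "dubowitz_crl",
      "method": "dubowitz",
      "covariate_source": "crl",
      "design": "single",
      "coefficients": { "beta0": 2.57, "beta1_z": 0.40, "beta2_ga": -0.35 },
      "centering": { "z": 0, "newborn_ga": 34 },
      "sd_single": 1.04,
      "n_women": 250,
      "note": "anchored at newborn GA 34 weeks, Z 0"
    },
    {
      "name": "sfh_crl",
      "method": "sfh",
      "covariate_source": "crl",
      "design": "single",
      "coefficients": { "beta0": 3.94, "beta1_z": 0.16, "beta2_ga": -0.62 },
      "centering": { "z": 0, "newborn_ga": 34 },
      "sd_single": 0.72,
      "n_women": 704,
      "note": "anchored at newborn GA 34 weeks, Z 0"
    },
    {
      "name": "hc_crl",
      "method": "hc",
      "covariate_source": "crl",
      "design": "replicated",
      "coefficients": { "beta0": 0.75, "beta1_z": 0.23, "beta2_ga": 0.0, "beta3_us": -0.11 },
      "centering": { "z": 0, "newborn_ga": 39, "ga_us": 16 },
      "sd_single": 0.73,
      "n_women": 975,
      "note": "anchored at measurement 16 weeks; newborn-GA modification reported as not clinically significant and omitted"
    },
    {
      "name": "hc_crl_late",
      "method": "hc",
      "covariate_source": "crl",
      "design": "replicated",
      "coefficients": { "beta0": -1.81, "beta1_z": 0.23, "beta2_ga": 0.0 },
      "centering": { "z": 0, "newborn_ga": 39 },
      "sd_single": 0.73,
      "n_women": 975,
      "note": "anchored at measurement 40 weeks (late-measurement form)"
    },
    {
      "name": "bpd_crl",
      "method": "bpd",
      "covariate_source": "crl",
      "design": "replicated",
      "coefficients": { "beta0": 0.96, "beta1_z": 0.26, "beta2_ga": 0.0 },
      "centering": { "z": 0, "newborn_ga": 39 },
      "sd_single": 0.85,
      "n_women": 975,
      "note": "gestation time of measurement did not modify BPD agreement in the CRL-covariate form"
    },
    {
      "name": "dubowitz_crl_subgroup",
      "method": "dubowitz",
      "covariate_source": "crl",
      "design": "single",
      "coefficients": { "beta0": 1.02, "beta1_z": 0.47, "beta2_ga": -0.52 },
      "centering": { "z": 0, "newborn_ga": 39 },
      "sd_single": 0.87,
      "n_women": 147,
      "note": "malaria-unexposed, no extreme oversampling"
    }
  ]
}
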