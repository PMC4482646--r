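---
title: "Quantifying agreement between gestational-age estimation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying agreement between gestational-age estimation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestagree)
```

## The problem

Crown-rump length (CRL) measured by first-trimester ultrasound is the
reference method for dating a pregnancy, but in resource-limited antenatal
settings -- and for women who first present late in pregnancy -- it is often
unavailable. Clinicians then fall back on a Dubowitz newborn examination, a
serial symphysis-fundal height (SFH) formula, or second/third-trimester
ultrasound biometry (head circumference, HC; biparietal diameter, BPD). Each
alternative is biased relative to CRL dating, and the bias is not constant:
it varies with how preterm the newborn is, with growth restriction
(birthweight-for-GA Z-score), and -- for antenatal biometry -- with how late
in gestation the scan was taken. Misjudging gestational age (GA) by even a
couple of weeks changes clinical decisions around viability, corticosteroids
and intensive care, and misclassifies preterm birth in epidemiological work.

`gestagree` quantifies those biases as Bland-Altman-style limits of
agreement (LOA) on the within-woman difference scale, fits the bias
*surface* over the modifying covariates, and turns fitted or published
surfaces into a calculator usable at the bedside where no CRL exists.

## The model

For woman $i$, let $d_{ik}$ be the difference (in weeks) between the
alternative method's newborn GA estimate and the CRL-derived newborn GA for
replicate $k$ (positive = the method overestimates). The bias surface is

$$ d_{ik} = \beta_0 + \beta_1 Z_i + \beta_2 (G_i - 39) + \beta_3 (U_i - 25)
   + u_i + \varepsilon_{ik}, $$

where $Z_i$ is the birthweight-for-GA Z-score, $G_i$ the newborn GA (weeks,
centred at 39), $U_i$ the GA at the ultrasound measurement (weeks, centred
at 25; only for HC/BPD), $u_i \sim N(0, \sigma_u^2)$ a woman-by-method
effect, and $\varepsilon_{ik} \sim N(0, \sigma_e^2)$ a replicate residual.
The quantity a clinician cares about is the accuracy of **one future
measurement**, so the reported spread is

$$ \mathrm{SD}_{\text{single}} = \sqrt{\sigma_u^2 + \sigma_e^2}, \qquad
   \text{95% LOA} = \text{bias} \pm 2 \times \mathrm{SD}_{\text{single}}. $$

The multiplier is exactly 2, not 1.96: the published intervals this package
reproduces satisfy bias $\pm 2\,$SD at two decimals (for instance
$2.57 \pm 2 \times 1.04 = (0.49, 4.65)$), and we verified three such triples
before freezing the convention. One published BPD interval upper bound
(printed 1.84 where $0.39 + 2 \times 0.73 = 1.85$) reflects rounding of
unrounded coefficients and is deliberately not asserted anywhere.

### Estimation: closed-form moment steps

`fit_bias_surface_single()` (one measurement per woman: newborn exam,
serial-SFH dating) is ordinary least squares of $d_i$ on the centred
covariates; the residual SD (denominator $n - p$) is
$\mathrm{SD}_{\text{single}}$. For paired data this is algebraically the
same bias contrast a two-measurement mixed model with a woman random effect
estimates.

`fit_bias_surface_replicated()` (duplicated HC/BPD) uses three moment steps:

1. OLS of the per-woman mean difference $\bar d_i$ on the centred
   covariates gives $\hat\beta$ and the mean-level residual variance
   $v_{\text{mean}} = \hat\sigma_u^2 + \hat\sigma_e^2/2$;
2. the pooled within-woman variance
   $v_{\text{rep}} = \sum_i \sum_k (d_{ik} - \bar d_i)^2 / \sum_i (m_i - 1)$
   estimates $\sigma_e^2$;
3. $\mathrm{SD}_{\text{single}} = \sqrt{v_{\text{mean}} + v_{\text{rep}}/2}$
   undoes the averaging gain the duplicate enjoyed.

Because the covariates are constant within woman and the design is balanced
($m_i = 2$; other replicate counts are rejected in this version), these
moment steps coincide exactly with the REML fit of the stacked mixed model
-- the test suite checks agreement with an independent `lme4` fit to
$10^{-6}$ on the fixed effects. We chose the moment form as canonical
because it is closed-form, auditable, and states the single-future-
measurement contract explicitly; the likelihood route is the cross-check,
not the implementation. The model-fitting software and restricted-vs-full
likelihood choices behind the published parameter sets are not fully
specified anywhere we could verify, so exact numerical equivalence with
them is not claimed -- only the documented equivalence on this package's
own designs.

Interaction *p*-values come from `interaction_lrt()`: twice the gap in
Gaussian maximum log-likelihood between nested difference-scale models,
referred to $\chi^2$ with the term-count difference as degrees of freedom
(per-woman means are used when replicates are present). Its type-I error at
$n = 250$ is verified to sit inside the 95% binomial envelope of the
nominal 0.05 over 1,000 null simulations.

### Covariate parameterization matters

The covariates themselves depend on which GA estimate you trust. Computed
from CRL dating (`covariate_source = "crl"`), the surfaces answer "how
wrong is the method, given the truth"; computed from the method's own GA
(`covariate_source = "method"`), they answer the clinically usable question
"how wrong is the method, given only what I can observe without CRL". The
slopes differ in sign and magnitude between the two forms -- bias grows
with CRL-derived Z-score but shrinks with method-derived Z-score, for
example -- so `run_pipeline()` always fits and reports both side by side,
and every fit records its `covariate_source`.

## The calculator

`predict_bias()` evaluates a surface at chosen covariates and returns bias
with 95% LOA. `published_fits()` loads the parameter sets bundled in
`inst/extdata/published_fits.json` -- the method-covariate ("calculator")
surfaces for all four methods plus the reference-covariate surfaces at
their reported anchor points -- so the calculator works without refitting:

```{r calculator}
fits <- published_fits()
predict_bias(fits$hc, z = 0, newborn_ga = 34, ga_us = 25)
predict_bias(fits$dubowitz, z = -2, newborn_ga = 39)
```

Each bundled surface carries the covariate region it was estimated on;
evaluation outside it warns and flags the result (`in_observed_range`)
rather than extrapolating silently. One bundled interval's upper bound is
printed in two conflicting ways in its source material (3.30 in prose, 3.20
in the parameter table); the fixture uses 3.20, which is what
$0.52 + 2 \times 1.34$ gives. Similarly, the BPD newborn-GA slope is
printed as 0.22 in prose but 0.30 in the parameter table; the fixture
follows the table.

## Dating formulas and derived quantities

GA is stored internally as decimal weeks; `"W+D"` notation is converted at
I/O as $W + D/7$. Dating coefficients live in a YAML registry
(`inst/extdata/dating_formulas.yaml`), each entry carrying its citation:
the Robinson-Fleming square-root CRL curve (output in days), the
Chitty-Altman log-cubic HC curve, and the Hadlock quadratic BPD curve. The
registry is validated at load (finite, strictly increasing over the
validity range) and unit tests pin the transcriptions to their anchor
points (CRL 10 mm $\to$ 7.03 weeks; 41 mm $\to$ 10.76; 80 mm $\to$ 13.68).
Inversion (needed by the generator) is closed-form except for the HC curve,
where a damped Newton iteration from a linear-interpolation start converges
to $10^{-12}$ within the validity range.

Two components are deliberately pluggable synthetic defaults, because their
official coefficient sets are external data this package does not bundle:

* **Growth standard.** `synthetic_growth_standard()` uses a log-quadratic
  median weight curve (about 1200 g at 28 weeks, 3600 g at 40 weeks), a 3%
  sex offset and an 11% coefficient-of-variation spread, valid over 24-43
  weeks. Z-scores outside the validity range are reported missing with a
  reason, never extrapolated -- cohort reports therefore show a handful of
  missing Z-scores for post-term births, as real cohort tables do.
  International centile coefficients can be supplied via
  `growth_standard()`. SGA is strictly $Z < -1.28$ (below the 10th
  centile); the threshold is sometimes printed without its minus sign
  elsewhere, but "below the 10th centile" fixes the sign unambiguously.

* **Serial-SFH dating.** `ga_from_sfh()` requires at least three timed
  measurements and refuses ("insufficient") otherwise. The default model is
  linear in GA (`height_cm = -2 + 1.0 * ga`) with 1 cm measurement noise;
  under those defaults a five-point series dates a pregnancy within the
  ±2-week accuracy serial-SFH formulas are reported to achieve, which the
  test suite verifies by simulation. A published population-specific
  formula can be substituted through the `params` argument.

## The synthetic cohort generator

No individual-level cohort data are bundled, so `simulate_cohort()`
generates cohorts with the structure the analysis assumes:

* **Truth scale.** True newborn GA *is* the CRL-derived GA, drawn from
  N(39, 1.5) truncated to [28, 44.4] weeks -- a realistic clinic
  distribution with a viability floor. Generated bias is therefore bias
  relative to CRL, the analysis target.
* **Two cohort designs.** The `dubowitz` design (default n = 250) draws
  `round(0.30 n)` records from the pre-term/post-term strata by
  inverse-CDF sampling of the truncated truth distribution restricted to
  that region (an explicit error if the configuration puts no mass there),
  and records the stratum label so the sub-group analysis can undo the
  oversampling. The `biometry` design (default n = 975) schedules one study
  scan uniformly on 16-40 weeks, measures HC and BPD twice, and attaches a
  serial SFH series to a 704/975 fraction of women.
* **Measurement model.** A method's GA estimate is truth plus the
  configured bias surface plus a woman-by-method effect plus a per-replicate
  residual. Biometric mm values are the dating-curve inverses at the noised
  scan GA, so re-dating a generated measurement reproduces it exactly; scan
  times whose noised estimates leave a curve's validity range (or that fall
  after birth) are resampled and counted.
* **Defaults are the study conditions.** The generative surfaces default to
  the published fits (newborn exam: 0.82 weeks at the 39-week centering
  point, +0.40/Z, -0.35/week, SD 1.04; HC: -0.37, -0.07/Z, +0.28/week,
  -0.07/scan-week, SD 0.69 split as $\sigma_u = 0.50$,
  $\sigma_e = 0.4755$; BPD SD 0.73 split 0.55/0.48, an exact Pythagorean
  split). These were fixed once from the published values and are exposed
  in `sim_config()`, not tuned.

What the generator does **not** emulate: gestational-diabetes effects,
digit preference and other human measurement artefacts, correlation between
malaria exposure and growth restriction (the malaria flag is an independent
Bernoulli used only by the sub-group filter), missing-data mechanisms
beyond the SFH availability fraction, and any real ranking of methods'
accuracy in a new population. Passing parameter-recovery tests therefore
show the estimators are correct for the assumed model, not that the model
captures every feature of clinic data.

## Numerical and design choices

* Complete-case handling: difference-table rows lacking a Z-score are
  dropped per fit and counted (`n_dropped`), mirroring how cohort tables
  footnote missing Z-scores.
* Report percentages round half-up (`round_half_up()`), the convention
  under which the published 2x2 marginals reconstruct uniquely;
  `reconstruct_from_marginals()` enumerates all integer-feasible tables and
  errors on zero or multiple survivors rather than guessing.
* Confidence intervals for sensitivity/specificity are exact
  Clopper-Pearson (`binom.test`); the CI method behind the published
  classification table is unstated, so printed bounds may differ by a
  point. One published misclassification sentence pairs 39% with a CI of
  (40, 65); the package reports the point estimate with its own exact CI
  and leaves the anomaly to this note.
* `fit_bias_surface_replicated()` supports only $m_i = 2$ and errors,
  listing woman ids, otherwise; the general unequal-$m$ correction is out
  of scope for this version.
* Degenerate inputs: zero-variance differences fit cleanly (slopes 0,
  SD 0); `kappa_statistic()` returns `NA` for degenerate marginals;
  `loa_interval()` rejects negative SDs.
* The 72-hour newborn-exam window cannot be checked more finely than whole
  days from date fields, so the validator does not attempt it.

## Problem sizes used in the checks

The test suite simulates at the study scales it models: n = 250 for the
newborn-exam design, n = 975 for the duplicated-biometry design, 50,000
women for the empirical LOA-coverage check (93.5-96.5% band around the
nominal 95.45% of a ±2 SD interval), 1,000 null replicates for LRT
calibration, and 2,000 series for SFH accuracy. These sizes give
Monte-Carlo error comfortably inside the asserted tolerances.

## Limitations

The package fits only the two designs described (one measurement per
woman; exactly two replicates per woman), on the difference scale. It does
not invert biases to "correct" a GA estimate -- it reports bias and LOA and
stops there. The bundled surfaces describe one study population on the
Thai-Myanmar border; in other populations they should be refitted
(`run_pipeline()` on local data) rather than reused, and the calculator
refuses to pretend otherwise outside the observed covariate ranges.
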