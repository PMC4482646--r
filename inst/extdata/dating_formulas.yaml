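# Registry of gestational-age dating formulas.
#
# Coefficients are transcribed from the cited primary references so that the
# transcription is auditable and swappable; they do not live in code. Each
# entry maps one biometric (mm) to gestational age.
#
# types:
#   sqrt_linear  : ga = b0 + b1 * sqrt(x)            (x in mm)
#   log_cubic    : ga = exp(b0 + b1*x + b2*x^2 + b3*x^3)
#   quadratic_cm : ga = b0 + b1*(x/10) + b2*(x/10)^2 (evaluated on cm)
formulas:
  - name: robinson_fleming_crl
    citation: "Robinson HP, Fleming JEE (1975). A critical evaluation of sonar crown-rump length measurements. Br J Obstet Gynaecol 82:702-710."
    input_biometric: crl_mm
    type: sqrt_linear
    output_units: days
    coefficients:
      b0: 23.73
      b1: 8.052
    valid_input_range: [10.0, 80.0]
  - name: chitty_altman_hc
    citation: "Chitty LS, Altman DG (1997). New charts for ultrasound dating of pregnancy. Ultrasound Obstet Gynecol 10:174-191."
    input_biometric: hc_mm
    type: log_cubic
    output_units: weeks
    coefficients:
      b0: 1.854
      b1: 0.010451
      b2: -0.000029919
      b3: 0.000000043156
    valid_input_range: [80.0, 350.0]
  - name: hadlock_bpd
    citation: "Hadlock FP, Deter RL, Harrist RB, Park SK (1984). Estimating fetal age: computer-assisted analysis of multiple fetal growth parameters. Radiology 152:497-501."
    input_biometric: bpd_mm
    type: quadratic_cm
    output_units: weeks
    coefficients:
      b0: 9.54
      b1: 1.482
      b2: 0.1676
    valid_input_range: [14.0, 100.0]
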