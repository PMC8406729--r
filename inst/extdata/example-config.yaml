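# Example rohclass configuration.
# Scan keys omitted here keep their defaults (window 60 -> 50 by 5,
# slide 1, min run 15, class frequency > 0.75%, FDR 1%,
# 1000 threshold samples with the 0.05-0.10 significance band).
scan:
  initial_window: 60
  min_window: 50
  fdr_q: 0.01

# Directions default to lower-unfavorable for MY/FY/PY/NRR and
# higher-unfavorable for NS/FSTC/AFS; they only need to be stated to
# override the default.
traits:
  MY: {unit: kg}
  FSTC: {unit: days}

# Variance components per analyzed trait (trait units squared); normally
# taken from a routine genetic evaluation, or estimated once with
# estimate_variance_components().
variance_components:
  MY:
    animal: 900155
    hy: 150026
    hrys: 150026
    ss: 150026
    ait: 150026
    residual: 1200207
  FSTC:
    animal: 334
    hy: 56
    hrys: 56
    ss: 56
    ait: 56
    residual: 445

factors:
  fixed: [hys]
  random: [hy, hrys, ss, ait]
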