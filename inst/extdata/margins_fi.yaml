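# Covariate margins for the synthetic ASCOT-Carer valuation cohort.
# `sample`: share in the analysis sample (n = 1005), used as the Bernoulli
# rate by the respondent simulator. `population`: Finnish general adult
# population share, used by the post-stratification adjustment.
hgood:
  sample: 0.539
eduhigh:
  sample: 0.302
tmlong:
  sample: 0.750
renter:
  sample: 0.464
  population: 0.274
lowedu:
  sample: 0.108
  population: 0.188
noreligion:
  sample: 0.379
  population: 0.267
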