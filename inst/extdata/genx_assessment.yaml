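# End-to-end pipeline configuration for the GenX worked example:
# 2-year male-rat liver endpoints -> BMD (frequentist + Bayesian model
# average) -> deterministic RfD and probabilistic RfD -> MCLG.
version: 1
seed: 17
quantal:
  fixtures: [cystic_focal_degeneration, centrilobular_hypertrophy, centrilobular_necrosis]
  bmr: {kind: extra_risk, level: 0.10}
  confidence: 0.95
rfd:
  endpoint: cystic_focal_degeneration
  animal_bw: 0.29      # chronic-rat body weight back-calculated from the
                       # reported POD/HED pair; report alongside results
  human_bw: 70
  ufs: {a: 3, h: 10, d: 3}
bayes:
  endpoint: cystic_focal_degeneration
  n_draws: 100000
prfd:
  incidence: 0.01
  uf_d: 3
  n_samples: 100000
guideline:
  body_weight: 70
  drinking_water_intake: 2
  rsc: 0.2
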