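# Default lognormal adjustment-factor parameters for the probabilistic
# reference-dose chain, following the published probabilistic hazard
# characterization defaults (WHO/IPCS-style). Each factor is a lognormal
# described by its median (p50) and P95/P50 ratio.
version: 1
af_bw:
  # total daily dose scales as BW^0.7 => per-kg dose ratio exponent 0.3;
  # exponent_sd is the standard deviation of the allometric exponent and
  # widens the factor as (BW_human/BW_animal)^(1.6449 * exponent_sd)
  allometric_exponent: 0.7
  exponent_sd: 0.024
af_tktd:
  # residual interspecies TK/TD after allometry
  p50: 1.0
  p95_p50: 3.0
af_h:
  # median-to-I-th-percentile human sensitivity ratio, by target incidence I
  "0.01": {p50: 9.7, p95_p50: 4.3}
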