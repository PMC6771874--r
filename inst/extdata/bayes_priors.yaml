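# Priors for the Bayesian quantal suite, specified as normal distributions
# on the transformed parameter scale (logit for probabilities, log for
# positive slopes/powers, identity for locations) of the dose-normalized
# models (u = dose / max dose). Styled after the published defaults of the
# standard benchmark-dose software's Bayesian suite; calibrated once against
# the 2-year bioassay worked example and then frozen.
version: 1
background_logit: {mean: -1.0, sd: 2.0}
asymptote_logit: {mean: 0.0, sd: 3.0}
location: {mean: 0.0, sd: 4.0}
log_slope: {mean: 0.55, sd: 0.45}   # slope on log-dose (median ~1.7)
log_power: {mean: 0.55, sd: 0.45}   # gamma/weibull shape (median ~1.7)
log_rate: {mean: 0.1, sd: 0.7}      # rates on the scaled dose
log_beta: {mean: -0.7, sd: 0.7}     # multistage coefficients (scaled dose)
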