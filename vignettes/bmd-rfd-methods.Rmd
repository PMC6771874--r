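---
title: "Benchmark-dose modeling and reference-dose derivation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose modeling and reference-dose derivation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmdtox)
```

This vignette is the package's own account of the statistical machinery:
the models and their assumptions, the parameters that matter, the numerical
choices, and where genuinely open design questions were settled.

## Dose-response models and likelihoods

Quantal (dichotomous) data are per-group incidences $x_g$ out of $n_g$
animals at doses $d_g$ (mg/kg/day). Every model in the nine-member suite
defines a response probability $P(d;\theta)$, non-decreasing in dose under
the default constraints, and is fit by maximizing the binomial
log-likelihood $\sum_g x_g \log P_g + (n_g - x_g)\log(1 - P_g)$. Most
members share the background form $P(d) = \gamma + (1-\gamma)F(d)$, for
which extra risk $[P(d)-P(0)]/[1-P(0)]$ equals $F(d)$ itself — the reason
extra risk is the conventional quantal benchmark response.

Continuous data are group summaries $(n_g, \bar y_g, s_g)$. The normal
likelihood is written in sufficient-statistic form,
$-\tfrac{n_g}{2}\log(2\pi\sigma_g^2)
 -[(n_g-1)s_g^2 + n_g(\bar y_g - \mu_g)^2]/(2\sigma_g^2)$,
which is *identical* to the individual-data likelihood (a test asserts the
identity numerically). Constant variance is the default and is profiled out
analytically; a power-of-mean variance model
($\sigma_g^2 = \alpha|\mu_g|^\rho$) is available for fitting, though the
profile-likelihood bound is implemented for the constant-variance model
only. The data give no basis for preferring a variance model, and the 1-SD
benchmark convention below is defined against a single modeled SD.

**Dose and response scaling.** All fitting happens on $u = d/\max(d)$, and
continuous responses are additionally divided by the largest group mean.
This is purely a numerical re-parameterization: it conditions the
optimizer, makes the Bayesian priors dimensionless, and renders BMD and
BMDL *exactly* equivariant under a rescaling of dose (a property-based test
checks equality to near machine precision). Fitted parameters are reported
on the scaled axes together with the scale factors.

## Benchmark doses and profile-likelihood bounds

The BMR conventions follow standard regulatory practice: 10% extra risk
for incidence data, one control SD (`bmr_sd()`) or a relative deviation
(`bmr_rel()`) for continuous endpoints. Added risk is implemented for
completeness; extra risk is the default everywhere. For every suite model
the BMD has a closed form (the multistage polynomial is solved exactly via
`polyroot`), so no root-finding tolerance enters the point estimate. A BMD
more than $10^4$ times the highest tested dose (a flat fitted slope) is
reported as "BMR unattainable" rather than as a number.

The BMDL is a one-sided 95% profile-likelihood bound: re-parameterize the
model so the BMD is an explicit parameter (each model has an exact "slope
substitution" that pins the BMD at a candidate value $B$), re-maximize the
likelihood over the remaining parameters, and find the smallest $B$ whose
profiled log-likelihood stays within $\chi^2_1(0.90)/2 = 1.352771$ nats of
the global maximum. The profile is scanned downward on a geometric grid
(step $10^{0.05}$) with warm-started optimizations, and the crossing is
polished by `uniroot` at relative tolerance $10^{-7}$. If the profile never
closes above a floor of $10^{-4} \times$ BMD, the floor is returned with an
explicit flag. For the continuous 1-SD benchmark the profiled $\sigma$
feeds back into the benchmark change; the substitution is iterated to a
fixed point within each profile step.

A simulation study in the test suite (500 bioassay-layout replicates,
quantal-linear truth) checks that the true BMD exceeds the BMDL in at
least 93% of replicates at the nominal 95% level.

## Optimization

Fits use multi-start local optimization (`nlminb` under box constraints):
a method-of-moments style seed (control-group background, mid-box slopes)
plus Latin-hypercube starts (`lhs`), ten starts by default, all generated
from a caller-supplied seed so fits are reproducible bit-for-bit; the
caller's RNG stream is left untouched. The incumbent is polished by
repeated restarts until the objective stops improving. On small models the
test suite requires the optimizer to match a brute-force grid oracle to
within $10^{-3}$ nats. Degenerate incidence patterns (all zero, all one)
fit at the parameter bounds rather than failing.

Shape and log-dose-slope parameters are bounded below by 1 by default
("restricted" suite), preventing supralinear low-dose behavior; an
unrestricted toggle exists. Parameters that finish on a constraint
boundary are not counted as estimated: AIC ($-2\ell + 2k$) and the Pearson
goodness-of-fit degrees of freedom ($G - k$ for $G$ groups) use the
boundary-aware count, the convention of the standard benchmark-dose
software family. The multistage degree defaults to
$\min(G - 1, 3)$ for frequentist fits and 2 in the Bayesian averaging
suite (the model-averaging convention).

## Model selection

Fits are screened for adequacy — convergence, an attainable BMD, Pearson
goodness-of-fit $p \ge 0.10$, and $|$scaled residual$| \le 2$ at the
control group and at the group nearest the BMD; saturated fits (no
goodness-of-fit degrees of freedom) are not auto-selectable. Among
survivors the lowest AIC wins. The literature states the criteria
qualitatively; the 0.10 and 2 cutoffs are the conventional ones. Ties
(within 0.1 AIC) break by fewer estimated parameters, then lower BMDL,
then lower BMD, then suite order — each step is needed because wide dose
spacing (the packaged bioassay has none between 1 and 50 mg/kg/day) leaves
several models at numerically identical likelihoods; the final two steps
prefer the more conservative point of departure and make selection fully
deterministic. The BMD/BMDL ratio of the winner is flagged above 5 as a
sign of high model uncertainty.

## Bayesian model averaging

Each suite model receives independent normal priors on *transformed*
parameters — logit scale for probabilities, log scale for slopes and
powers, identity for locations — of the dose-normalized model, so one
dimensionless prior configuration (`inst/extdata/bayes_priors.yaml`)
applies to any dataset. The posterior mode is found by the same
multi-start machinery; the marginal likelihood uses the Laplace
approximation
$\log m \approx \log \pi(\hat z) + \tfrac{k}{2}\log 2\pi -
\tfrac12 \log\det H$, with $H$ the negative Hessian (`pracma::hessian`) at
the mode; a singular $H$ is regularized through its eigenvalues and
flagged. Posterior model weights are proportional to $m$ under a uniform
model prior. The model-averaged BMD/BMDL are the median and 5th percentile
of mixture draws: models drawn by weight, parameters from each model's
Laplace Gaussian, each draw's BMD computed in closed form; draws that
cannot attain the BMR are censored at $10^3 \times$ the highest dose and
counted (more than 20% censoring is an error). Laplace weighting was
chosen over MCMC deliberately: it is deterministic given the seed,
desk-scale fast, and matches the weighting scheme of the reference
software family.

The prior *families* are fixed by the structure above; their location and
scale values are not identifiable from first principles, so they live in
the versioned YAML config. The shipped values were calibrated once against
the package's worked bioassay example (the published model-averaged
BMD/BMDL pair for the cystic focal degeneration endpoint) and then frozen;
swapping the file changes the priors without touching code.

## Deterministic reference dose

$\mathrm{HED} = \mathrm{POD}\times(BW_a/BW_h)^{1/4}$ (BW$^{3/4}$ scaling
of daily dose). The animal body weight is a *required* input, surfaced in
every report — the worked-example configuration uses 0.29 kg, the chronic
rat weight implied by the published POD/HED pair, and a table of
conventional species defaults is provided. Uncertainty factors compose on
the half-log convention: each "3" contributes $10^{0.5}$, so
$\{3, 10, 3\}$ composes to $10^2 = 100$, not the literal product 90. This
convention is forced by the worked example's stated total. Reference doses
are reported to one significant figure (the field's convention), with the
raw value always retained alongside.

## Probabilistic reference dose

The chain is pure lognormal algebra. `ad_from_bmd(bmd, bmdl)` builds the
animal-dose distribution with median BMD and 5th percentile BMDL,
i.e. $\sigma_{\ln} = \ln(\mathrm{BMD}/\mathrm{BMDL})/1.6449$. The three
adjustment factors are independent lognormals described by (P50, P95/P50)
in `inst/extdata/aprob_defaults.yaml`:

* **AF_BW** — allometric scaling. The framework this module follows scales
  *total* daily dose as $BW^{0.7}$, giving a per-kg median of
  $(BW_h/BW_a)^{0.3}$, with uncertainty in the exponent (sd 0.024)
  widening the factor as a power of the body-weight ratio. Note the
  deliberate asymmetry with the deterministic HED's $BW^{3/4}$: the two
  conventions coexist in practice, and each pipeline follows the
  convention of the method it implements — using $^{1/4}$ scaling inside
  the probabilistic chain would shift the sensitive-human percentile about
  25% upward and away from the probabilistic framework's own defaults.
* **AF_TK/TD** — residual interspecies toxicokinetics/toxicodynamics after
  allometry: P50 = 1, P95/P50 = 3 (the half-log residual factor read as a
  95th percentile).
* **AF_H^I** — ratio of the median human to the human at the $I$-th
  sensitivity percentile: for the default $I$ = 1%, P50 = 9.7,
  P95/P50 = 4.3. $I$ = 50% degenerates the factor to 1, collapsing
  $HD_M^I$ onto $HD_M^{50\%}$ (a test asserts this identity).

Because the factors are independent lognormals, log-medians subtract and
log-variances add, so every percentile of $HD_M^{50\%}$ and $HD_M^I$ has a
closed form; a Monte Carlo evaluator (default $10^5$ samples, $10^6$ in
the acceptance script) must agree with it — the 5th percentiles to within
1% at $10^6$ draws — which guards both implementations at once. The
database factor UF_D is applied *deterministically after* the 5th
percentile, dividing literally by 3 (the half-log reading $10^{0.5}$ is
also reported; at one significant figure the worked example's pRfD is the
same either way). A per-factor variance budget
($\sigma_i^2/\sigma_{tot}^2$ on the log scale) accompanies every result.

## Guideline value

$\mathrm{MCLG} = \mathrm{RfD} \times BW \times RSC / \mathrm{intake}$,
converted to µg/L, with the standard adult defaults (70 kg, 2 L/day, 20%
relative source contribution) as explicit, overridable inputs.

## Synthetic data: what it does and does not emulate

The generator draws incidences binomially around any suite model's curve
and continuous summaries from normal individual responses with constant
SD, at arbitrary dose layouts — `table1_like_design()` reproduces the
packaged bioassay's layout (doses 0, 0.1, 1, 50; n = 70) with a
quantal-linear truth fitted to a fixture, chosen over a higher-degree
truth because its benchmark dose is identified at that layout and so
usable as a coverage target. Binomial and normal noise are the only
mechanisms: no litter (intra-class) correlation, no overdispersion, no
time course, no dose-measurement error. Passing recovery and coverage
tests therefore demonstrates correctness of the estimators under the
models' own assumptions, not robustness to the clustered or overdispersed
structure of real developmental bioassays.

## Validation problem sizes

The shipped tests run at sizes chosen to keep Monte Carlo error well below
the tolerance they assert: parameter recovery at $10^4$ animals/group
averaged over 4 replicates (binomial noise alone leaves ~2% error on a 5%
background); large-sample consistency at $10^6$/group; BMDL coverage over
500 bioassay-layout replicates; goodness-of-fit calibration over 1000
null replicates; Bayesian averaging at $10^5$ mixture draws; Monte Carlo
propagation at $10^6$ samples.

## Known limitations

* Profile-likelihood BMDLs for continuous endpoints require the
  constant-variance model.
* The Bayesian module covers the quantal suite only, with Laplace (not
  MCMC) posteriors; informative chemical-specific priors are out of scope.
* Adjustment factors in the probabilistic chain are independent by
  construction; correlated factors are unsupported.
* Summary (group-level) data only: no individual-animal, time-to-event or
  litter-structured modeling.
* The continuous developmental benchmark is interpreted as a relative
  deviation from the control mean (`bmr_rel(0.05)`); hybrid
  extra-risk formulations for continuous data are not implemented.
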