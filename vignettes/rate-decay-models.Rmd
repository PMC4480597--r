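---
title: "Modelling time-dependent substitution-rate decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling time-dependent substitution-rate decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdrp)
```

## The problem

Molecular evolutionary rates estimated over short timescales are
systematically higher — often by orders of magnitude — than rates estimated
over geological timescales, and the estimated value decreases *continuously*
as the measurement window widens. This time-dependent rate phenomenon (TDRP)
means a single "molecular clock" rate extrapolated across timescales can
badly bias divergence-date estimates. Viruses with a long, stable
co-speciation history with their hosts are an ideal system to measure the
phenomenon: host fossil-calibrated divergence dates supply node ages `t`
spanning five orders of magnitude, and a strict-clock Bayesian analysis of
the viral alignment supplies node-to-tip substitution counts `s`
(substitutions/site), so every dated internal node yields an average-rate
measurement `rbar = s / t` at its own timescale.

`tdrp` implements the full analysis around this design: four empirical decay
laws for the instantaneous rate `r(t)`, their induced curves for `s(t)` and
`rbar(t)`, nonlinear least-squares fitting under two criteria, leave-one-out
cross-validation (LOOCV) of the models as date predictors, and date inference
for uncalibrated nodes. A synthetic-data generator reproduces the statistical
shape of such a dataset so that every stage is testable with known truth.

## The four decay models

With `t` measured present-to-past (`t = 0` now), the instantaneous-rate
families are

* VEX (vertically-translated exponential): `r = alpha * exp(-t*beta) + k`
* EX (simple exponential): `r = alpha * exp(-t*beta)`
* VPL (vertically-translated power law): `r = alpha * t^-beta + k`
* PL (simple power law): `r = alpha * t^-beta`

`k >= 0` is the stable long-term rate the translated families decay towards;
`alpha, beta > 0` are free shape parameters. Integrating from the origin
(zero substitutions at zero elapsed time) gives closed forms for the
cumulative substitutions `s(t)`, e.g. for PL
`s = alpha * t^(1-beta) / (1-beta)`, and dividing by `t` gives the
average-rate curves `rbar(t)`. For the power-law families this forces
`beta < 1`: at `beta >= 1` the integral through the origin diverges, so the
constraint box for fitting is `beta` in `(1e-6, 1 - 1e-6)` even though
positivity is the only constraint stated for the other parameters.

Under PL the log-log relationship is exactly affine:
`log10 rbar = const - beta * log10 t`, which anchors both the preliminary
correlation analysis and a closed-form quality check
(`loglog_fit()` recovers `-beta` to machine precision on noiseless data).

## Data model and uncertainty propagation

A `cospeciation_dataset()` couples a rooted ultrametric tree (branch lengths
in substitutions/site; node height equals node-to-tip substitutions under the
strict clock) with per-node `s` posterior draws and, for calibrated nodes, a
published median and 95% interval for the host-derived age. Interval bounds
become a normal standard deviation via the wider half-width,
`max((median - lower)/1.96, (upper - median)/1.96)` — conservative when the
published interval is asymmetric.

Uncertainty is propagated by resampling (`assemble_rate_sets()`): each
replicate draws one age per dated node from its normal prior, *constrained so
every child is younger than its nearest dated ancestor*, and pairs it with one
uniformly drawn `s` sample. Ordering is enforced top-down: ancestors are
drawn first and each descendant is drawn from its normal truncated above at
the ancestor's realised age, via the inverse CDF. This produces exact
per-row feasibility with no rejection loops; a whole-row rejection sampler is
kept in the test suite as the distributional oracle, and the two agree
closely wherever truncation binds weakly. Ages are truncated below at 1e-6
Myr so no non-positive times occur. Draws are refused (with an error) only
when a child's prior mass lies essentially entirely above its ancestor's.

When only `(median, lower95, upper95)` summaries of `s` are available, draws
are reconstructed log-normally to match the median and interval; the dataset
flags this, since real posterior draws are preferable.

## Fitting

Two criteria mirror the two uses of the models:

* **LSE of rbar** — minimise squared error of the average-rate curve against
  the observed `rbar` values; used to describe the decay and recover
  short-/long-term rates.
* **LSE of t** — minimise squared error of predicted against observed ages,
  with ages predicted by inverting the cumulative curve (`invert_time()`);
  used for cross-validation and date inference, since that task is
  time prediction.

Fitting is Levenberg–Marquardt (`minpack.lm::nls.lm`) on transformed
parameters — `log alpha`, `log beta` (exponentials) or a scaled logit of
`beta` (power laws), `log k` — so the positivity and `beta < 1` constraints
hold by construction. Residuals and analytic Jacobians use `expm1`/`log1p`
forms: the naive `1 - exp(-t*beta)` cancels catastrophically when `t*beta`
is tiny, which otherwise lets the optimiser wander into numerically
degenerate exponential fits with fictitious objective values. Transformed
coordinates are clamped to ±55 (natural scale ~1e-24 to 7e23) so
intermediate steps cannot overflow. For the time criterion the Jacobian
comes from the implicit-function theorem:
`d t_pred / d p = (ds/dp) / s'(t_pred)`.

Inversion of `s(t)` is closed-form for PL and EX; VEX and VPL use a
safeguarded, vectorised Newton iteration inside a geometrically expanded
bracket (warm-started at the observed ages inside the objective), converging
to `1e-10 + 1e-8 * t`. EX saturates at `s = alpha/beta`; inside the fitting
objective, unreachable points contribute a finite residual
`t_max * s * beta / alpha` that grows continuously with the violation, so
the optimiser can exit the infeasible region rather than fail. In
prediction, unreachable draws yield missing values that are counted and
reported.

Each fit uses one data-driven start (log–log or log-linear regression
initialisation, which lands very close to the optimum for power-law-like
data) plus seeded Latin-hypercube starts, 20 in total for standalone fits.
Inside LOOCV and the calibration-scheme loops — several thousand fits per
run — 3 starts and an iteration cap of 40 are used instead: the objective
is observed to plateau well before iteration 30, with the remaining
iterations only shrinking `k` logarithmically toward zero, and the
data-driven start makes the optimum insensitive to the number of restarts.
Fits require at least one more point than free parameters; adjusted
R-squared (`1 - (1-R2)(n-1)/(n-p-1)`) is reported only when at least two
residual degrees of freedom exist, so the deliberate 3-point power-law fits
of the calibration schemes run with the statistic suppressed rather than
erroring. Fitting operates internally in Myr (rates in
substitutions/site/Myr) for conditioning; reported rates are converted to
substitutions/site/year by exact 1e6 factors.

## Model comparison and date inference

`run_loocv()` treats each resampled set as one validation round: each node
in turn is held out, each model is refitted to the rest under the time
criterion, and the held-out age is predicted from the node's `s` draw. The
per-round score is the out-of-sample mean squared error on the Myr scale.
Rounds are the blocks of a tie-corrected Friedman test over the four models,
followed by the six pairwise two-sided Wilcoxon signed-rank tests with
Bonferroni correction (exact null up to 25 rounds, normal approximation with
continuity correction beyond). Rounds missing any prediction (EX saturation
or a failed fold) are excluded from the rank tests and counted.

`run_calibration_scheme()` reproduces the three-node calibration experiments:
six fixed schemes (`shallow` = nodes 1–3, `intermediate` = 4–6, `deep` = 8,
10, 11, and three dispersed triples), fitting the chosen model to the three
calibrators only and predicting all other dated nodes. Nodes 7 and 9 never
calibrate: their host-derived and model-recovered dates disagree strongly in
both directions, so neither can serve as ground truth. Three-parameter
kinds are refused on three calibrators (they would interpolate exactly)
unless explicitly overridden. `infer_missing_dates()` performs the final
application — dating the uncalibrated nodes (labelled I and II in the
fv-like preset) from an ensemble fitted to all dated nodes except 7 and 9 —
pairing fits and `s` draws by replicate index so each replicate is
internally coherent.

## The synthetic generator and what it does (not) show

`synthetic_scenario()` fixes the generating conditions; `generate_dataset()`
realises them. The `fv-like` preset places 11 dated nodes at 0.96, 2.17,
8.30, 11.50, 19.05, 31.56, 43.47, 87.18, 87.30, 88.70 and 98.90 Myr and two
undated nodes at 23.40 and 40.81 Myr, matching the depth profile of a
14-taxon foamy-virus/host co-speciation dataset (the 19.05 Myr node is the
log-midpoint of its neighbours, whose published value is not in the main
sources). The default true model is PL with `alpha = 1.5e-4`
substitutions/site/year and `beta = 0.6`, the decay connecting a short-term
rate of order 1e-4 at 10 years to a long-term rate of order 1e-8 at 30 Myr.
The tree is a pectinate ladder realising these heights: only node heights
enter any downstream computation, so topology beyond the nesting order is
immaterial.

Substitution draws are log-normal around the true `s(t)` (positive,
right-skewed, median-parameterised, like Bayesian branch-length posteriors)
with coefficient of variation `s_noise_cv * (1 + t/max t)`, so absolute
spread grows down the tree. The default baseline CV is 0.02: for a ~3,350-nt
alignment with deep `s ~ 0.56`, counting statistics alone give
`CV ~ sqrt(1/(s*L)) ~ 2%`, and the default reproduces that order.
Calibration intervals default to ±10% of the true age
(`calib_halfwidth_frac = 0.1`), typical of published host divergence-date
CIs. Ground truth is returned separately and never consulted by fitting
code.

Two caveats delimit what passing tests show. First, the generator draws `s`
independently across nodes, whereas real node-height posteriors are
correlated along the tree and the node-wise data are not phylogenetically
independent; the analyses here, like the design they implement, accept that
non-independence. Second, model discrimination by LOOCV is
noise-regime-sensitive: with heavy noise in `s` (the predictor under the
time criterion), errors-in-variables dilution makes the best out-of-sample
predictor *flatter* than the true inverse curve, and the three-parameter
families can exploit that — under a heavy-noise regime VEX/VPL can tie or
even edge out the generating PL in median out-of-sample error while the mean
ranks still favour PL. At the default, counting-statistics-scale noise the
generating PL wins both summaries, but its margin over VPL is small and a
statistical near-tie (Bonferroni-adjusted Wilcoxon p near 1 between PL and
VPL); only the simple exponential separates decisively. Conclusions about
real data should therefore rest on the full rank-test output, not the median
ordering alone.

## Numerical choices, degenerate inputs, limitations

* Ultrametricity is asserted to relative 1e-6; node height is the mean over
  descendant tip distances.
* Degenerate (zero-width) calibration priors are point masses, handled
  exactly; infeasible child/parent orderings error at construction or
  simulation, never silently.
* `rate_model` JSON serialisation carries 17 significant digits and
  round-trips value-exactly.
* Randomisation test: one-sided lower tail with add-one correction,
  `p = (1 + #[null <= observed]) / (1 + n_null)`, defaulting to 100 null
  re-pairings; decay is a directional alternative and the quotient artefact
  is negative, so the lower tail is the conservative comparison.
* Percentile summaries are central 2.5/97.5 quantiles throughout.
* Problem sizes in the test-suite simulations (e.g. 200 recovery replicates,
  200 LOOCV rounds, 500 calibration repetitions) are the package's chosen
  experiment sizes, balancing Monte-Carlo error on the checked quantities
  against runtime.
* Not implemented by design: likelihood-based fitting and information
  criteria (the models are empirical, with no likelihood), k-fold variants,
  additional decay families, lineage-specific rate dynamics, and any
  sequence-level simulation or Bayesian tree estimation — the package
  consumes the `(s, t)` layer such analyses produce.
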