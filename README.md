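# tdrp — time-dependent substitution-rate decay models for divergence dating

Substitution-rate estimates are not constant in the timescale over which
they are measured: the shorter the window, the higher the estimated rate,
with a smooth, continuous decay in between (the *time-dependent rate
phenomenon*, TDRP). Ignoring it and extrapolating a single clock rate
across timescales biases divergence-date inference — shallow calibrations
underestimate deep dates, deep calibrations overestimate shallow ones.

`tdrp` is for molecular evolutionists and virologists who have node-dated
phylogenetic data — node-to-tip substitution counts `s` (substitutions/site,
from a strict-clock analysis) paired with independently calibrated node ages
`t` (e.g. host divergence dates in a virus–host co-speciation system) — and
want to (i) describe the rate decay empirically, (ii) pick the best decay
law by predictive validation, and (iii) use it to date uncalibrated nodes.

## The models

Four empirical laws for the instantaneous rate `r(t)` (`t` in the
present-to-past direction, `k` the stable long-term rate, `alpha, beta > 0`):

| kind | instantaneous rate | cumulative substitutions `s(t)` |
|------|--------------------|---------------------------------|
| VEX  | `alpha e^(-t beta) + k` | `alpha/beta (1 - e^(-t beta)) + k t` |
| EX   | `alpha e^(-t beta)`     | `alpha/beta (1 - e^(-t beta))`       |
| VPL  | `alpha t^(-beta) + k`   | `alpha t^(1-beta)/(1-beta) + k t`    |
| PL   | `alpha t^(-beta)`       | `alpha t^(1-beta)/(1-beta)`          |

(`beta < 1` for the power laws so the curve passes through the origin.)
Node-to-tip average rates are `rbar(t) = s(t)/t`. Models are fitted by
constrained nonlinear least squares under either the LSE-of-`rbar`
criterion (describing the decay) or the LSE-of-`t` criterion (predicting
dates by inverting `s(t)`), compared by leave-one-out cross-validation on
out-of-sample MSE with Friedman and pairwise Wilcoxon (Bonferroni) rank
tests, and applied to date inference with full uncertainty propagation by
resampling of `s` draws and ordering-constrained calibration ages.

## Worked example

Everything below runs on a synthetic dataset with known truth (a
foamy-virus-like co-speciation design: 11 dated nodes spanning ~1–99 Myr,
two undated nodes, true PL decay with `alpha = 1.5e-4` s/n/y, `beta = 0.6`):

```r
library(tdrp)

scenario <- synthetic_scenario(seed = 42)      # fv-like preset
gen <- generate_dataset(scenario)
gen$dataset
#> Cospeciation dataset: 14 tips, 13 internal nodes (11 dated)
#>   s draws per node: 1000-1000

sets <- assemble_rate_sets(gen$dataset, 200, seed = 43)
ens <- fit_ensemble(sets, "PL", "LSE_rbar", n_starts = 5)
ens$summary
#>   quantity     median    lower95    upper95
#> 1    alpha 0.03783776 0.03654835 0.03883273
#> 2     beta 0.59877531 0.57679022 0.62391321
#> 3        k 0.00000000 0.00000000 0.00000000
#> 4   adj_r2 0.99947290 0.99705711 0.99988223
```

The fitted `beta` (0.599 [0.577, 0.624]) recovers the generating 0.6;
`alpha` is on the Myr scale (`0.0378 = 1.5e-4 * 1e6^0.4`). Evaluating the
fitted curve at the two conventional timescales reconciles the short-term /
long-term rate discrepancy — nearly four orders of magnitude from a single
smooth decay:

```r
ok <- Filter(Negate(is.null), ens$fits)
rate_at_timescale(ok, 10)    # 10 years:  9.29e-05 [6.89e-05, 1.31e-04] s/n/y
rate_at_timescale(ok, 3e7)   # 30 Myr:    1.23e-08 [1.17e-08, 1.28e-08] s/n/y
```

Dates for the two uncalibrated nodes, from an ensemble fitted to the dated
nodes (excluding the two whose references are unreliable):

```r
infer_missing_dates(gen$dataset, n_sets = 200, seed = 44)
#>   node_id median_myr lower95_myr upper95_myr n_replicates
#> 1       I   24.37830    20.61712    29.26225          200
#> 2      II   41.09645    34.37596    47.81505          200
```

The generating truth placed these nodes at 23.40 and 40.81 Myr — both well
inside the inferred intervals. Model comparison runs as
`run_loocv(assemble_rate_sets(gen$dataset, 200, seed = 1))`, and the
three-node calibration experiments as
`run_calibration_scheme(gen$dataset, "dispersed-I", n_sets = 1500, seed = 1)`.

A command-line wrapper (`inst/scripts/tdrp.R`) exposes the same pipeline as
`simulate`, `correlate`, `fit`, `loocv` and `infer-dates` subcommands; every
run writes a `manifest.json` with the resolved configuration, seed and input
checksums.

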