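# fptreg

Temporal precision of threshold-crossing events in regulated gene
expression.

Cellular behaviors — a neuroblast ending its migration, a cell committing
to divide or differentiate — are often triggered when a molecular species
`X` first accumulates to a threshold copy number `x*`. Production is noisy,
so the trigger time is a random variable: a first-passage time (FPT). This
package is for quantitative biologists asking how *regulation* of that
production — by an activator that accumulates (`a(t) = k t`) or a repressor
that decays (`r(t) = N e^(-mu t)`) through a Hill rate law
`f+(a) = alpha a^H/(a^H + K^H)`, `f-(r) = alpha K^H/(r^H + K^H)` — shapes
the mean and variance of the crossing time.

The core conventions: the maximal rate `alpha` is always calibrated so the
mean FPT equals a target time `t*`, and variance is reported as the scaled
variance `var * x*/t*^2`, which is exactly 1 for unregulated (constitutive)
production — the gamma law with mean `x*/alpha` and variance `x*/alpha^2`.
Scaled variance below 1 means regulation buys precision.

What the package provides:

* **Exact solver** (`build_generator`, `fpt_moment`, `fpt_stats`,
  `fpt_density`, `calibrate_alpha`, `scan_variance`): the two-species
  master equation with an absorbing boundary at `x*`, FPT moments via
  `<t^m> = (-1)^(m+1) m! V' (M^-1)^(m+1) P(0)` computed by sequential
  block-structured linear solves.
* **Sharp-switch analytics** (`variance_decomposition`,
  `activator_descent`, `repressor_optimum`, `regulator_cost`,
  `variance_vs_rho`): closed-form variance as regulator noise plus target
  noise, optimal-regulation formulas, and cost-constrained
  variance-vs-linearity curves.
* **Stochastic simulator** (`simulate_ensemble`, `ensemble_fpt_stats`,
  `calibrate_alpha_sim`): exact Gillespie kernel with geometric production
  bursts, Poisson initial counts, birth–death regulator dynamics, and
  binomial partitioning at cell division.
* **Scatter pipeline** (`generate_scatter`, `binned_timing_stats`,
  `rho_trapezoid`): estimators for destructive single-cell (smFISH-style)
  cross-sectional data, plus a synthetic-scatter generator.
* **Config/CLI** (`read_config`, `run_config`, `inst/cli/fptreg.R`):
  sectioned text configs, deterministic delimited-text outputs with full
  provenance headers.

## Worked example

A repressor with `N = 15` molecules decaying at `mu t* = 2.75`, switching
the target off above `K = 2.6` with `H = 1`; threshold `x* = 15` at target
time `t* = 1`:

```r
library(fptreg)

spec <- system_spec(
  regulator_spec(mu = 2.75, n0 = 15),
  regulation_spec("repressor", alpha = NA, K = 2.6, H = 1),
  x_star = 15, t_star = 1)

spec <- calibrated_spec(spec)   # set alpha so the mean FPT equals t*
spec$regulation$alpha
#> [1] 34.08994

fpt_stats(spec)
#> <fpt_result> mean = 1, var = 0.0363844, scaled var (var*x*/t*^2) = 0.545766

ens <- simulate_ensemble(spec, n_runs = 50000, seed = 7)
ensemble_fpt_stats(ens)
#> <fpt_result> mean = 1.00061, var = 0.0365121, scaled var (var*x*/t*^2) = 0.547682
#>   standard errors: mean 0.000854543, var 0.000242121 (50000/50000 runs crossed)
```

Reading: the exact solver says this repressor timer crosses with scaled
variance 0.55 — about half the timing noise of an unregulated gene with
the same mean crossing time (scaled variance 1) — and a 50,000-run
Gillespie ensemble reproduces it within one standard error. The maximal
rate needed is `alpha = 34.1` molecules per `t*`, versus 15 for the
unregulated gene: precision is bought with extra production capacity and
with regulator molecules (`regulator_cost(spec$regulator, 1)` gives the
time-averaged repressor count, 5.1).

The same system from the shell:

```sh
Rscript inst/cli/fptreg.R fpt --config inst/extdata/repressor_example.ini --out out/
cat out/fpt_summary.txt
```

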