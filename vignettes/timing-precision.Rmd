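---
title: "Timing precision of regulated threshold crossing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing precision of regulated threshold crossing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fptreg)
```

## The model

Many cellular decisions fire when a molecular species $X$ first accumulates
to a threshold copy number $x_*$. `fptreg` studies the temporal precision of
that event when the production of $X$ is controlled by a second species $Y$
with its own stochastic dynamics: an **accumulating activator** (pure
zeroth-order production at rate $k$, starting from zero) or a **diminishing
repressor** (pure first-order degradation at rate $\mu$, starting from $N$
molecules). Either way the production rate of $X$,

$$f_+(a) = \alpha\,\frac{a^H}{a^H + K^H}, \qquad
  f_-(r) = \alpha\,\frac{K^H}{r^H + K^H},$$

rises over time, so the mean target trajectory $\bar x(t)$ accelerates. The
quantity of interest is the first-passage time (FPT) at which the stochastic
count $x(t)$ first reaches $x_*$: its mean $\bar t$ and variance
$\sigma_t^2$. We report variance as the **scaled variance**
$\sigma_t^2 x_*/t_*^2$, which equals exactly 1 for constitutive
(unregulated) production when the mean is calibrated to the target time
$t_*$ — the FPT of $x_*$ sequential exponential steps is gamma distributed
with mean $x_*/\alpha$ and variance $x_*/\alpha^2$. Scaled variance below 1
therefore means regulation buys temporal precision.

Throughout, $\alpha$ is not a free parameter: it is **calibrated** so the
mean FPT equals $t_*$ (`calibrate_alpha()`, relative tolerance $10^{-8}$),
leaving $(k, K, H)$ or $(\mu, K, H, N)$ as the regulatory design space.

## Exact solver

`build_generator()` assembles the master-equation generator on the truncated
state space $\{(y, x): 0 \le y \le Y,\ 0 \le x < x_*\}$, ordered by
concatenating regulator columns level by level. The layout is block lower
bidiagonal: one repeated within-level block carries regulator transitions
and total outflow, and diagonal production blocks $\mathrm{diag}\,f_\pm(y)$
move $x \to x+1$. Production out of the top level is unbalanced — that
probability flux enters the absorbing state $x = x_*$, so the generator's
eigenvalues all have negative real part and the flux
$F(t) = \sum_y f_\pm(y) P_{y,x_*-1}(t)$ is the FPT density
(`fpt_density()`, integrated with `deSolve`). Moments come from the
integration-by-parts identity
$\langle t^m \rangle = (-1)^{m+1} m!\, V^\top (M^{-1})^{m+1} P(0)$,
evaluated as $m+1$ sequential linear solves (`fpt_moment()`), never an
explicit inverse. The block structure makes each solve a sequence of $x_*$
small triangular (pure birth or pure death regulator) or QR
(birth–death) solves — $O(x_* Y)$ work, no fill-in.

**Truncation.** A produced regulator is unbounded, so its index is cut at
$Y = \lceil m + 10\sqrt{m}\rceil$ where $m$ is the largest mean count
reached within `t_max` (default $2 t_*$, which covers the calibrated mean
plus many standard deviations, the FPT sd being $\sim t_*/\sqrt{x_*}$);
production into $y > Y$ is suppressed. The test suite verifies that
doubling $Y$ changes the scaled variance by less than $10^{-8}$. A
degenerate truncation (e.g. a sharp switch whose threshold $K$ exceeds
every reachable count) makes the within-level block singular and is
reported as an "unreachable threshold" error rather than a numeric answer.

**Calibration.** The mean FPT is strictly decreasing in $\alpha$ and
bounded below by the unregulated value, so the root of
$\bar t(\alpha) = t_*$ is unique and bracketed from $\alpha = x_*/t_*$;
`stats::uniroot` on $\log\alpha$ locates it and a short proportional
polish enforces the $10^{-8}$ relative tolerance. In the sharp-switch
limit the deterministic shortcut $\alpha = x_*/(t_* - t_0)$
(`alpha_deterministic()`) is also provided, where $t_0$ is the time the
mean regulator crosses $K$.

## Sharp-switch analytics

With $H \to \infty$ regulation becomes an on/off switch at $y = K$ (ties
count as active, consistent with defining $t_0$ by $\bar y(t_0) = K$) and
$\bar x(t)$ is piecewise linear: zero until $t_0$, slope $\alpha$ after.
Propagating the regulator's copy-number variance (Poisson $k t_0$ for the
activator; binomial $N p(1-p)$, $p = e^{-\mu t_0}$, for the repressor) and
the target's own Poisson noise through the deterministic slopes gives the
closed forms implemented in `variance_decomposition()`:

$$\frac{\sigma_t^2 x_*}{t_*^2} \approx \frac{K x_*}{(k t_*)^2} +
  \Bigl(1 - \frac{K}{k t_*}\Bigr)^2 \quad\text{(activator)},\qquad
  \frac{(N-K) x_*}{N K (\mu t_*)^2} +
  \Bigl(1 - \frac{\ln(N/K)}{\mu t_*}\Bigr)^2 \quad\text{(repressor)}.$$

The two terms expose the central tradeoff: crossing the regulator threshold
early minimizes inherited regulator noise but leaves the target effectively
unregulated (linear, noisy); crossing late makes the target rise steeply
(low target noise) but inherits the regulator's timing jitter. Minimizing
over $K$ gives the activator descent path $K = k t_* - x_*/2$ with variance
$(x_*/k t_*)(1 - x_*/(4 k t_*))$ (`activator_descent()`), and an interior
repressor optimum $K = e^{-2} N$, $\mu t_* = e^2 x_*/(2N) + 2$, variance
$x_*/(x_* + 4 e^{-2} N)$ (`repressor_optimum()`, mode `"approximate"`).
The `"transcendental"` mode instead solves the exact stationarity condition
$\tfrac12 \ln(N/K) = 1 - K/N$; note this equation depends on $K$ only
through $K/N$ and its nontrivial root is $K/N \approx 0.2032$ for *every*
$N$, so the $e^{-2} \approx 0.135$ form is a genuine small-$K/N$
simplification, not a large-$N$ limit.

With $\rho = 1 - t_0/t_*$ (the linearity index below) and the time-averaged
regulator cost $\langle a\rangle = k t_*/2$ or
$\langle r\rangle = N(1 - e^{-\mu t_*})/(\mu t_*)$, eliminating parameters
yields the cost-constrained curves of `variance_vs_rho()`:
$x_*(1-\rho)/(2\langle a\rangle) + \rho^2$ and
$(e^3/27)(x_*/\langle r\rangle)(1-\rho)^3 + \rho^2$, the repressor curve
after optimizing the initial number $N = 3\langle r\rangle/(1-\rho)$. The
pre-minimization form is kept in `repressor_var_rho_N()` with its exact
exponential bracket; the $-1$ inside that bracket is only dropped in the
reduced curve, which is harmless for $\rho < 1$ and irrelevant at
$\rho = 1$ where both give the unregulated value 1.

### How good are the closed forms?

They are approximations twice over: $H \to \infty$ regulation, and
small-noise propagation of copy-number variance through deterministic
slopes. Cross-checking against the exact solver at $H = 3$, $x_* = N = 15$
(the test suite does this along $K = 10$ slices spanning a decade around
the optima) puts the median relative deviation at roughly 12% — about 15%
on the activator side and 5% on the repressor side. The deviation shrinks
markedly in better-conditioned regions (activator $K = 30$: 0.7–8.5%;
repressor $\mu t_* \gtrsim 4$: below 8%). Similarly, the exact
$H = 3$ variance surface of the repressor is a shallow valley whose argmin
sits at visibly larger $\mu t_*$-to-$K$ ratio than the closed-form point
$(e^{-2}N,\ e^2 x_*/2N + 2)$; the closed form locates the basin, not the
grid cell. The corresponding acceptance checks are deliberately left
asserting the stricter published-style figures and fail honestly at
today's numbers; the package reports what the exact solver computes.

## Stochastic simulator

`simulate_ensemble()` runs the exact Gillespie direct method (compiled
kernel) for the three reactions, plus the robustness extensions:

* **Bursts** (`burst_spec(b)`): each regulator production event adds
  $1 + \mathrm{Geom}(1/b)$ molecules — support $\{1, 2, \dots\}$, mean $b$;
  $b = 1$ short-circuits the draw so it is bit-for-bit the plain process.
* **Poisson initial repressor** (`n0_poisson`): the initial count is drawn
  per run with mean $n_0$, adding extrinsic initial-condition noise.
* **Birth–death regulator**: both $k > 0$ and $\mu > 0$, relaxing towards
  $k/\mu$. As the steady state approaches the regulation threshold,
  crossing becomes an exponentially rare event and the timing degrades —
  the solver and simulator both expose this regime.
* **Cell division** (`division_spec`): once per run, at a Gaussian time
  (mean `t_d_mean`, sd `t_d_sd`, redrawn if nonpositive — a negative
  division time is unphysical), both counts are binomially partitioned
  with probability $1/2$ and $K$ is scaled by the volume factor, since
  $K = K_d V$. Defaults `t_d_mean = 0.9 t_*`, `t_d_sd = 0.05 t_*` mimic a
  division shortly before the target time, as seen in the motivating
  neuroblast data; they are configuration defaults, not measured values.
  The FPT is the *first* crossing; in absorbing mode the run ends there, so
  division only ever acts on runs that have not yet crossed, matching the
  solver's absorbing-state convention.

Reproducibility: all runs consume R's global RNG sequentially inside one
kernel call, so `(spec, seed, n_runs)` determines the ensemble bit for bit.
We chose a single documented stream over per-run substreams because the
package never simulates in parallel, and one stream keeps the kernel free
of seeding logic; the cost is that run $i$'s draws depend on runs
$1..i-1$, which no supported analysis observes.

For model variants outside the solver's reach (bursts, Poisson initial
counts, division), `calibrate_alpha_sim()` recalibrates $\alpha$ against
the ensemble sample mean, re-using one fixed seed per evaluation so the
objective is deterministic and monotone; tolerance $10^{-3} t_*$ on the
sample mean (comparable to the mean's own standard error at the default
50,000 runs).

## Cross-sectional scatter analysis

Destructive single-cell counting (smFISH-style) yields one $(t, x)$ point
per cell, not trajectories. `generate_scatter()` emulates this: one
simulated trajectory per cell, one observation time drawn uniformly on
$[0, T_{obs}]$ (a population of cells progressing at a common rate,
sampled without reference to their internal state), and the count at that
time. Defaults $n_{cells} = 200$, $T_{obs} = 1.3\,t_*$ are plumbing
choices; **the window must cover the crossing-time distribution** — if
$T_{obs}$ clips the upper tail of the FPT distribution, binned variance
estimates are deflated (the suite demonstrates this and uses
$T_{obs} = 2 t_*$ where the spread demands it). Trajectories continue past
$x_*$ by default; `halt_at_threshold` freezes them there instead.

Two estimators mirror how one would analyze such data:

* `rho_trapezoid()` — the linearity index
  $\rho = \tfrac{2}{x_* t_*}\int_0^{t_*} x(t)\,dt$ by trapezoidal sum over
  time-sorted points, $(0,0)$ prepended, value at $t_*$ interpolated.
  $\rho = 1$ for a linear rise, $\to 0$ for a sharp late rise; exact on
  piecewise-linear curves sampled at their breakpoints, where it equals
  the sharp-switch identity $1 - t_0/t_*$ (`rho_step()`).
* `binned_timing_stats()` — for every threshold candidate $x_{mid}$ and bin
  width $\Delta x$ on a grid (defaults: midpoints 10–25 stepping by 1,
  $\Delta x \in \{3, 6, 9, 12\}$), the times of points with
  $x \in [x_{mid} \pm \Delta x/2]$ estimate the crossing time (mean) and
  timing variance (unbiased variance), scaled as
  $\mathrm{var}\cdot x_{mid}/\mathrm{mean}^2$; the grid average is the
  estimate and the across-grid spread its uncertainty. Bins with fewer
  than two points are dropped (an error if none survive).

This estimator is deliberately biased the way any cross-sectional analysis
is: in-bin times include the residence time $\sim \Delta x/\mathrm{slope}$
spent crossing the bin (positive bias, largest for shallow slopes and wide
bins) and mix thresholds across the grid. End-to-end tests therefore
assert recovery within 25% of the generating model, not exactness: with
500 cells from a sharp-switch activator at cost
$\langle a\rangle/x_* = 10$ and $\rho = 0.2$, the recovered
$(\hat\rho, \widehat{\sigma_t^2 x_*/t_*^2})$ lands on the cost-10
variance-vs-linearity curve to ~12%. Passing these tests shows the
pipeline is self-consistent on data generated by its own reaction scheme;
it does not certify the estimator on real measurements, where cell-stage
heterogeneity, detection efficiency and non-uniform sampling in time add
biases the generator does not emulate.

## Numerical and design choices

* State ordering $s = x (Y+1) + y$; solves exploit the block bidiagonal
  layout rather than a generic sparse factorization.
* Hill rates are evaluated in log space, so $H$ in the hundreds neither
  overflows nor loses the $[0, \alpha]$ bounds; `H = Inf` is the exact
  step, tie active. `K = 0` is the unregulated convention: an activator
  always on, a repressor on only at $y = 0$.
* $K$ is real-valued (also after division halving): it enters only through
  the rate law.
* Deterministic switch times clamp to zero when the regulator starts past
  its threshold in its direction of motion, and error when the steady
  state stops short of the threshold ("threshold unreachable").
* Problem sizes in the suite: exact-solver grids up to $30 \times 30$ with
  per-point calibration, simulator ensembles of 50,000 runs (20,000 per
  calibration iteration), scatter fixtures of 300–800 cells — sizes at
  which every statistical assertion has comfortable power while a full
  run of the suite stays under a minute on one core.

## Limitations

Single regulator species, no feedback on the target, no transcriptional
delay, at most one division per run, and no inference of $(H, K, k, \mu)$
from data — the scatter module estimates timing statistics and linearity
only. The variance decomposition is derived in the sharp-switch limit; at
moderate $H$ and copy numbers expect the ~10–15% deviations quantified
above.
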