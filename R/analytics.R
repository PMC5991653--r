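#' Mean regulator dynamics
#'
#' Deterministic mean copy number of the regulator: `k * t` for the pure
#' accumulating activator, `n0 * exp(-mu t)` for the pure decaying repressor,
#' and the exponential relaxation `k/mu + (n0 - k/mu) exp(-mu t)` when both
#' production and degradation are present (steady state `k/mu`).
#'
#' @param reg A [regulator_spec()].
#' @param t Time(s), `>= 0` (vectorized).
#' @return Mean copy number(s).
#' @export
mean_regulator <- function(reg, t) {
  stopifnot(inherits(reg, "regulator_spec"))
  if (any(t < 0)) stop("t must be >= 0")
  if (reg$mu == 0) return(reg$n0 + reg$k * t)
  ss <- reg$k / reg$mu
  ss + (reg$n0 - ss) * exp(-reg$mu * t)
}

#' Deterministic threshold-crossing time of the regulator
#'
#' The time `t0` at which the mean regulator count equals the half-maximal
#' number `K`: `K / k` for the accumulating activator and
#' `log(n0 / K) / mu` for the decaying repressor (clamped at 0 when the
#' regulator starts at or past its threshold). For a birth-death regulator
#' the exponential relaxation is inverted in closed form; if the steady
#' state lies on the wrong side of `K` the threshold is never reached and
#' an error is raised — approaching that regime makes threshold crossing an
#' exponentially rare event.
#'
#' @param reg A [regulator_spec()].
#' @param K Threshold copy number (real `>= 0`).
#' @return The crossing time `t0 >= 0`.
#' @export
threshold_time_t0 <- function(reg, K) {
  stopifnot(inherits(reg, "regulator_spec"), length(K) == 1L, K >= 0)
  if (reg$mu == 0) {
    if (K <= reg$n0) return(0)
    if (reg$k == 0) stop("threshold unreachable: regulator neither produced nor above K")
    return((K - reg$n0) / reg$k)
  }
  # y(t) = ss + (n0 - ss) exp(-mu t): exponential relaxation towards ss
  ss <- reg$k / reg$mu
  n0 <- reg$n0
  increasing <- n0 < ss
  # already past K relative to the direction of motion: switch time is 0
  if (increasing && n0 >= K) return(0)
  if (!increasing && n0 <= K) return(0)
  if (increasing && ss <= K)
    stop("threshold unreachable: regulator steady state k/mu does not exceed K")
  if (!increasing && ss >= K)
    stop("threshold unreachable: regulator steady state k/mu does not fall below K")
  ratio <- (K - ss) / (n0 - ss)     # in (0, 1)
  -log(ratio) / reg$mu
}

#' Deterministic mean target dynamics
#'
#' Two closed-form regimes are available. In `"step"` mode (sharp-switch
#' regulation) the mean target count is piecewise linear: zero until the
#' regulator crosses its threshold at `t0`, then rising with slope `alpha`.
#' In `"hill1"` mode (Hill coefficient `H = 1`) the mean-field equation
#' `dx/dt = f(ybar(t))` integrates to
#' `alpha t - (alpha K / k) log((k t + K) / K)` for the activator and
#' `(alpha / mu) log((N + K e^(mu t)) / (N + K))` for the repressor.
#'
#' @param spec A [system_spec()] with `alpha` set.
#' @param t Time(s), `>= 0` (vectorized).
#' @param mode `"step"` or `"hill1"`.
#' @return Mean target count(s).
#' @export
mean_target <- function(spec, t, mode = c("step", "hill1")) {
  mode <- match.arg(mode)
  if (any(t < 0)) stop("t must be >= 0")
  alpha <- spec$regulation$alpha
  if (is.na(alpha)) stop("alpha is uncalibrated")
  K <- spec$regulation$K
  r <- spec$regulator
  if (mode == "step") {
    t0 <- threshold_time_t0(r, K)
    return(ifelse(t < t0, 0, alpha * (t - t0)))
  }
  if (is.finite(spec$regulation$H) && spec$regulation$H != 1)
    stop("configuration error: hill1 mode requires H = 1")
  if (spec$regulation$sign == "activator") {
    if (r$mu != 0 || r$n0 != 0) stop("hill1 activator form assumes pure production from 0")
    if (K == 0) return(alpha * t)
    alpha * t - (alpha * K / r$k) * log((r$k * t + K) / K)
  } else {
    if (r$k != 0) stop("hill1 repressor form assumes pure degradation")
    N <- r$n0
    (alpha / r$mu) * log((N + K * exp(r$mu * t)) / (N + K))
  }
}

#' Sharp-switch linearity index
#'
#' For piecewise-linear mean dynamics the linearity index reduces to
#' `rho = 1 - t0 / t_star`: the fraction of the target window during which
#' the target is actually being produced. The trapezoidal estimator
#' [rho_trapezoid()] agrees with this identity exactly on piecewise-linear
#' curves.
#'
#' @param spec A [system_spec()].
#' @return `rho` in `[0, 1]`.
#' @export
rho_step <- function(spec) {
  t0 <- threshold_time_t0(spec$regulator, spec$regulation$K)
  1 - t0 / spec$t_star
}

#' Sharp-switch variance decomposition
#'
#' Closed-form approximation to the scaled timing variance in the step
#' (`H = Inf`) limit, as the sum of two noise sources propagated through the
#' deterministic slopes: regulator noise (uncertainty in when the regulator
#' crosses `K`; Poisson variance `k t0` for the activator, binomial variance
#' `N p (1 - p)` with `p = exp(-mu t0)` for the repressor) and target noise
#' (Poisson counting noise of the target itself, variance
#' `alpha (t_star - t0)`). With the sharp-switch calibration
#' `alpha = x_star/(t_star - t0)` this gives, as scaled variance,
#' `K x*/(k t*)^2 + (1 - K/(k t*))^2` for the activator and
#' `(N - K) x* / (N K (mu t*)^2) + (1 - log(N/K)/(mu t*))^2` for the
#' repressor.
#'
#' @param spec A [system_spec()] for a pure activator or pure repressor.
#' @return A list with `regulator_term`, `target_term` and their sum
#'   `scaled_var`.
#' @export
variance_decomposition <- function(spec) {
  K <- spec$regulation$K
  xs <- spec$x_star; ts <- spec$t_star
  r <- spec$regulator
  t0 <- threshold_time_t0(r, K)
  if (t0 >= ts) stop("infeasible: deterministic switch time t0 >= t_star")
  if (is_pure_activator(spec) && r$k > 0 && r$n0 == 0) {
    kt <- r$k * ts
    reg_term <- K * xs / kt^2
    tar_term <- (1 - K / kt)^2
  } else if (is_pure_repressor(spec)) {
    N <- r$n0
    if (K <= 0 || K > N) stop("repressor decomposition requires 0 < K <= N")
    mt <- r$mu * ts
    reg_term <- (N - K) * xs / (N * K * mt^2)
    tar_term <- (1 - log(N / K) / mt)^2
  } else {
    stop("variance decomposition is defined for the pure activator and pure repressor")
  }
  list(regulator_term = reg_term, target_term = tar_term,
       scaled_var = reg_term + tar_term)
}

#' Optimal half-maximal number along the activator descent path
#'
#' Minimizing the sharp-switch activator variance over `K` at fixed
#' `k t_star` gives `K = 0` (no benefit from regulation) when
#' `k t_star < x_star / 2`, and `K = k t_star - x_star / 2` otherwise; the
#' variance along this path is 1 on the first branch and
#' `(x*/(k t*)) (1 - x*/(4 k t*))` on the second, decreasing towards zero
#' as `k t_star` grows. The two branches agree (variance 1) at the joint
#' `k t_star = x_star / 2`.
#'
#' @param k_t_star Dimensionless activator accumulation `k * t_star`
#'   (vectorized, `> 0`).
#' @param x_star Target threshold.
#' @return A data frame with columns `k_t_star`, `K`, `scaled_var`.
#' @export
activator_descent <- function(k_t_star, x_star) {
  if (any(k_t_star <= 0)) stop("k_t_star must be > 0")
  low <- k_t_star < x_star / 2
  K <- ifelse(low, 0, k_t_star - x_star / 2)
  v <- ifelse(low, 1, (x_star / k_t_star) * (1 - x_star / (4 * k_t_star)))
  data.frame(k_t_star = k_t_star, K = K, scaled_var = v)
}

#' Optimal repressor parameters
#'
#' The sharp-switch repressor variance has an interior minimum in
#' `(K, mu t_star)`. In `"approximate"` mode (the `K << N` limit) the
#' optimum is `K = exp(-2) N`, `mu t_star = e^2 x_star / (2 N) + 2`, with
#' minimal scaled variance `x_star / (x_star + 4 exp(-2) N)`. In
#' `"transcendental"` mode the stationarity condition
#' `(1/2) log(N / K) = 1 - K / N` is solved numerically (the equation
#' depends on `K` only through `K / N`; its nontrivial root is
#' `K / N ~= 0.2032`) and `mu t_star = log(N/K) + x_star / (2 K)` is
#' back-substituted, with the variance evaluated from
#' [variance_decomposition()].
#'
#' @param N Initial repressor copy number (`>= 1`).
#' @param x_star Target threshold.
#' @param mode `"approximate"` or `"transcendental"`.
#' @return A list with `K`, `mu_t_star`, `scaled_var`.
#' @export
repressor_optimum <- function(N, x_star, mode = c("approximate", "transcendental")) {
  mode <- match.arg(mode)
  if (N < 1) stop("N must be >= 1")
  if (mode == "approximate") {
    K <- exp(-2) * N
    mt <- exp(2) * x_star / (2 * N) + 2
    v <- x_star / (x_star + 4 * exp(-2) * N)
    return(list(K = K, mu_t_star = mt, scaled_var = v))
  }
  g <- function(c) 0.5 * log(1 / c) - (1 - c)   # c = K/N; root below the trivial c = 1
  root <- stats::uniroot(g, lower = 1e-12, upper = 0.5, tol = 1e-14)
  if (abs(g(root$root)) > 1e-8) stop("no root of the stationarity condition in (0, N)")
  K <- root$root * N
  mt <- log(N / K) + x_star / (2 * K)
  sp <- system_spec(regulator_spec(mu = mt, n0 = round(N)),
                    regulation_spec("repressor", alpha = NA, K = K, H = Inf),
                    x_star = x_star, t_star = 1)
  v <- variance_decomposition(sp)$scaled_var
  list(K = K, mu_t_star = mt, scaled_var = v)
}

#' Time-averaged regulator cost
#'
#' The mean number of regulator molecules present over the target window,
#' `(1/t_star) * integral of ybar(t) over [0, t_star]`: `k t_star / 2` for
#' the accumulating activator and `(N / (mu t_star)) (1 - exp(-mu t_star))`
#' for the decaying repressor (approaching `N` as `mu t_star -> 0` and
#' `N / (mu t_star)` for a fast-decaying repressor). Temporal precision
#' improves with this cost.
#'
#' @param reg A [regulator_spec()].
#' @param t_star Target time (`> 0`).
#' @return The time-averaged copy number.
#' @export
regulator_cost <- function(reg, t_star) {
  stopifnot(inherits(reg, "regulator_spec"))
  if (t_star <= 0) stop("t_star must be > 0")
  if (reg$mu == 0) return(reg$n0 + reg$k * t_star / 2)
  if (reg$k == 0) {
    mt <- reg$mu * t_star
    return(reg$n0 / mt * (1 - exp(-mt)))
  }
  ss <- reg$k / reg$mu
  mt <- reg$mu * t_star
  ss + (reg$n0 - ss) * (1 - exp(-mt)) / mt
}

#' Scaled variance as a function of linearity and cost
#'
#' Minimal sharp-switch scaled timing variance at a given linearity index
#' `rho` and regulator cost: `x_star (1 - rho) / (2 <a>) + rho^2` for the
#' activator, and `(e^3 / 27) (x_star / <r>) (1 - rho)^3 + rho^2` for the
#' repressor, where the initial repressor number has been optimized away
#' internally (`N = 3 <r> / (1 - rho)`). Both curves equal 1 at `rho = 1`
#' (the unregulated endpoint) and decrease with increasing cost at any
#' fixed `rho < 1`.
#'
#' @param regime `"activator"` or `"repressor"`.
#' @param rho Linearity index in `(0, 1]` (vectorized).
#' @param cost Time-averaged regulator number `<a>` or `<r>` (`> 0`).
#' @param x_star Target threshold.
#' @return Scaled variance value(s).
#' @export
variance_vs_rho <- function(regime = c("activator", "repressor"), rho, cost, x_star) {
  regime <- match.arg(regime)
  if (any(rho <= 0 | rho > 1)) stop("rho must be in (0, 1]")
  if (cost <= 0) stop("cost must be > 0")
  if (regime == "activator") {
    x_star * (1 - rho) / (2 * cost) + rho^2
  } else {
    (exp(3) / 27) * (x_star / cost) * (1 - rho)^3 + rho^2
  }
}

#' Repressor variance at fixed linearity, cost and initial number
#'
#' The intermediate sharp-switch repressor variance before optimizing over
#' the initial number `N`:
#' `x* (exp(N (1 - rho) / <r>) - 1) <r>^2 / N^3 + rho^2`. For nonlinear
#' dynamics (`rho < 1`) the `-1` inside the bracket is negligible and
#' dropping it and minimizing over `N` (at `N = 3 <r> / (1 - rho)`) yields
#' the repressor curve of [variance_vs_rho()]; here the exact bracket is
#' kept, which also gives the correct unregulated endpoint at `rho = 1`.
#'
#' @param rho Linearity index in `(0, 1]`.
#' @param cost Time-averaged repressor number `<r>` (`> 0`).
#' @param N Initial repressor number.
#' @param x_star Target threshold.
#' @return Scaled variance value(s).
#' @export
repressor_var_rho_N <- function(rho, cost, N, x_star) {
  if (any(rho <= 0 | rho > 1)) stop("rho must be in (0, 1]")
  x_star * (exp(N * (1 - rho) / cost) - 1) * cost^2 / N^3 + rho^2
}
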