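#' Stochastic simulation of the regulated threshold-crossing scheme
#'
#' Exact (Gillespie direct method) simulation of the reactions: regulator
#' production at rate `k` (incrementing by 1, or by a geometric burst when a
#' [burst_spec()] is given), regulator degradation at rate `mu * y`, and
#' target production at rate `f(y)` given by the regulation function. The
#' first time the target count reaches `x_star` is recorded as the
#' first-passage time; in absorbing mode (the default) the run then stops,
#' matching the absorbing-state convention of the exact solver. With a
#' [division_spec()], each run divides once at a truncated-Gaussian time:
#' both copy numbers are binomially partitioned and `K` is scaled by the
#' volume factor.
#'
#' All runs consume a single R random-number stream in a fixed sequential
#' order, so identical `(spec, burst, division, n_runs, seed)` reproduce the
#' ensemble bit for bit.
#'
#' @param spec A [system_spec()] with `alpha` set.
#' @param burst A [burst_spec()] or `NULL` (equivalent to `b = 1`).
#' @param division A [division_spec()] or `NULL`.
#' @param n_runs Number of independent realizations.
#' @param seed Integer seed.
#' @param t_max Simulation horizon; runs not crossing by `t_max` are flagged,
#'   never silently dropped. Default `4 * t_star`.
#' @param absorb If `TRUE` (default) a run terminates at its first crossing;
#'   if `FALSE` the trajectory continues to `t_max` (used for cross-sectional
#'   observation).
#' @param t_query Optional vector of one observation time per run; the target
#'   count at that time is returned (destructive single-cell sampling).
#' @param t_grid Optional time grid on which ensemble mean trajectories of
#'   regulator and target are accumulated.
#' @return An object of class `trajectory_ensemble`: `fpt_samples` (`NA` for
#'   runs not crossing by `t_max`), `x_at` and `y_at` (if `t_query` given),
#'   `mean_curves` (if `t_grid` given), and the inputs.
#' @export
simulate_ensemble <- function(spec, burst = NULL, division = NULL,
                              n_runs, seed, t_max = 4 * spec$t_star,
                              absorb = TRUE, t_query = NULL, t_grid = NULL) {
  stopifnot(inherits(spec, "system_spec"))
  if (!is.null(burst)) stopifnot(inherits(burst, "burst_spec"))
  if (!is.null(division)) stopifnot(inherits(division, "division_spec"))
  if (is.na(spec$regulation$alpha)) stop("alpha is uncalibrated")
  if (t_max <= spec$t_star) stop("t_max must exceed t_star")
  if (!is.null(t_query) && length(t_query) != n_runs)
    stop("t_query must supply one observation time per run")
  r <- spec$regulator; rg <- spec$regulation
  set.seed(seed)
  res <- ssa_ensemble_cpp(
    k = r$k, mu = r$mu, n0 = as.numeric(r$n0), n0_poisson = r$n0_poisson,
    sign = if (rg$sign == "activator") 1L else -1L,
    alpha = rg$alpha, K = rg$K, H = rg$H,
    x_star = spec$x_star,
    burst_b = if (is.null(burst)) 1 else burst$b,
    has_div = !is.null(division),
    td_mean = if (is.null(division)) 0 else division$t_d_mean,
    td_sd = if (is.null(division)) 0 else division$t_d_sd,
    vol_factor = if (is.null(division)) 1 else division$volume_factor,
    t_max = t_max, absorb = absorb,
    t_query = if (is.null(t_query)) numeric(0) else as.numeric(t_query),
    t_grid = if (is.null(t_grid)) numeric(0) else as.numeric(t_grid),
    n_runs = as.integer(n_runs))
  structure(list(
    fpt_samples = res$fpt,
    x_at = res$x_at,
    y_at = res$y_at,
    mean_curves = if (!is.null(t_grid))
      data.frame(t = t_grid, y = res$mean_y, x = res$mean_x) else NULL,
    n_runs = as.integer(n_runs), seed = as.integer(seed),
    t_max = t_max, spec = spec, burst = burst, division = division),
    class = "trajectory_ensemble")
}

#' @exportS3Method base::print
print.trajectory_ensemble <- function(x, ...) {
  nc <- sum(!is.na(x$fpt_samples))
  cat(sprintf("<trajectory_ensemble> %d runs (seed %d), %d crossed by t_max = %g\n",
              x$n_runs, x$seed, nc, x$t_max))
  invisible(x)
}

#' Draw geometric burst sizes
#'
#' Burst sizes on `{1, 2, ...}` with mean `b`: `1 + G` where `G` is the
#' standard geometric number of failures with success probability `1/b`.
#' `b = 1` degenerates to single molecules. Uses the current R RNG state.
#'
#' @param n Number of draws.
#' @param b Mean burst size (`>= 1`).
#' @return Integer vector of burst sizes, all `>= 1`.
#' @export
draw_burst <- function(n, b) {
  if (b < 1) stop("b must be >= 1")
  if (b == 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / b)
}

#' Apply one cell division to a state
#'
#' Symmetric binomial partitioning: regulator and target counts are each
#' replaced by a `Binomial(count, 1/2)` draw, and the half-maximal number
#' `K` is scaled by the volume factor (since `K = K_d * V`). Uses the
#' current R RNG state.
#'
#' @param state A list with integer counts `y` and `x`.
#' @param regulation A [regulation_spec()].
#' @param division A [division_spec()].
#' @return A list with the updated `state` and `regulation`.
#' @export
apply_division <- function(state, regulation, division) {
  stopifnot(is.list(state), inherits(regulation, "regulation_spec"),
            inherits(division, "division_spec"))
  state$y <- stats::rbinom(1, state$y, 0.5)
  state$x <- stats::rbinom(1, state$x, 0.5)
  regulation$K <- regulation$K * division$volume_factor
  list(state = state, regulation = regulation)
}

#' Sample first-passage statistics of an ensemble
#'
#' Sample mean and unbiased sample variance of the crossing times, with
#' asymptotic standard errors (`sd/sqrt(n)` for the mean; for the variance,
#' `sqrt((m4 - var^2)/n)` from the fourth central moment). Runs that did not
#' cross by `t_max` are excluded from the moments and reported in
#' `n_not_crossed`.
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @return An object of class `fpt_result` carrying `mean_t`, `var_t`,
#'   `scaled_var`, standard errors in `$se`, and crossing counts.
#' @export
ensemble_fpt_stats <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  tt <- ensemble$fpt_samples
  tt <- tt[!is.na(tt)]
  n <- length(tt)
  if (n == 0) stop("no crossings: no run reached x_star by t_max")
  if (n < 2) stop("fewer than two crossings; cannot estimate a variance")
  m <- mean(tt)
  v <- stats::var(tt)
  m4 <- mean((tt - m)^4)
  res <- fpt_result(mean_t = m, var_t = v, spec = ensemble$spec,
                    se = list(mean = sqrt(v / n),
                              var = sqrt(max(m4 - v^2, 0) / n)),
                    n_crossed = n, n_runs = ensemble$n_runs)
  res$n_not_crossed <- ensemble$n_runs - n
  res
}

#' Calibrate `alpha` by stochastic simulation
#'
#' Simulation-based analogue of [calibrate_alpha()] for model variants the
#' exact solver does not cover (bursts, Poisson initial counts, cell
#' division): finds `alpha` such that the ensemble sample mean crossing time
#' equals `t_star`. Every evaluation reuses the same seed, so the objective
#' is a deterministic, monotone-decreasing function of `alpha` and ordinary
#' bracketing applies; the returned `alpha` drives the sample mean within
#' `tol * t_star` of `t_star` on that seed.
#'
#' @inheritParams simulate_ensemble
#' @param n_runs Runs per evaluation (default 50000).
#' @param tol Relative tolerance on the sample mean (default `1e-3`).
#' @param t_max Simulation horizon per run.
#' @return The calibrated `alpha`.
#' @export
calibrate_alpha_sim <- function(spec, burst = NULL, division = NULL,
                                n_runs = 50000, seed, tol = 1e-3,
                                t_max = 6 * spec$t_star) {
  ts <- spec$t_star
  mean_at <- function(alpha) {
    sp <- spec
    sp$regulation$alpha <- alpha
    ens <- simulate_ensemble(sp, burst, division, n_runs = n_runs, seed = seed,
                             t_max = t_max)
    tt <- ens$fpt_samples
    if (anyNA(tt)) stop("calibration run did not cross by t_max; increase t_max")
    mean(tt)
  }
  lo <- spec$x_star / ts          # production rate never exceeds alpha
  g_lo <- mean_at(lo) - ts
  if (abs(g_lo) <= tol * ts) return(lo)
  hi <- 4 * lo
  for (i in 1:60) {
    if (mean_at(hi) - ts < 0) break
    hi <- hi * 2
    if (i == 60) stop("infeasible target time: simulated mean exceeds t_star for all alpha")
  }
  root <- stats::uniroot(function(u) mean_at(exp(u)) - ts,
                         lower = log(lo), upper = log(hi), tol = 1e-6)
  alpha <- exp(root$root)
  m <- mean_at(alpha)
  it <- 0L
  while (abs(m - ts) > tol * ts && it < 25L) {
    alpha <- alpha * m / ts
    m <- mean_at(alpha)
    it <- it + 1L
  }
  if (abs(m - ts) > tol * ts)
    stop("simulation calibration did not reach the requested tolerance")
  alpha
}
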