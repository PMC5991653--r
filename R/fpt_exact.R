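#' State-space truncation for the master-equation solver
#'
#' The generator acts on states `(y, x)` with regulator count `y` in
#' `0..Y` and target count `x` in `0..x_star - 1` (the level `x_star` is the
#' absorbing state and lies outside the vector). For a pure-death repressor
#' the regulator count is bounded by its initial number, `Y = n0`. For a
#' produced regulator the count is unbounded and is truncated at
#' `Y = ceil(m + 10 sqrt(m))` — the largest mean count `m` reached by
#' `t_max` plus ten Poisson standard deviations — with production into
#' `y > Y` suppressed. Results are insensitive to doubling `Y` (tested).
#'
#' @param spec A [system_spec()].
#' @param t_max Largest time scale the truncation must cover; default
#'   `2 * t_star`, which bounds the calibrated mean crossing time plus its
#'   spread for all systems of interest.
#' @return An object of class `state_space` with elements `Y`, `t_max`,
#'   `n_states`.
#' @export
state_space <- function(spec, t_max = NULL) {
  stopifnot(inherits(spec, "system_spec"))
  if (is.null(t_max)) t_max <- 2 * spec$t_star
  r <- spec$regulator
  if (r$k == 0) {
    Y <- r$n0
  } else {
    m <- if (r$mu == 0) r$k * t_max else max(r$n0, r$k / r$mu)
    Y <- ceiling(m + 10 * sqrt(max(m, 1)))
    Y <- max(Y, r$n0)
  }
  if (Y < 0) stop("configuration error: negative regulator truncation")
  structure(list(Y = as.integer(Y), t_max = t_max,
                 n_states = as.integer(spec$x_star * (Y + 1L))),
            class = "state_space")
}

#' Build the absorbing-boundary generator matrix
#'
#' Assembles the master-equation generator for the joint process
#' `(y, x)` with the target level `x_star` absorbing. States are ordered
#' `s = x * (Y + 1) + y` (the probability array concatenated by target
#' level). The block layout is lower bidiagonal: identical diagonal blocks
#' `M1` hold the regulator birth/death transitions and the total outflow,
#' and subdiagonal blocks `M2 = diag(f(y))` carry target production
#' `x -> x + 1`. Production out of the top block-column is not balanced —
#' that flux enters the absorbing state, so probability leaks and all
#' eigenvalues of the generator have negative real part.
#'
#' @param spec A [system_spec()] with a finite calibrated `alpha`.
#' @param truncation A [state_space()]; default `state_space(spec)`.
#' @return An object of class `generator_matrix`: a list with the sparse
#'   generator `M`, the dense within-level block `M1`, the production rates
#'   `f` (`f(0..Y)`), the block kind (`"lower"`, `"upper"` or `"general"`),
#'   `Y`, `x_star` and the initial regulator count `y0`.
#' @export
build_generator <- function(spec, truncation = state_space(spec)) {
  stopifnot(inherits(spec, "system_spec"), inherits(truncation, "state_space"))
  if (is.na(spec$regulation$alpha))
    stop("alpha is uncalibrated; run calibrate_alpha() first")
  Y <- truncation$Y
  if (Y < 0 || spec$x_star < 1) stop("configuration error: Y < 0 or x_star < 1")
  r <- spec$regulator
  n1 <- Y + 1L
  y <- 0:Y
  f <- regulation_rate(spec$regulation, y)

  # within-level block M1: regulator moves + total outflow on the diagonal.
  # Production into y > Y is suppressed (truncation), hence the (i < Y) factor.
  prod_on <- if (r$k > 0) as.numeric(y < Y) else numeric(n1)
  diag_entries <- -(r$k * prod_on + r$mu * y + f)
  M1 <- diag(diag_entries, n1, n1)
  if (r$k > 0 && Y >= 1) M1[cbind(2:n1, 1:Y)] <- r$k          # y-1 -> y
  if (r$mu > 0 && Y >= 1) M1[cbind(1:Y, 2:n1)] <- r$mu * y[-1] # y+1 -> y
  kind <- if (r$mu == 0) "lower" else if (r$k == 0) "upper" else "general"

  # full sparse generator (needed for time propagation)
  ii <- jj <- vv <- vector("list", 3L)
  idx <- function(x, yy) x * n1 + yy + 1L
  nz <- which(M1 != 0, arr.ind = TRUE)
  xs <- spec$x_star
  blk <- rep(0:(xs - 1L), each = nrow(nz))
  ii[[1]] <- rep(nz[, 1], xs) + blk * n1
  jj[[1]] <- rep(nz[, 2], xs) + blk * n1
  vv[[1]] <- rep(M1[nz], xs)
  if (xs >= 2L) {
    pos <- which(f != 0)
    if (length(pos)) {
      blk2 <- rep(1:(xs - 1L), each = length(pos))
      ii[[2]] <- rep(pos, xs - 1L) + blk2 * n1
      jj[[2]] <- rep(pos, xs - 1L) + (blk2 - 1L) * n1
      vv[[2]] <- rep(f[pos], xs - 1L)
    }
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(xs * n1, xs * n1))

  y0 <- r$n0
  if (y0 > Y) stop("configuration error: initial regulator count exceeds truncation")
  structure(list(M = M, M1 = M1, f = f, kind = kind, Y = Y,
                 x_star = xs, y0 = as.integer(y0), spec = spec),
            class = "generator_matrix")
}

#' @exportS3Method base::print
print.generator_matrix <- function(x, ...) {
  cat(sprintf(
    "<generator_matrix> %d states (x_star = %d levels x Y + 1 = %d), %s blocks\n",
    nrow(x$M), x$x_star, x$Y + 1L, x$kind))
  invisible(x)
}

# Solve M w = b using the block lower-bidiagonal layout: one factorization of
# the within-level block, then forward substitution over target levels.
# Pure-birth / pure-death regulators give triangular M1 (forwardsolve /
# backsolve); birth-death gives a tridiagonal M1 handled by QR.
gen_solve <- function(gen, b) {
  n1 <- gen$Y + 1L
  xs <- gen$x_star
  M1 <- gen$M1
  if (gen$kind != "general") {
    d <- diag(M1)
    if (any(d == 0))
      stop("unreachable threshold: production rate vanishes on an absorbing set of regulator states")
    solve1 <- if (gen$kind == "lower") {
      function(rhs) forwardsolve(M1, rhs)
    } else {
      function(rhs) backsolve(M1, rhs)
    }
  } else {
    qrM <- qr(M1)
    if (qrM$rank < n1)
      stop("unreachable threshold: within-level generator block is singular")
    solve1 <- function(rhs) solve.qr(qrM, rhs)
  }
  w <- numeric(xs * n1)
  prev <- NULL
  for (x in 0:(xs - 1L)) {
    rows <- (x * n1 + 1L):((x + 1L) * n1)
    rhs <- b[rows]
    if (!is.null(prev)) rhs <- rhs - gen$f * prev
    prev <- as.numeric(solve1(rhs))
    w[rows] <- prev
  }
  w
}

# initial probability vector: all mass at (y = n0, x = 0)
initial_vector <- function(gen) {
  p0 <- numeric(gen$x_star * (gen$Y + 1L))
  p0[gen$y0 + 1L] <- 1
  p0
}

# exit-rate row vector: f(y) on the top target level, zeros before
exit_vector <- function(gen) {
  v <- numeric(gen$x_star * (gen$Y + 1L))
  v[((gen$x_star - 1L) * (gen$Y + 1L) + 1L):(gen$x_star * (gen$Y + 1L))] <- gen$f
  v
}

#' Raw first-passage-time moment from the generator
#'
#' Computes `<t^m> = (-1)^(m+1) m! V' (M^-1)^(m+1) P(0)` by `m + 1`
#' sequential linear solves against the sparse block generator; the inverse
#' is never formed. The initial condition places all probability at the
#' initial regulator count with zero target molecules.
#'
#' @param spec A [system_spec()].
#' @param truncation A [state_space()]; default `state_space(spec)`.
#' @param m Moment order, 1 or 2 (higher orders are accepted but unused by
#'   the rest of the package).
#' @return The raw moment `<t^m>` of the first-passage time.
#' @export
fpt_moment <- function(spec, truncation = state_space(spec), m = 1) {
  if (spec$regulator$n0_poisson)
    stop("exact solver requires a fixed initial count (n0_poisson is simulation-only)")
  gen <- build_generator(spec, truncation)
  w <- initial_vector(gen)
  for (j in seq_len(m + 1L)) w <- gen_solve(gen, w)
  (-1)^(m + 1) * factorial(m) * sum(exit_vector(gen) * w)
}

#' Exact first-passage-time statistics
#'
#' Mean, variance and scaled variance `var * x_star / t_star^2` of the
#' threshold-crossing time, from the first two moments of the absorbing
#' master equation. The scaled variance equals 1 for the unregulated
#' (gamma) process when `alpha = x_star / t_star`.
#'
#' @inheritParams fpt_moment
#' @return An object of class `fpt_result` with `mean_t`, `var_t`,
#'   `scaled_var`.
#' @export
fpt_stats <- function(spec, truncation = state_space(spec)) {
  if (spec$regulator$n0_poisson)
    stop("exact solver requires a fixed initial count (n0_poisson is simulation-only)")
  gen <- build_generator(spec, truncation)
  v <- exit_vector(gen)
  w <- gen_solve(gen, initial_vector(gen))
  w <- gen_solve(gen, w)
  m1 <- sum(v * w)
  w <- gen_solve(gen, w)
  m2 <- -2 * sum(v * w)
  fpt_result(mean_t = m1, var_t = m2 - m1^2, spec = spec)
}

# constructor for the result container shared with the simulator
fpt_result <- function(mean_t, var_t, spec, density = NULL, se = NULL,
                       n_crossed = NULL, n_runs = NULL) {
  structure(list(mean_t = mean_t, var_t = var_t,
                 scaled_var = var_t * spec$x_star / spec$t_star^2,
                 x_star = spec$x_star, t_star = spec$t_star,
                 density = density, se = se,
                 n_crossed = n_crossed, n_runs = n_runs),
            class = "fpt_result")
}

#' @exportS3Method base::print
print.fpt_result <- function(x, ...) {
  cat(sprintf("<fpt_result> mean = %g, var = %g, scaled var (var*x*/t*^2) = %g\n",
              x$mean_t, x$var_t, x$scaled_var))
  if (!is.null(x$se))
    cat(sprintf("  standard errors: mean %g, var %g (%d/%d runs crossed)\n",
                x$se$mean, x$se$var, x$n_crossed, x$n_runs))
  invisible(x)
}

#' First-passage-time density on a time grid
#'
#' Propagates the truncated master equation with [deSolve::ode()] and returns
#' the probability flux into the absorbing state,
#' `F(t) = sum_y f(y) P(y, x_star - 1, t)`. Over a long enough window the
#' trapezoidal integral of `F` approaches 1 (the crossing happens almost
#' surely, up to truncation tolerance).
#'
#' @inheritParams fpt_moment
#' @param t_grid Increasing vector of nonnegative times.
#' @param rtol,atol Integration tolerances passed to [deSolve::ode()].
#' @return A data frame with columns `t` and `density`.
#' @export
fpt_density <- function(spec, t_grid, truncation = state_space(spec),
                        rtol = 1e-10, atol = 1e-12) {
  if (any(diff(t_grid) <= 0) || any(t_grid < 0))
    stop("t_grid must be increasing and nonnegative")
  gen <- build_generator(spec, truncation)
  M <- gen$M
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  sol <- deSolve::ode(y = initial_vector(gen), times = times,
                      func = function(t, y, parms) list(as.numeric(M %*% y)),
                      rtol = rtol, atol = atol)
  P <- sol[match(t_grid, times), -1, drop = FALSE]
  v <- exit_vector(gen)
  data.frame(t = t_grid, density = as.numeric(P %*% v))
}

#' Calibrate the maximal production rate
#'
#' Finds the `alpha` for which the exact mean first-passage time equals
#' `t_star`. The mean is strictly decreasing in `alpha` (regulation only
#' scales the production propensity), so the root is unique; it is bracketed
#' starting from the unregulated value `x_star / t_star` (a lower bound,
#' since regulation can only delay production) and located with
#' [stats::uniroot()] on `log(alpha)`.
#'
#' @inheritParams fpt_moment
#' @param tol Relative tolerance on the achieved mean; default `1e-8`.
#' @return The calibrated `alpha` (a scalar).
#' @seealso [calibrated_spec()] which returns the spec with `alpha` set.
#' @export
calibrate_alpha <- function(spec, truncation = state_space(spec), tol = 1e-8) {
  xs <- spec$x_star; ts <- spec$t_star
  t0 <- tryCatch(threshold_time_t0(spec$regulator, spec$regulation$K),
                 error = function(e) NA_real_)
  if (!is.finite(spec$regulation$H) && is.finite(t0) && t0 >= ts)
    stop("infeasible target time: deterministic switch time t0 >= t_star")
  mean_at <- function(alpha) {
    sp <- spec
    sp$regulation$alpha <- alpha
    fpt_stats(sp, truncation)$mean_t
  }
  lo <- xs / ts
  g_lo <- mean_at(lo) - ts
  if (abs(g_lo) <= tol * ts) return(lo)
  if (g_lo < 0) stop("internal error: regulated mean below unregulated bound")
  hi <- if (is.finite(t0) && t0 < ts) 10 * xs / (ts - t0) else 10 * lo
  hi <- max(hi, 2 * lo)
  for (i in 1:60) {
    if (mean_at(hi) - ts < 0) break
    hi <- hi * 2
    if (i == 60) stop("infeasible target time: mean crossing time exceeds t_star for all alpha")
  }
  root <- stats::uniroot(function(u) mean_at(exp(u)) - ts,
                         lower = log(lo), upper = log(hi),
                         tol = .Machine$double.eps^0.5)
  alpha <- exp(root$root)
  # polish to the requested relative tolerance on the mean
  m <- mean_at(alpha)
  it <- 0L
  while (abs(m - ts) > tol * ts && it < 20L) {
    alpha <- alpha * m / ts   # mean is ~ inversely proportional to alpha
    m <- mean_at(alpha)
    it <- it + 1L
  }
  if (abs(m - ts) > tol * ts)
    stop("calibration did not reach the requested tolerance")
  alpha
}

#' Return a spec with `alpha` calibrated to the target time
#'
#' @inheritParams calibrate_alpha
#' @return The input `system_spec` with `regulation$alpha` set.
#' @export
calibrated_spec <- function(spec, truncation = state_space(spec), tol = 1e-8) {
  spec$regulation$alpha <- calibrate_alpha(spec, truncation, tol)
  spec
}

#' Deterministic sharp-switch calibration
#'
#' In the step (`H = Inf`) limit the deterministic target dynamics are
#' piecewise linear: zero before the switch time `t0` and slope `alpha`
#' after. Requiring the mean to reach `x_star` at `t_star` gives
#' `alpha = x_star / (t_star - t0)`; with no regulation (`t0 = 0`) this is
#' the familiar `x_star / t_star`.
#'
#' @param spec A [system_spec()].
#' @return The deterministic `alpha`.
#' @export
alpha_deterministic <- function(spec) {
  t0 <- threshold_time_t0(spec$regulator, spec$regulation$K)
  if (t0 >= spec$t_star)
    stop("infeasible target time: deterministic switch time t0 >= t_star")
  spec$x_star / (spec$t_star - t0)
}

#' Scan the scaled timing variance over a regulatory parameter grid
#'
#' For each grid point the rate parameter and half-maximal number are set,
#' `alpha` is calibrated so the mean crossing time equals `t_star`, and the
#' scaled variance is evaluated with the exact solver. For an accumulating
#' activator the surface decreases towards large `k` and `K`; for a
#' diminishing repressor it has an interior global minimum in `(K, mu t*)`.
#'
#' @param spec A [system_spec()] template; its `k` (or `mu`) and `K` are
#'   overridden at each grid point.
#' @param K_values Values of the half-maximal number `K`.
#' @param rate_t_values Values of the dimensionless rate `k * t_star`
#'   (activator) or `mu * t_star` (repressor).
#' @param rate Which rate the grid varies: `"k"` or `"mu"`.
#' @param t_max Passed to [state_space()].
#' @return A data frame with one row per grid point and columns `K`,
#'   `k_t_star` or `mu_t_star`, `alpha`, `mean_t`, `var_t`, `scaled_var`.
#' @export
scan_variance <- function(spec, K_values, rate_t_values, rate = c("k", "mu"),
                          t_max = NULL) {
  rate <- match.arg(rate)
  grid <- expand.grid(K = K_values, rate_t = rate_t_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- spec
    sp$regulation$K <- grid$K[i]
    if (rate == "k") sp$regulator$k <- grid$rate_t[i] / sp$t_star
    else sp$regulator$mu <- grid$rate_t[i] / sp$t_star
    tr <- state_space(sp, t_max)
    st <- tryCatch({
      sp <- calibrated_spec(sp, tr)
      fpt_stats(sp, tr)
    }, error = function(e) {
      stop(sprintf("grid point K = %g, %s*t_star = %g: %s",
                   grid$K[i], rate, grid$rate_t[i], conditionMessage(e)),
           call. = FALSE)
    })
    data.frame(K = grid$K[i], rate_t = grid$rate_t[i],
               alpha = sp$regulation$alpha, mean_t = st$mean_t,
               var_t = st$var_t, scaled_var = st$scaled_var)
  })
  out <- do.call(rbind, res)
  names(out)[2] <- if (rate == "k") "k_t_star" else "mu_t_star"
  out
}
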