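#' Regulation function specification
#'
#' Describes how the regulator sets the production rate of the target species.
#' The rate law is a Hill function of the regulator copy number `y`:
#' activating, `alpha * y^H / (y^H + K^H)`, or repressing,
#' `alpha * K^H / (y^H + K^H)`. `H = Inf` selects the sharp-switch limit in
#' which production is an on/off function of whether `y` has crossed `K`;
#' a tie (`y == K`) counts as active for both signs, consistent with defining
#' the deterministic switching time by equality of the mean with `K`.
#'
#' @param sign `"activator"` or `"repressor"`.
#' @param alpha Maximal production rate of the target (molecules per unit
#'   time), `>= 0`. May be `NA` to mean "to be calibrated".
#' @param K Half-maximal regulator copy number (real, `>= 0`). `K = 0` is the
#'   unregulated limit: an activator then produces at `alpha` for every `y`,
#'   a repressor only at `y = 0`.
#' @param H Hill coefficient (cooperativity), real `>= 1` or `Inf` for the
#'   step limit.
#' @return An object of class `regulation_spec`.
#' @seealso [regulation_rate()], [regulator_spec()], [system_spec()]
#' @export
#' @examples
#' reg <- regulation_spec("activator", alpha = 2, K = 15, H = 3)
#' regulation_rate(reg, y = 15)  # half-maximal point: alpha / 2
regulation_spec <- function(sign = c("activator", "repressor"), alpha, K, H = 1) {
  sign <- match.arg(sign)
  stopifnot(length(alpha) == 1L, length(K) == 1L, length(H) == 1L)
  if (!is.na(alpha) && alpha < 0) stop("alpha must be >= 0")
  if (is.na(K) || K < 0) stop("K must be >= 0")
  if (is.na(H) || H < 1) stop("H must be >= 1 (Inf for the step limit)")
  structure(list(sign = sign, alpha = as.numeric(alpha), K = as.numeric(K),
                 H = as.numeric(H)),
            class = "regulation_spec")
}

#' Regulator dynamics specification
#'
#' The regulator undergoes zeroth-order production at rate `k` and first-order
#' degradation at per-molecule rate `mu`, starting from `n0` copies. The two
#' canonical cases are the accumulating activator (`k > 0`, `mu = 0`,
#' `n0 = 0`) and the diminishing repressor (`k = 0`, `mu > 0`, `n0 = N > 0`);
#' allowing both `k > 0` and `mu > 0` gives a regulator that relaxes
#' exponentially towards the steady state `k / mu`.
#'
#' @param k Production rate (molecules per unit time, `>= 0`).
#' @param mu Per-molecule degradation rate (per unit time, `>= 0`).
#' @param n0 Initial copy number (integer `>= 0`).
#' @param n0_poisson If `TRUE`, the initial copy number is drawn per
#'   realization from a Poisson distribution with mean `n0` (stochastic
#'   simulation only; the exact solver requires a fixed initial count).
#' @return An object of class `regulator_spec`.
#' @export
regulator_spec <- function(k = 0, mu = 0, n0 = 0, n0_poisson = FALSE) {
  stopifnot(length(k) == 1L, length(mu) == 1L, length(n0) == 1L)
  if (is.na(k) || k < 0) stop("k must be >= 0")
  if (is.na(mu) || mu < 0) stop("mu must be >= 0")
  if (is.na(n0) || n0 < 0 || n0 != round(n0)) stop("n0 must be a nonnegative integer")
  structure(list(k = as.numeric(k), mu = as.numeric(mu), n0 = as.integer(n0),
                 n0_poisson = isTRUE(n0_poisson)),
            class = "regulator_spec")
}

#' Full system specification
#'
#' Bundles the regulator dynamics, the regulation function, the target
#' threshold `x_star` and the target mean crossing time `t_star`. The event of
#' interest is the first time the target copy number reaches `x_star`; the
#' maximal rate `alpha` is conventionally calibrated so that the mean
#' first-passage time equals `t_star` (see [calibrate_alpha()]).
#'
#' @param regulator A [regulator_spec()].
#' @param regulation A [regulation_spec()].
#' @param x_star Target threshold (integer `>= 1`).
#' @param t_star Target mean crossing time (`> 0`).
#' @return An object of class `system_spec`.
#' @export
system_spec <- function(regulator, regulation, x_star, t_star) {
  stopifnot(inherits(regulator, "regulator_spec"),
            inherits(regulation, "regulation_spec"))
  if (is.na(x_star) || x_star < 1 || x_star != round(x_star))
    stop("x_star must be an integer >= 1")
  if (is.na(t_star) || t_star <= 0) stop("t_star must be > 0")
  structure(list(regulator = regulator, regulation = regulation,
                 x_star = as.integer(x_star), t_star = as.numeric(t_star)),
            class = "system_spec")
}

#' Unregulated (constitutive) system
#'
#' Constant-rate production of the target with no regulator: the first-passage
#' time to `x_star` is then gamma distributed with mean `x_star / alpha` and
#' variance `x_star / alpha^2`, so with `alpha = x_star / t_star` the scaled
#' variance `var * x_star / t_star^2` equals exactly 1. This is the baseline
#' against which regulation is judged.
#'
#' @param x_star Target threshold.
#' @param t_star Target time.
#' @param alpha Production rate; defaults to `x_star / t_star`.
#' @return A `system_spec` with a trivial regulator and `K = 0` activation.
#' @export
unregulated_spec <- function(x_star, t_star, alpha = x_star / t_star) {
  system_spec(regulator_spec(k = 0, mu = 0, n0 = 0),
              regulation_spec("activator", alpha = alpha, K = 0, H = 1),
              x_star = x_star, t_star = t_star)
}

#' Production-burst specification
#'
#' Each regulator production event adds a geometrically distributed number of
#' molecules on `{1, 2, ...}` with mean `b`; `b = 1` degenerates to
#' single-molecule events and recovers the simple Poisson production process.
#'
#' @param b Mean burst size (real `>= 1`).
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(b) {
  if (length(b) != 1L || is.na(b) || b < 1) stop("b must be >= 1")
  structure(list(b = as.numeric(b)), class = "burst_spec")
}

#' Cell-division specification
#'
#' A single division event per realization at a time drawn from a Gaussian
#' with mean `t_d_mean` and standard deviation `t_d_sd` (redrawn if
#' nonpositive). At division, regulator and target copy numbers are each
#' replaced by binomial draws with success probability 1/2 (symmetric
#' partitioning) and the half-maximal number `K` is scaled by `volume_factor`,
#' because `K = K_d * V` for dissociation constant `K_d` and cell volume `V`.
#'
#' @param t_d_mean Mean division time (`> 0`).
#' @param t_d_sd Standard deviation of the division time (`>= 0`).
#' @param volume_factor Post-division volume fraction, default `1/2`.
#' @return An object of class `division_spec`.
#' @export
division_spec <- function(t_d_mean, t_d_sd, volume_factor = 0.5) {
  if (length(t_d_mean) != 1L || is.na(t_d_mean) || t_d_mean <= 0)
    stop("t_d_mean must be > 0")
  if (length(t_d_sd) != 1L || is.na(t_d_sd) || t_d_sd < 0)
    stop("t_d_sd must be >= 0")
  if (length(volume_factor) != 1L || is.na(volume_factor) ||
      volume_factor <= 0 || volume_factor > 1)
    stop("volume_factor must be in (0, 1]")
  structure(list(t_d_mean = as.numeric(t_d_mean), t_d_sd = as.numeric(t_d_sd),
                 volume_factor = as.numeric(volume_factor)),
            class = "division_spec")
}

#' Evaluate the regulation rate law
#'
#' Production rate of the target given `y` regulator molecules. With finite
#' `H` this is the Hill function (activating or repressing); with `H = Inf`
#' it is the on/off step at `y = K`, the tie `y == K` counting as active.
#'
#' @param reg A [regulation_spec()].
#' @param y Regulator copy number(s), integer `>= 0` (vectorized).
#' @return Production rate(s) in `[0, alpha]`.
#' @export
regulation_rate <- function(reg, y) {
  stopifnot(inherits(reg, "regulation_spec"))
  if (any(is.na(y)) || any(y < 0)) stop("y must be a nonnegative count")
  alpha <- reg$alpha; K <- reg$K; H <- reg$H
  act <- reg$sign == "activator"
  if (K == 0) {
    # unregulated limit; step-tie convention (y >= K resp. y <= K active)
    return(if (act) rep(alpha, length(y)) else alpha * as.numeric(y <= 0))
  }
  if (!is.finite(H)) {
    return(alpha * as.numeric(if (act) y >= K else y <= K))
  }
  out <- numeric(length(y))
  pos <- y > 0
  if (act) {
    # alpha / (1 + (K/y)^H), evaluated in log space to dodge overflow
    out[pos] <- alpha / (1 + exp(H * (log(K) - log(y[pos]))))
    out[!pos] <- 0
  } else {
    out[pos] <- alpha / (1 + exp(H * (log(y[pos]) - log(K))))
    out[!pos] <- alpha
  }
  out
}

#' @exportS3Method base::print
print.regulation_spec <- function(x, ...) {
  cat(sprintf("<regulation_spec> %s: alpha = %s, K = %g, H = %s\n", x$sign,
              if (is.na(x$alpha)) "(uncalibrated)" else format(x$alpha),
              x$K, if (is.finite(x$H)) format(x$H) else "Inf (step)"))
  invisible(x)
}

#' @exportS3Method base::print
print.regulator_spec <- function(x, ...) {
  cat(sprintf("<regulator_spec> k = %g, mu = %g, n0 = %d%s\n",
              x$k, x$mu, x$n0, if (x$n0_poisson) " (Poisson)" else ""))
  invisible(x)
}

#' @exportS3Method base::print
print.system_spec <- function(x, ...) {
  cat(sprintf("<system_spec> x_star = %d, t_star = %g\n", x$x_star, x$t_star))
  print(x$regulator); print(x$regulation)
  invisible(x)
}

# internal: convenient pure-case predicates
is_pure_repressor <- function(spec) spec$regulator$k == 0 && spec$regulator$mu > 0
is_pure_activator <- function(spec) spec$regulator$mu == 0
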