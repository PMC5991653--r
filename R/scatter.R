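#' Generate synthetic cross-sectional single-cell scatter
#'
#' Emulates destructive single-cell measurement (smFISH-style): each
#' simulated cell contributes exactly one `(observation time, target count)`
#' point. One trajectory is simulated per cell with the stochastic scheme
#' (including optional bursts and cell division), an observation time is
#' drawn uniformly on `[0, t_obs_max]`, and the target count at that time is
#' recorded. Trajectories continue past the threshold by default;
#' `halt_at_threshold = TRUE` freezes the count at `x_star` to mimic
#' saturating expression. Observation times use the given seed and
#' trajectories use `seed + 1` (a fixed spawning rule, so the whole scatter
#' is reproducible from one seed).
#'
#' With `deterministic = TRUE` the points are placed exactly on the
#' deterministic mean curve [mean_target()] (noise-free stand-in mode; the
#' counts are then real-valued).
#'
#' @param spec A [system_spec()] with `alpha` set.
#' @param burst,division Optional [burst_spec()] / [division_spec()].
#' @param n_cells Number of cells (one point each).
#' @param t_obs_max Upper end of the observation window; default
#'   `1.3 * t_star`.
#' @param seed Integer seed.
#' @param deterministic Noise-free mean-curve mode.
#' @param mode Mean-curve regime for deterministic mode (see
#'   [mean_target()]).
#' @param halt_at_threshold Freeze the count at `x_star` once crossed.
#' @return A data frame of class `scatter_data` with columns `t`, `x`, and a
#'   `provenance` attribute.
#' @export
generate_scatter <- function(spec, burst = NULL, division = NULL,
                             n_cells = 200, t_obs_max = 1.3 * spec$t_star,
                             seed, deterministic = FALSE,
                             mode = c("step", "hill1"),
                             halt_at_threshold = FALSE) {
  stopifnot(inherits(spec, "system_spec"), n_cells >= 0)
  mode <- match.arg(mode)
  set.seed(seed)
  t_obs <- stats::runif(n_cells, 0, t_obs_max)
  if (deterministic) {
    x <- mean_target(spec, t_obs, mode = mode)
  } else if (n_cells > 0) {
    ens <- simulate_ensemble(spec, burst, division, n_runs = n_cells,
                             seed = seed + 1L, t_max = t_obs_max,
                             absorb = halt_at_threshold, t_query = t_obs)
    x <- ens$x_at
  } else {
    x <- numeric(0)
  }
  structure(data.frame(t = t_obs, x = x),
            class = c("scatter_data", "data.frame"),
            provenance = list(seed = seed, n_cells = n_cells,
                              t_obs_max = t_obs_max,
                              deterministic = deterministic,
                              halt_at_threshold = halt_at_threshold))
}

#' Trapezoidal linearity index
#'
#' The linearity of a trajectory (or scatter) over the target window,
#' `rho = (2 / (x_star * t_star)) * integral of x(t) dt from 0 to t_star`,
#' i.e. the area under the curve normalized by that of a perfectly linear
#' rise to `x_star` at `t_star`. Computed by a trapezoidal sum over the
#' points sorted by time, with `(0, 0)` prepended and the value at `t_star`
#' obtained by linear interpolation. `rho = 1` for perfectly linear
#' dynamics and `rho -> 0` for a sharp rise at `t_star`; the trapezoidal
#' sum is exact on piecewise-linear curves sampled at their breakpoints.
#'
#' @param data A `scatter_data` / data frame with columns `t`, `x`, or a
#'   numeric vector of times.
#' @param x If `data` is a vector of times, the matching counts.
#' @param x_star Target threshold used for normalization.
#' @param t_star Target time; must lie within the observed time range.
#' @return The scalar `rho`.
#' @export
rho_trapezoid <- function(data, x = NULL, x_star, t_star) {
  if (is.data.frame(data)) {
    t <- data$t; x <- data$x
  } else {
    t <- data
  }
  if (length(t) == 0) stop("empty trajectory")
  o <- order(t)
  t <- t[o]; x <- x[o]
  if (!any(t < t_star)) stop("no points before t_star")
  if (max(t) < t_star) stop("t_star lies outside the observed time range")
  if (t[1] > 0) { t <- c(0, t); x <- c(0, x) }
  x_end <- stats::approx(t, x, xout = t_star, ties = "ordered")$y
  keep <- t < t_star
  tt <- c(t[keep], t_star)
  xx <- c(x[keep], x_end)
  integral <- sum(diff(tt) * (xx[-length(xx)] + xx[-1]) / 2)
  2 * integral / (x_star * t_star)
}

#' Bin grid for threshold-window timing estimation
#'
#' The candidate thresholds and bin widths over which the timing statistics
#' are averaged: bin midpoints `x_star` stepping by `x_star_step` over
#' `x_star_range` and bin widths `dx_values`. The defaults span midpoints
#' 10..25 and widths 3, 6, 9, 12.
#'
#' @param x_star_range Inclusive bounds for candidate threshold midpoints.
#' @param dx_values Bin widths.
#' @param x_star_step Step between midpoints.
#' @return An object of class `bin_config` carrying the `(x_mid, dx)` grid.
#' @export
bin_config <- function(x_star_range = c(10, 25), dx_values = c(3, 6, 9, 12),
                       x_star_step = 1) {
  stopifnot(length(x_star_range) == 2L, x_star_range[1] <= x_star_range[2],
            all(dx_values > 0))
  grid <- expand.grid(x_mid = seq(x_star_range[1], x_star_range[2],
                                  by = x_star_step),
                      dx = dx_values, KEEP.OUT.ATTRS = FALSE)
  structure(list(grid = grid, x_star_range = x_star_range,
                 dx_values = dx_values), class = "bin_config")
}

#' Bin-based timing statistics from cross-sectional scatter
#'
#' For every `(x_mid, dx)` combination the bin
#' `[x_mid - dx/2, x_mid + dx/2]` is applied to the counts, and the mean and
#' unbiased variance of the observation times of the in-bin points estimate
#' the crossing time `t_star` and the timing variance for threshold
#' `x_mid`; the scaled variance is formed as `var * x_mid / mean^2`.
#' Optionally the trapezoidal linearity index is evaluated per combination
#' at `(x_mid, mean_t)`. Final estimates are averages over the grid with
#' the spread across combinations as the reported uncertainty.
#'
#' Note the estimator is cross-sectional: the time spent by a trajectory
#' inside an `x` bin adds a positive bias to the timing variance relative
#' to the true first-passage variance, which is part of what this procedure
#' (deliberately) measures.
#'
#' @param data A `scatter_data` / data frame with columns `t`, `x`.
#' @param cfg A [bin_config()].
#' @param rho If `TRUE`, also estimate the linearity index per combination.
#' @return An object of class `binned_timing`: per-combination table and
#'   aggregate estimates `t_star_est`, `var_est`, `scaled_var_est` (and
#'   `rho_est` if requested), each with the across-grid standard deviation.
#' @export
binned_timing_stats <- function(data, cfg = bin_config(), rho = FALSE) {
  stopifnot(is.data.frame(data), inherits(cfg, "bin_config"))
  if (nrow(data) == 0) stop("empty scatter")
  g <- cfg$grid
  per <- lapply(seq_len(nrow(g)), function(i) {
    lo <- g$x_mid[i] - g$dx[i] / 2
    hi <- g$x_mid[i] + g$dx[i] / 2
    tt <- data$t[data$x >= lo & data$x <= hi]
    if (length(tt) < 2)
      return(data.frame(x_mid = g$x_mid[i], dx = g$dx[i], n = length(tt),
                        mean_t = NA_real_, var_t = NA_real_,
                        scaled_var = NA_real_, rho = NA_real_))
    m <- mean(tt); v <- stats::var(tt)
    r <- if (rho) tryCatch(rho_trapezoid(data, x_star = g$x_mid[i], t_star = m),
                           error = function(e) NA_real_) else NA_real_
    data.frame(x_mid = g$x_mid[i], dx = g$dx[i], n = length(tt),
               mean_t = m, var_t = v, scaled_var = v * g$x_mid[i] / m^2,
               rho = r)
  })
  per <- do.call(rbind, per)
  ok <- !is.na(per$mean_t)
  if (!any(ok)) {
    bad <- paste(sprintf("(x_mid = %g, dx = %g)", per$x_mid, per$dx),
                 collapse = ", ")
    stop("all bins underpopulated (< 2 points): ", bad)
  }
  agg <- function(v) c(est = mean(v[ok]), sd = stats::sd(v[ok]))
  out <- list(per_combo = per,
              n_combos_used = sum(ok),
              t_star_est = agg(per$mean_t)[["est"]],
              t_star_sd = agg(per$mean_t)[["sd"]],
              var_est = agg(per$var_t)[["est"]],
              var_sd = agg(per$var_t)[["sd"]],
              scaled_var_est = agg(per$scaled_var)[["est"]],
              scaled_var_sd = agg(per$scaled_var)[["sd"]])
  if (rho) {
    okr <- ok & !is.na(per$rho)
    out$rho_est <- mean(per$rho[okr])
    out$rho_sd <- stats::sd(per$rho[okr])
  }
  structure(out, class = "binned_timing")
}

#' @exportS3Method base::print
print.binned_timing <- function(x, ...) {
  cat(sprintf(
    "<binned_timing> %d/%d combinations used\n  t* = %g (sd %g)\n  var = %g (sd %g)\n  scaled var = %g (sd %g)\n",
    x$n_combos_used, nrow(x$per_combo), x$t_star_est, x$t_star_sd,
    x$var_est, x$var_sd, x$scaled_var_est, x$scaled_var_sd))
  if (!is.null(x$rho_est))
    cat(sprintf("  rho = %g (sd %g)\n", x$rho_est, x$rho_sd))
  invisible(x)
}

#' Read / write scatter tables
#'
#' Two-column tab-delimited text with a one-line header `t  x`; comment
#' lines start with `#`. Values are written at full double precision.
#'
#' @param path File path.
#' @return `read_scatter` returns a `scatter_data` data frame.
#' @export
read_scatter <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  if (!all(c("t", "x") %in% names(df)))
    stop("scatter file must have columns 't' and 'x'")
  if (any(df$t < 0) || any(df$x < 0)) stop("scatter values must be nonnegative")
  structure(df[, c("t", "x")], class = c("scatter_data", "data.frame"),
            provenance = list(file = path))
}

#' @rdname read_scatter
#' @param data A `scatter_data` / data frame with columns `t`, `x`.
#' @param header_lines Optional provenance comment lines (without the
#'   leading `#`).
#' @export
write_scatter <- function(data, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  writeLines("t\tx", con)
  writeLines(sprintf("%.17g\t%.17g", data$t, as.numeric(data$x)), con)
  invisible(path)
}
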