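test_that("mean regulator dynamics and switch times", {
  act <- regulator_spec(k = 20)
  rep <- regulator_spec(mu = 2.75, n0 = 15)
  expect_equal(mean_regulator(act, 0), 0)
  expect_equal(mean_regulator(act, 1), 20)          # k t* = 20 at t = t*
  expect_equal(mean_regulator(rep, 0), 15)
  expect_equal(mean_regulator(rep, 2), 15 * exp(-5.5))
  expect_error(mean_regulator(act, -0.1), "t must")

  expect_equal(threshold_time_t0(act, 0), 0)
  expect_equal(threshold_time_t0(act, 10), 0.5)
  expect_equal(threshold_time_t0(rep, 2.6), log(15 / 2.6) / 2.75)
  expect_equal(threshold_time_t0(rep, 15), 0)       # starts at its threshold
  # birth-death: the closed form actually solves ybar(t0) = K
  bd <- regulator_spec(k = 40, mu = 2, n0 = 0)      # steady state 20
  t0 <- threshold_time_t0(bd, 10)
  expect_equal(mean_regulator(bd, t0), 10, tolerance = 1e-12)
  expect_error(threshold_time_t0(bd, 25), "unreachable")
  expect_error(threshold_time_t0(regulator_spec(k = 8, mu = 1, n0 = 10), 5),
               "unreachable")                        # decreasing, ss above K
})

test_that("mean target dynamics: piecewise-linear and H = 1 closed forms", {
  sp <- system_spec(regulator_spec(k = 20),
                    regulation_spec("activator", NA, K = 10, H = Inf), 15, 1)
  sp$regulation$alpha <- alpha_deterministic(sp)     # x*/(t* - t0) = 30
  expect_equal(mean_target(sp, c(0, 0.25, 0.5), mode = "step"), c(0, 0, 0))
  expect_equal(mean_target(sp, 1, mode = "step"), 15)   # calibration condition
  expect_equal(mean_target(sp, 0.75, mode = "step"), 30 * 0.25)

  # H = 1 closed forms against direct quadrature of dx/dt = f(ybar(t))
  act <- system_spec(regulator_spec(k = 20),
                     regulation_spec("activator", 25, K = 15, H = 1), 15, 1)
  ode_act <- deSolve::ode(y = 0, times = c(0, 0.4, 1), parms = NULL,
    func = function(t, x, p) list(25 * (20 * t) / (20 * t + 15)),
    rtol = 1e-12, atol = 1e-12)
  expect_equal(mean_target(act, c(0.4, 1), mode = "hill1"), ode_act[2:3, 2],
               tolerance = 1e-8, ignore_attr = TRUE)
  rep <- system_spec(regulator_spec(mu = 2.75, n0 = 15),
                     regulation_spec("repressor", 20, K = 2.6, H = 1), 15, 1)
  ode_rep <- deSolve::ode(y = 0, times = c(0, 0.6, 1.2), parms = NULL,
    func = function(t, x, p)
      list(20 * 2.6 / (15 * exp(-2.75 * t) + 2.6)),
    rtol = 1e-12, atol = 1e-12)
  expect_equal(mean_target(rep, c(0.6, 1.2), mode = "hill1"), ode_rep[2:3, 2],
               tolerance = 1e-8, ignore_attr = TRUE)
  # unregulated limit of the H = 1 activator form
  act0 <- system_spec(regulator_spec(k = 20),
                      regulation_spec("activator", 25, K = 0, H = 1), 15, 1)
  expect_equal(mean_target(act0, 0.7, mode = "hill1"), 25 * 0.7)
  expect_error(mean_target(fig1_activator(H = 3) |> calibrated_spec(),
                           0.5, mode = "hill1"), "H = 1")
})

test_that("sharp-switch variance decomposition equals the propagated noise terms", {
  # independent route: molecule-number variances propagated through the
  # deterministic slopes, with alpha = x*/(t* - t0)
  cases <- list(activator_h3(20, K = 10), activator_h3(35, K = 18),
                repressor_h3(2.75, K = 2.6), repressor_h3(5, K = 3))
  for (sp in cases) {
    r <- sp$regulator; K <- sp$regulation$K
    xs <- sp$x_star; ts <- sp$t_star
    t0 <- threshold_time_t0(r, K)
    alpha <- xs / (ts - t0)
    slope_y <- if (r$mu == 0) r$k else r$mu * r$n0 * exp(-r$mu * t0)
    var_y <- if (r$mu == 0) r$k * t0
             else r$n0 * exp(-r$mu * t0) * (1 - exp(-r$mu * t0))
    expected <- (var_y / slope_y^2 + alpha * (ts - t0) / alpha^2) * xs / ts^2
    vd <- variance_decomposition(sp)
    expect_equal(vd$scaled_var, expected, tolerance = 1e-12)
    expect_equal(vd$scaled_var, vd$regulator_term + vd$target_term)
  }
  # unregulated corner: no regulator noise, pure target (gamma) noise
  vd0 <- variance_decomposition(activator_h3(20, K = 1e-12))
  expect_equal(vd0$regulator_term, 0, tolerance = 1e-10)
  expect_equal(vd0$target_term, 1, tolerance = 1e-10)
  expect_error(variance_decomposition(activator_h3(10, K = 12)), "infeasible")
})

test_that("activator descent path: branches, continuity and monotone descent", {
  xs <- 15
  d <- activator_descent(c(5, 7.5, 10, 20, 40, 1e5), xs)
  expect_equal(d$K, c(0, 0, 2.5, 12.5, 32.5, 1e5 - 7.5))
  expect_equal(d$scaled_var[1:2], c(1, 1))
  # continuity at the joint: second branch evaluated at x*/2 also gives 1
  expect_equal((xs / 7.5) * (1 - xs / (4 * 7.5)), 1)
  path <- activator_descent(seq(7.5, 200, length.out = 100), xs)
  expect_true(all(diff(path$scaled_var) < 0))
  expect_lt(d$scaled_var[6], 1e-3)     # large k t* limit
})

test_that("repressor optimum: closed form, stationarity, transcendental root", {
  N <- 15; xs <- 15
  opt <- repressor_optimum(N, xs, "approximate")
  expect_equal(opt$K, exp(-2) * N)
  expect_equal(opt$mu_t_star, exp(2) * xs / (2 * N) + 2)
  expect_equal(opt$scaled_var, xs / (xs + 4 * exp(-2) * N))
  # consistency: substituting the optimum into the K << N form of the
  # variance (regulator term x*/(K (mu t*)^2)) reproduces the minimum value
  # as an algebraic identity, for any N
  for (Nv in c(15, 200, 4000)) {
    o2 <- repressor_optimum(Nv, xs, "approximate")
    back <- xs / (o2$K * o2$mu_t_star^2) +
      (1 - log(Nv / o2$K) / o2$mu_t_star)^2
    expect_equal(back, o2$scaled_var, tolerance = 1e-12)
  }

  tr <- repressor_optimum(N, xs, "transcendental")
  # the root satisfies its defining stationarity condition ...
  expect_equal(0.5 * log(N / tr$K), 1 - tr$K / N, tolerance = 1e-10)
  # ... which is scale invariant: K/N is the same constant for every N
  expect_equal(tr$K / N, repressor_optimum(500, xs, "transcendental")$K / 500,
               tolerance = 1e-10)
  expect_equal(tr$K / N, 0.203188, tolerance = 1e-5)
  # and it is a genuine stationary point of the full variance formula:
  # central differences in K and mu t* vanish to second order
  h <- 1e-5
  v <- function(K, mt) variance_decomposition(system_spec(
    regulator_spec(mu = mt, n0 = N),
    regulation_spec("repressor", NA, K, Inf), xs, 1))$scaled_var
  expect_lt(abs(v(tr$K + h, tr$mu_t_star) - v(tr$K - h, tr$mu_t_star)) / (2 * h),
            1e-3)
  expect_lt(abs(v(tr$K, tr$mu_t_star + h) - v(tr$K, tr$mu_t_star - h)) / (2 * h),
            1e-3)
})

test_that("regulator cost: time-averaged copy number", {
  expect_equal(regulator_cost(regulator_spec(k = 20), 1), 10)  # k t* / 2
  N <- 15
  expect_equal(regulator_cost(regulator_spec(mu = 1e-9, n0 = N), 1), N,
               tolerance = 1e-6)
  fast <- regulator_cost(regulator_spec(mu = 50, n0 = N), 1)
  expect_equal(fast, N / 50, tolerance = 1e-3)
  # matches direct quadrature of the mean for the birth-death extension
  bd <- regulator_spec(k = 12, mu = 3, n0 = 2)
  tg <- seq(0, 1, length.out = 4001)
  expect_equal(regulator_cost(bd, 1), trapz(tg, mean_regulator(bd, tg)),
               tolerance = 1e-6)
})

test_that("variance vs linearity curves: endpoints, optima, cost ordering", {
  xs <- 15
  expect_equal(variance_vs_rho("activator", 1, 150, xs), 1)
  expect_equal(variance_vs_rho("repressor", 1, 150, xs), 1)
  expect_error(variance_vs_rho("activator", 0, 150, xs), "rho")
  # interior activator minimum at rho = x*/(4 <a>)
  A <- 150
  om <- stats::optimize(function(r) variance_vs_rho("activator", r, A, xs),
                        c(1e-4, 1))
  expect_equal(om$minimum, xs / (4 * A), tolerance = 1e-4)
  # repressor curve at matched cost dips below the unregulated value
  rr <- seq(0.01, 1, length.out = 400)
  expect_lt(min(variance_vs_rho("repressor", rr, 10 * xs, xs)), 1)
  # more regulator molecules, less variance (fixed rho < 1)
  for (regime in c("activator", "repressor")) {
    v_lo <- variance_vs_rho(regime, 0.5, 50, xs)
    v_hi <- variance_vs_rho(regime, 0.5, 500, xs)
    expect_lt(v_hi, v_lo)
  }
  # the pre-minimization repressor form at N = 3<r>/(1 - rho) approaches the
  # reduced curve once the neglected term is immaterial
  r <- 0.4; cost <- 150
  N_opt <- 3 * cost / (1 - r)
  expect_equal(repressor_var_rho_N(r, cost, N_opt, xs),
               variance_vs_rho("repressor", r, cost, xs), tolerance = 1e-2)
  # at rho = 1 the exact bracket gives the unregulated endpoint
  expect_equal(repressor_var_rho_N(1, cost, 100, xs), 1)
})
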