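test_that("degenerate generator: single state, constant rate", {
  sp <- system_spec(regulator_spec(), regulation_spec("activator", 2.5, 0),
                    x_star = 1, t_star = 1)
  gen <- build_generator(sp)
  expect_equal(as.matrix(gen$M), matrix(-2.5, 1, 1), ignore_attr = TRUE)
  st <- fpt_stats(sp)
  expect_equal(st$mean_t, 1 / 2.5)   # single exponential step
  expect_equal(st$var_t, 1 / 2.5^2)
})

test_that("generator matches a hand-enumerated dense matrix (x*=2, Y=2, H=1)", {
  k <- 2; alpha <- 3; K <- 1.5
  sp <- system_spec(regulator_spec(k = k),
                    regulation_spec("activator", alpha, K, H = 1),
                    x_star = 2, t_star = 1)
  tr <- structure(list(Y = 2L, t_max = 1, n_states = 6L), class = "state_space")
  gen <- build_generator(sp, tr)
  f <- alpha * (0:2) / (0:2 + K)
  # states ordered (x, y): (0,0) (0,1) (0,2) (1,0) (1,1) (1,2)
  M1 <- matrix(0, 3, 3)
  diag(M1) <- -(k * c(1, 1, 0) + f)      # production capped at y = Y
  M1[2, 1] <- k; M1[3, 2] <- k
  M_hand <- matrix(0, 6, 6)
  M_hand[1:3, 1:3] <- M1
  M_hand[4:6, 4:6] <- M1
  M_hand[4:6, 1:3] <- diag(f)
  expect_equal(as.matrix(gen$M), M_hand, ignore_attr = TRUE)
  expect_equal(gen$M1, M1)
  # within a block, columns conserve probability up to the f outflow
  expect_equal(colSums(M1), -f, ignore_attr = TRUE)
})

test_that("constant-rate production reproduces the gamma closed form", {
  sp <- unregulated_spec(15, 1)
  st <- fpt_stats(sp)
  expect_equal(st$mean_t, 1, tolerance = 1e-12)
  expect_equal(st$var_t, 15 / 15^2, tolerance = 1e-10)
  expect_equal(st$scaled_var, 1, tolerance = 1e-10)
  expect_equal(st$scaled_var, st$var_t * 15 / 1^2)  # exact identity
})

test_that("moment formula agrees with brute-force time integration of the master equation", {
  # independent oracle: hand-coded master-equation RHS integrated in time,
  # moments accumulated as quadrature states alongside the probabilities
  k <- 5; K <- 3; H <- 1; alpha <- 4; xs <- 3
  Y <- 70
  f <- alpha * (0:Y) / (0:Y + K)
  rhs <- function(t, state, parms) {
    P <- matrix(state[1:(3 * (Y + 1))], nrow = Y + 1)
    outflow <- (k * c(rep(1, Y), 0) + f) * P
    dP <- -outflow
    dP[2:(Y + 1), ] <- dP[2:(Y + 1), ] + k * P[1:Y, ]
    dP[, 2:3] <- dP[, 2:3] + f * P[, 1:2]
    Fx <- sum(f * P[, 3])
    list(c(as.vector(dP), t * Fx, t^2 * Fx))
  }
  init <- c(1, rep(0, 3 * (Y + 1) - 1), 0, 0)
  sol <- deSolve::ode(y = init, times = c(0, 12), func = rhs,
                      rtol = 1e-12, atol = 1e-14)
  m1_oracle <- as.numeric(sol[2, 3 * (Y + 1) + 2])
  m2_oracle <- as.numeric(sol[2, 3 * (Y + 1) + 3])

  sp <- system_spec(regulator_spec(k = k),
                    regulation_spec("activator", alpha, K, H),
                    x_star = xs, t_star = 1)
  expect_equal(fpt_moment(sp, m = 1), m1_oracle, tolerance = 1e-6)
  expect_equal(fpt_moment(sp, m = 2), m2_oracle, tolerance = 1e-6)
})

test_that("first-passage density: gamma special case and conservation", {
  sp <- unregulated_spec(4, 1)
  tg <- seq(0.002, 6, length.out = 500)
  d <- fpt_density(sp, tg)
  expect_equal(d$density, dgamma(tg, shape = 4, rate = 4), tolerance = 1e-8)
  expect_gte(trapz(d$t, d$density), 1 - 1e-6)
  expect_lte(trapz(d$t, d$density), 1 + 1e-6)

  rsp <- calibrated_spec(fig1_repressor())
  tg2 <- seq(0.005, 4.5, length.out = 400)
  d2 <- fpt_density(rsp, tg2)
  expect_gte(trapz(d2$t, d2$density), 1 - 1e-6)
  expect_true(all(d2$density >= -1e-12))
})

test_that("density agrees with the empirical crossing-time distribution", {
  rsp <- calibrated_spec(fig1_repressor())
  n <- 50000
  ens <- simulate_ensemble(rsp, n_runs = n, seed = 101)
  tt <- ens$fpt_samples
  expect_false(anyNA(tt))
  tg <- seq(0.002, 4, length.out = 800)
  d <- fpt_density(rsp, tg)
  cdf_model <- cumsum(c(0, diff(tg) * (d$density[-800] + d$density[-1]) / 2))
  for (q in c(0.5, 0.8, 1, 1.2, 1.5, 2)) {
    p_model <- stats::approx(tg, cdf_model, xout = q)$y
    p_emp <- mean(tt <= q)
    se <- sqrt(p_model * (1 - p_model) / n)
    expect_lt(abs(p_emp - p_model), 4 * se + 1e-4)
  }
})

test_that("calibration: unregulated value, scaling, sharp-switch formula", {
  sp <- unregulated_spec(15, 1, alpha = NA)
  expect_equal(calibrate_alpha(sp), 15)           # alpha = x*/t*
  # doubling alpha halves the unregulated mean
  expect_equal(fpt_stats(unregulated_spec(15, 1, alpha = 30))$mean_t, 0.5,
               tolerance = 1e-12)
  # deterministic sharp-switch calibration alpha = x*/(t* - t0)
  stp <- system_spec(regulator_spec(k = 20),
                     regulation_spec("activator", NA, K = 10, H = Inf), 15, 1)
  expect_equal(alpha_deterministic(stp), 15 / (1 - 0.5))
  a <- calibrate_alpha(stp)
  stp$regulation$alpha <- a
  expect_equal(fpt_stats(stp)$mean_t, 1, tolerance = 1e-7)
})

test_that("results are insensitive to doubling the regulator truncation", {
  sp <- calibrated_spec(activator_h3(20))
  tr <- state_space(sp)
  tr2 <- tr
  tr2$Y <- 2L * tr$Y
  tr2$n_states <- sp$x_star * (tr2$Y + 1L)
  s1 <- fpt_stats(sp, tr)
  s2 <- fpt_stats(sp, tr2)
  expect_equal(s1$mean_t, s2$mean_t, tolerance = 1e-10)
  expect_equal(s1$scaled_var, s2$scaled_var, tolerance = 1e-8)
})

test_that("unreachable thresholds are reported, not silently mangled", {
  # step activator whose switch threshold exceeds the truncated state space
  sp <- system_spec(regulator_spec(k = 2),
                    regulation_spec("activator", 5, K = 100, H = Inf), 5, 1)
  expect_error(fpt_stats(sp), "unreachable")
  # sharp switch that cannot fire before t_star
  late <- system_spec(regulator_spec(k = 20),
                      regulation_spec("activator", NA, K = 30, H = Inf), 15, 1)
  expect_error(calibrate_alpha(late), "infeasible")
})

test_that("variance scan: grid shape and unregulated corner", {
  sp <- activator_h3(20)
  g <- scan_variance(sp, K_values = c(0, 5), rate_t_values = c(15, 25),
                     rate = "k")
  expect_equal(nrow(g), 4)
  expect_named(g, c("K", "k_t_star", "alpha", "mean_t", "var_t", "scaled_var"))
  expect_equal(g$mean_t, rep(1, 4), tolerance = 1e-7)
  # K = 0 rows are the unregulated process: scaled variance 1
  expect_equal(g$scaled_var[g$K == 0], rep(1, 2), tolerance = 1e-6)
})
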