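# canonical parameter sets used across tests (x* = 15, t* = 1 throughout)

fig1_activator <- function(H = 1) {
  system_spec(regulator_spec(k = 20),
              regulation_spec("activator", alpha = NA, K = 15, H = H),
              x_star = 15, t_star = 1)
}

fig1_repressor <- function(H = 1) {
  system_spec(regulator_spec(mu = 2.75, n0 = 15),
              regulation_spec("repressor", alpha = NA, K = 2.6, H = H),
              x_star = 15, t_star = 1)
}

activator_h3 <- function(k_t_star, K = 10) {
  system_spec(regulator_spec(k = k_t_star),
              regulation_spec("activator", alpha = NA, K = K, H = 3),
              x_star = 15, t_star = 1)
}

repressor_h3 <- function(mu_t_star, K, N = 15) {
  system_spec(regulator_spec(mu = mu_t_star, n0 = N),
              regulation_spec("repressor", alpha = NA, K = K, H = 3),
              x_star = 15, t_star = 1)
}

trapz <- function(t, y) sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
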