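# Independent oracles used to cross-check the closed-form implementation.

# Numerical integration of the two-compartment ODE with deSolve (independent
# of the closed-form logistic solution used by simulate_culture).
ode_culture_oracle <- function(p, d, horizon = 75, step = 1 / 60) {
  dead <- p$a0 * d
  deriv <- function(t, y, parms) {
    g <- if (t >= p$lag) p$r * y[1] * (1 - (y[1] + dead) / p$K) else 0
    list(g)
  }
  times <- seq(0, horizon, by = step)
  sol <- deSolve::ode(y = c(L = p$a0 * (1 - d)), times = times, func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  data.frame(t = sol[, 1], od = sol[, 2] + dead)
}

# Brute-force root scan for tau on the simulated trajectory.
scan_tau_oracle <- function(p, d, step = 0.001, horizon = 80) {
  traj <- simulate_culture(p, d, horizon = horizon, step = step)
  i <- which(traj$od >= 2 * p$a0)
  if (!length(i)) return(Inf)
  traj$t[i[1]]
}

# Numeric quadrature of the density-dependent secretion integral.
quad_secretion_oracle <- function(p, sp, t_inc) {
  if (t_inc <= sp$t_ind) return(0)
  stats::integrate(function(u) sp$k * (p$a0 * exp(p$r * u))^2,
                   lower = sp$t_ind, upper = t_inc,
                   rel.tol = 1e-12)$value
}

# Noise-free od_trace straight from the forward model.
noise_free_trace <- function(p, d, horizon = 75, id = "nf") {
  traj <- simulate_culture(p, d, horizon = horizon)
  od_trace(id, traj$t * 60, traj$od)
}

# Noisy trace for a given kill fraction (bypassing the dose machinery).
noisy_trace <- function(p, d, seed, horizon = 75, noise_sd = 0.02,
                        noise_floor = 0.002) {
  traj <- simulate_culture(p, d, horizon = horizon)
  withr::with_seed(seed, {
    od <- pmax(traj$od * exp(stats::rnorm(length(traj$od), 0, noise_sd)) +
                 stats::rnorm(length(traj$od), 0, noise_floor), 0)
    od_trace(sprintf("d%.2f_s%d", d, seed), traj$t * 60, od)
  })
}
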