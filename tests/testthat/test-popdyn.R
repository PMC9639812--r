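test_that("kill fraction follows the protected / Hill / critical regimes", {
  hica <- hica_response()
  un <- culture_condition()
  expect_identical(kill_fraction(0, hica, un), 0)
  expect_identical(kill_fraction(30, hica, un), 1)
  expect_identical(kill_fraction(100, hica, un), 1)
  expect_identical(kill_fraction(25, mva_response(), un), 1)
  # glucose or adaptation protects completely, whatever the dose
  expect_identical(kill_fraction(40, hica, culture_condition(glucose_present = TRUE)), 0)
  expect_identical(kill_fraction(40, hica, culture_condition(adapted = TRUE)), 0)
  # sub-critical Hill value
  expect_equal(kill_fraction(20, hica, un), 0.97 / 2)
  # non-decreasing on a dose grid
  d <- kill_fraction(seq(0, 40, by = 0.5), hica, un)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(kill_fraction(-1, hica, un), "non-negative")
})

test_that("simulated trajectories conserve OD = living + dead with constant dead mass", {
  p <- growth_params()
  for (d in c(0, 0.5, 1)) {
    traj <- simulate_culture(p, d, horizon = 30)
    expect_equal(traj$od, traj$living + traj$dead)
    expect_true(all(traj$dead == p$a0 * d))
    expect_true(all(traj$living >= 0))
  }
  expect_error(simulate_culture(p, 1.2), "\\[0, 1\\]")
  expect_error(simulate_culture(p, -0.1), "\\[0, 1\\]")
})

test_that("simulation limits: pure exponential (d=0, K large) and flat total kill", {
  p <- growth_params(K = 1e9)
  traj <- simulate_culture(p, 0, horizon = 3 / p$r, step = 0.1)
  expect_equal(traj$od, p$a0 * exp(p$r * traj$t), tolerance = 1e-9)
  flat <- simulate_culture(growth_params(), 1, horizon = 20)
  expect_true(all(flat$od == flat$od[1]))
  expect_equal(flat$od[1], growth_params()$a0)
})

test_that("closed-form trajectory matches independent ODE integration", {
  cases <- list(
    list(p = growth_params(), d = 2 / 3),
    list(p = growth_params(r = 0.12, lag = 3, K = 0.8, a0 = 0.01), d = 0.4),
    list(p = growth_params(r = 0.05, K = 2, a0 = 0.05), d = 0)
  )
  for (cs in cases) {
    traj <- simulate_culture(cs$p, cs$d, horizon = 60, step = 0.25)
    oracle <- ode_culture_oracle(cs$p, cs$d, horizon = 60, step = 0.25)
    expect_equal(traj$od, oracle$od, tolerance = 1e-7)
  }
})

test_that("tau closed form: doubling times, censoring, exponential limit", {
  pbig <- growth_params(K = 1e9)
  expect_equal(tau_forward(pbig, 0), 10)
  expect_equal(tau_forward(pbig, 2 / 3), 20)
  expect_identical(tau_forward(pbig, 1), Inf)
  # censored when doubling is unreachable under the cap
  expect_identical(tau_forward(growth_params(a0 = 0.6, K = 1), 0), Inf)
  # lag shifts tau additively
  expect_equal(tau_forward(growth_params(lag = 4, K = 1e9), 0), 14)
  # exponential-limit identity
  for (d in c(0, 0.3, 0.8)) {
    expect_equal(tau_forward(pbig, d), log((2 - d) / (1 - d)) / pbig$r,
                 tolerance = 1e-7)
  }
})

test_that("tau closed form agrees with brute-force root scans of the simulation", {
  # spec'd example: d = 2/3 at 0.001-h resolution
  p <- growth_params(K = 1e9)
  expect_equal(scan_tau_oracle(p, 2 / 3), 20, tolerance = 2e-3)
  # 100 random parameter draws at finite K
  withr::with_seed(7, {
    for (i in 1:100) {
      pp <- growth_params(r = runif(1, 0.03, 0.15), lag = runif(1, 0, 3),
                          K = 1, a0 = runif(1, 0.005, 0.05))
      d <- runif(1, 0, 0.9)
      tf <- tau_forward(pp, d)
      expect_lt(abs(tf - scan_tau_oracle(pp, d, horizon = tf + 5)), 1e-3)
    }
  })
})

test_that("tau is monotone: increasing in kill fraction, decreasing in growth rate", {
  for (r in seq(0.03, 0.15, by = 0.03)) {
    taus <- vapply(seq(0, 0.9, by = 0.1), function(d)
      tau_forward(growth_params(r = r), d), numeric(1))
    expect_true(all(diff(taus) > 0))
  }
  for (d in seq(0, 0.9, by = 0.1)) {
    taus <- vapply(seq(0.03, 0.15, by = 0.03), function(r)
      tau_forward(growth_params(r = r), d), numeric(1))
    expect_true(all(diff(taus) < 0))
  }
})

test_that("secretion signal is zero before induction, then strictly increasing", {
  p <- growth_params(); sp <- secretion_params()
  expect_identical(secrete_toxin(p, sp, 0), 0)
  expect_identical(secrete_toxin(p, sp, sp$t_ind), 0)
  sig <- secrete_toxin(p, sp, seq(sp$t_ind + 0.5, 40, by = 0.5))
  expect_true(all(diff(sig) > 0))
})

test_that("secretion closed form matches quadrature and honors accumulation bounds", {
  p <- growth_params(); sp <- secretion_params()
  for (t in c(5, 10, 20, 30))
    expect_equal(secrete_toxin(p, sp, t), quad_secretion_oracle(p, sp, t),
                 tolerance = 1e-9)
  expect_gt(secrete_toxin(p, sp, 20) / secrete_toxin(p, sp, 10), 5)
  expect_gt(secrete_toxin(p, sp, 30) / secrete_toxin(p, sp, 20), 3)
})

test_that("conditioned-medium calibration anchors the 30-h kill fraction at 2/3", {
  p <- growth_params(); sp <- secretion_params(); hica <- hica_response()
  expect_identical(cm_condition(0, sp, hica)$effective_dose, 0)
  s30 <- secrete_toxin(p, sp, 30)
  cond <- cm_condition(s30, sp, hica)
  expect_equal(kill_fraction(cond$effective_dose, hica, cond), 2 / 3,
               tolerance = 1e-9)
  # hence tau = 20 h downstream in the exponential regime
  d <- kill_fraction(cond$effective_dose, hica, cond)
  expect_equal(tau_forward(growth_params(K = 1e9), d), 20, tolerance = 1e-6)
  # monotone in the signal
  doses <- vapply(seq(0.001, 0.2, length.out = 30), function(s)
    cm_condition(s, sp, hica)$effective_dose, numeric(1))
  expect_true(all(diff(doses) > 0))
})
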