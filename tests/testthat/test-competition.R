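test_that("steady-state prediction: symmetric, skewed and one-sided inocula", {
  p <- growth_params()
  expect_identical(predict_steady_state(p, p)$f_inf, 0.5)
  pred <- predict_steady_state(p, p, d_A = 0, d_B = 2 / 3)
  expect_equal(pred$f_inf, 0.75, tolerance = 1e-12)
  expect_identical(predict_steady_state(p, p,
                                        inoculum_ratio = c(1, 0))$f_inf, 1)
  # closed form matches the simulated long-time living fraction
  expect_lt(abs(utils::tail(pred$f_t$fraction_A, 1) - pred$f_inf), 1e-4)
})

test_that("closed-form f_inf equals long-horizon simulation across random equal-rate cases", {
  withr::with_seed(11, {
    for (i in 1:8) {
      # exponential regime (huge cap): the closed form is exact there even
      # with unequal lags; under a finite cap it is a pre-saturation
      # approximation
      r <- runif(1, 0.05, 0.12)
      pA <- growth_params(r = r, lag = runif(1, 0, 2), a0 = 0.02, K = 1e9)
      pB <- growth_params(r = r, lag = runif(1, 0, 2), a0 = 0.02, K = 1e9)
      dA <- runif(1, 0, 0.8); dB <- runif(1, 0, 0.8)
      ratio <- c(runif(1, 0.2, 1), runif(1, 0.2, 1))
      pred <- predict_steady_state(pA, pB, dA, dB, inoculum_ratio = ratio)
      expect_lt(abs(utils::tail(pred$f_t$fraction_A, 1) - pred$f_inf), 1e-4)
      # symmetry: swapping the populations mirrors the fraction
      mirror <- predict_steady_state(pB, pA, dB, dA,
                                     inoculum_ratio = rev(ratio))
      expect_equal(mirror$f_inf, 1 - pred$f_inf, tolerance = 1e-10)
    }
  })
})

test_that("unequal growth rates are flagged degenerate", {
  fast <- growth_params(r = 0.1)
  slow <- growth_params(r = 0.05)
  pred <- predict_steady_state(fast, slow)
  expect_true(pred$degenerate)
  expect_identical(pred$f_inf, 1)
  expect_identical(predict_steady_state(slow, fast)$f_inf, 0)
})

test_that("fraction time courses sum to one and carry binomial errors", {
  s1 <- flow_sample("t0", 0, c(green_live = 250000, red_live = 250000))
  s2 <- flow_sample("t1", 24, c(green_live = 400000, red_live = 100000))
  fc <- fraction_timecourse(list(s2, s1))
  expect_identical(fc$t, c(0, 0, 24, 24))
  by_t <- tapply(fc$fraction, fc$t, sum)
  expect_true(all(abs(by_t - 1) < 1e-12))
  expect_identical(fc$fraction[fc$t == 0][1], 0.5)
  expect_equal(fc$se[fc$t == 0][1], sqrt(0.25 / 500000))
  # an absent label has fraction zero
  s3 <- flow_sample("t2", 48, c(green_live = 1000, red_live = 0))
  fc3 <- fraction_timecourse(list(s3))
  expect_identical(fc3$fraction[fc3$label == "red"], 0)
  expect_error(fraction_timecourse(list()), "no flow samples")
})

test_that("adapted cells overtake unadapted ones and match the growth-curve prediction", {
  p <- growth_params()
  pred <- predict_steady_state(p, p, d_A = 0, d_B = 2 / 3, count_dead = TRUE)
  traj <- simulate_competition(p, p, d_A = 0, d_B = 2 / 3)
  tps <- c(0, 8, 16, 24, 32, 48)
  samples <- lapply(seq_along(tps), function(i) {
    row <- traj[which.min(abs(traj$t - tps[i])), ]
    generate_flow_counts(
      list(adapted = list(living = row$living_A, dead = row$dead_A),
           unadapted = list(living = row$living_B, dead = row$dead_B)),
      total_events = 500000, count_dead = TRUE, seed = 70 + i,
      sample_id = sprintf("t%g", tps[i]), t = tps[i])
  })
  fc <- fraction_timecourse(samples, living_only = FALSE)
  adapted <- fc[fc$label == "adapted", ]
  # fraction rises monotonically (beyond counting noise) to the predicted level
  expect_true(all(diff(adapted$fraction) > -3 * sqrt(0.25 / 500000)))
  expect_gt(utils::tail(adapted$fraction, 1), 0.7)
  cmp <- compare_prediction(pred, adapted)
  expect_true(cmp$agree)
  # a flat 50:50 trajectory does not match the prediction
  flat <- data.frame(t = tps, fraction = 0.5, se = sqrt(0.25 / 500000))
  expect_false(compare_prediction(pred, flat)$agree)
  # single shared timepoint is compared at that point only
  one <- compare_prediction(pred, adapted[3, ])
  expect_identical(nrow(one$comparison), 1L)
})
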