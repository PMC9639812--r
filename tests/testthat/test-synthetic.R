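test_that("od generation is seed-deterministic and noise-free equals the model", {
  p <- growth_params()
  t1 <- generate_od_trace(p, seed = 42)
  t2 <- generate_od_trace(p, seed = 42)
  expect_identical(t1$od, t2$od)
  t3 <- generate_od_trace(p, seed = 43)
  expect_false(identical(t1$od, t3$od))
  # zero noise reproduces the deterministic trajectory exactly
  nf <- generate_od_trace(p, noise_sd = 0, noise_floor = 0, seed = 1,
                          horizon = 20)
  traj <- simulate_culture(p, 0, horizon = 20)
  expect_identical(nf$od, traj$od)
  expect_error(generate_od_trace(p), "seed")
})

test_that("dose panels carry monotone kill fractions and honor the dose grid", {
  p <- growth_params()
  single <- generate_dose_panel(0, hica_response(), p, seed = 1, horizon = 30)
  expect_length(single, 1)
  expect_identical(single[[1]]$metadata$kill_fraction, 0)
  panel <- generate_dose_panel(seq(0, 40, by = 10), hica_response(), p,
                               seed = 1, horizon = 5)
  kills <- vapply(panel, function(tr) tr$metadata$kill_fraction, numeric(1))
  expect_true(all(diff(kills) >= 0))
  expect_identical(kills[[5]], 1)
  expect_error(generate_dose_panel(c(0, 10, 10), hica_response(), p, seed = 1),
               "duplicate")
  expect_error(generate_dose_panel(c(-5, 0), hica_response(), p, seed = 1),
               "non-negative")
})

test_that("cm series: fresh medium shows no kill, longer incubation more kill", {
  series <- generate_cm_series(c(0, 10, 30), seed = 9, horizon = 2)
  kills <- vapply(series, function(tr) tr$metadata$kill_fraction, numeric(1))
  expect_identical(kills[[1]], 0)
  expect_true(all(diff(kills) > 0))
  expect_equal(kills[[3]], 2 / 3, tolerance = 1e-9)
})

test_that("flow counts are multinomial draws over subpopulation masses", {
  states <- list(green = list(living = 1, dead = 0),
                 red = list(living = 1, dead = 0))
  fs <- generate_flow_counts(states, total_events = 500000, seed = 3)
  expect_identical(sum(fs$counts), 500000L)
  f_green <- fs$counts[["green_live"]] / 500000
  expect_lt(abs(f_green - 0.5), 3 * sqrt(0.25 / 500000))
  # closed-form gate probability: dead 0.9 vs living 0.1 grown 8 h
  p <- growth_params()
  grown <- 0.1 * exp(p$r * 8)
  expected <- 0.9 / (0.9 + grown)
  fs2 <- generate_flow_counts(list(cells = list(living = grown, dead = 0.9)),
                              total_events = 1e6, seed = 4)
  dyed <- fs2$counts[["cells_dead"]] / 1e6
  expect_lt(abs(dyed - expected), 3 * sqrt(expected * (1 - expected) / 1e6))
  # single event lands in exactly one gate
  one <- generate_flow_counts(states, total_events = 1, seed = 5)
  expect_identical(sum(one$counts), 1L)
  expect_identical(sum(one$counts > 0), 1L)
  expect_error(generate_flow_counts(list(a = list(living = 0, dead = 0)),
                                    seed = 1), "zero")
  # determinism
  expect_identical(generate_flow_counts(states, 1000, seed = 11)$counts,
                   generate_flow_counts(states, 1000, seed = 11)$counts)
})

test_that("compound tables reproduce the requested Venn membership counts", {
  tab <- generate_compound_table(20, 8, 5, seed = 1)
  expect_identical(nrow(tab), 25L)
  expect_identical(sum(tab$in_wt_cm & tab$in_fbp1_cm), 20L)
  expect_identical(sum(tab$in_wt_cm & tab$in_fbp1_cm & tab$in_mm), 8L)
  expect_identical(sum(tab$in_wt_cm & tab$in_fbp1_cm & !tab$in_mm), 12L)
  expect_false(anyDuplicated(tab$compound) > 0)
  # empty candidate region
  tab0 <- generate_compound_table(0, 0, 3, seed = 2)
  expect_identical(sum(tab0$in_wt_cm & tab0$in_fbp1_cm & !tab0$in_mm), 0L)
  expect_error(generate_compound_table(5, 6, 0, seed = 1), "exceed")
  # membership counts always match the arguments
  withr::with_seed(10, {
    for (i in 1:5) {
      ns <- sample(0:30, 1); nm <- sample(0:ns, 1); nn <- sample(0:10, 1)
      tt <- generate_compound_table(ns, nm, nn, seed = i)
      expect_identical(sum(tt$in_wt_cm & tt$in_fbp1_cm), ns)
      expect_identical(sum(tt$in_wt_cm & tt$in_fbp1_cm & tt$in_mm), nm)
      expect_identical(nrow(tt), ns + nn)
    }
  })
})
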