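test_that("dose profiles order by dose and flag tau monotonicity", {
  p <- growth_params()
  # deterministic panel: taus come from the forward model, shuffled on input
  doses <- c(20, 0, 10, 25)
  traces <- lapply(doses, function(dd) {
    tr <- noise_free_trace(p, kill_fraction(dd, hica_response()), id = dd)
    tr$metadata$dose_mM <- dd
    tr
  })
  panel <- tau_dose_profile(analyze_dose_panel(traces, baseline_tau = 10.3))
  expect_identical(panel$doses, sort(doses))
  expect_true(panel$monotone_ok)
  expect_true(all(diff(panel$taus) >= 0))
  expect_identical(panel$delay_present, c(FALSE, FALSE, TRUE, TRUE))
  # a decreasing tau breaks the flag
  res <- analyze_dose_panel(traces)
  res[[1]]$tau <- 5
  expect_false(tau_dose_profile(res, doses)$monotone_ok)
  expect_error(tau_dose_profile(res[1], doses[1]), "at least two")
  expect_error(tau_dose_profile(res[c(2, 2, 1)], c(0, 0, 20)), "duplicate")
})

test_that("critical concentration is the smallest fully suppressed dose", {
  p <- growth_params()
  make_panel <- function(toxin, seed) {
    traces <- generate_dose_panel(seq(0, 40, by = 2.5), toxin, p, seed = seed)
    tau_dose_profile(analyze_dose_panel(traces))
  }
  hica_panel <- make_panel(hica_response(), 31)
  expect_identical(as.numeric(estimate_critical_concentration(hica_panel)), 30)
  mva_panel <- make_panel(mva_response(), 32)
  expect_identical(as.numeric(estimate_critical_concentration(mva_panel)), 25)
  # no censored dose -> NA
  sub <- hica_panel
  keep <- sub$doses < 30
  sub$doses <- sub$doses[keep]; sub$taus <- sub$taus[keep]
  sub$delay_present <- sub$delay_present[keep]
  expect_true(is.na(estimate_critical_concentration(sub)))
  # non-monotone censoring warns but still returns the smallest censored dose
  odd <- hica_panel
  odd$taus[odd$doses == 35] <- 12
  expect_warning(cc <- estimate_critical_concentration(odd), "monotone")
  expect_identical(as.numeric(cc), 30)
  expect_true(attr(cc, "inconsistent"))
})

test_that("potency shift recovers the conditioned-medium background multiplier", {
  p <- growth_params()
  base_tau <- tau_forward(p, 0)
  standalone <- generate_dose_panel(seq(0, 40, by = 2.5), hica_response(), p,
                                    seed = 51)
  background <- generate_dose_panel(seq(0, 40, by = 2.5) / 1000,
                                    hica_response(), p, seed = 52,
                                    background = TRUE)
  sp <- tau_dose_profile(analyze_dose_panel(standalone,
                                            baseline_tau = base_tau))
  bp <- tau_dose_profile(analyze_dose_panel(background,
                                            baseline_tau = base_tau))
  shift <- potency_shift(sp, bp)
  expect_gte(shift, 500)
  expect_lte(shift, 2000)
  # identical panels shift by exactly 1
  expect_identical(potency_shift(sp, sp), 1)
  # a less potent background gives a ratio below 1
  expect_lt(potency_shift(bp, sp), 1)
})

test_that("critical concentration is stable under grid refinement", {
  p <- growth_params()
  coarse <- generate_dose_panel(seq(0, 40, by = 2.5), hica_response(), p,
                                seed = 61)
  fine <- generate_dose_panel(seq(0, 40, by = 1.25), hica_response(), p,
                              seed = 62)
  cc_coarse <- estimate_critical_concentration(
    tau_dose_profile(analyze_dose_panel(coarse)))
  cc_fine <- estimate_critical_concentration(
    tau_dose_profile(analyze_dose_panel(fine)))
  expect_lte(abs(as.numeric(cc_fine) - as.numeric(cc_coarse)), 2.5)
})
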