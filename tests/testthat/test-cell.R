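test_that("the Markov IKr component mixes isoform currents linearly", {
  sch <- markov_scheme("mmodel1")
  pa <- herg_parameters("mmodel1", "hERG1a")
  pb <- herg_parameters("mmodel1", "hERG1b")
  # identical starting occupancies for both populations
  p0 <- steady_state(build_generator(sch, pa, -80))
  st <- list(pa = p0, pb = p0)
  V <- 0; dt <- 0.5
  pure_a <- markov_ikr_component(sch, pa, pb, mix = 0, V, dt, state = st)
  pure_b <- markov_ikr_component(sch, pa, pb, mix = 1, V, dt, state = st)
  half <- markov_ikr_component(sch, pa, pb, mix = 0.5, V, dt, state = st)
  expect_equal(half$IKr, (pure_a$IKr + pure_b$IKr) / 2, tolerance = 1e-12)
  # mix = 0 equals the pure a-isoform current
  expect_equal(pure_a$IKr,
               0.0422 * pure_a$state$pa[["O"]] * (V - (-87)))
})

test_that("the paced surrogate cell rests, fires, and shortens APD with hERG1b", {
  m0 <- surrogate_cell_model(fraction_b = 0)
  # zero stimulus: flat at rest for a full second
  quiet <- simulate_cell(m0, n_beats = 1, stim_amp = 0)
  expect_lt(max(abs(quiet$V - quiet$V[1])), 0.01)
  expect_error(apd(quiet), "no action potential")

  tr0 <- simulate_cell(m0, n_beats = 2)
  m1 <- surrogate_cell_model(fraction_b = 1)
  tr1 <- simulate_cell(m1, n_beats = 2)
  expect_lt(apd(tr1), apd(tr0))
  # IKr probability conservation across pacing
  expect_lt(max(abs(colSums(tr0$occ_a) - 1)), 1e-6)
  # open-state occupancy during repolarization is higher for the b-mixture
  w0 <- tr0$time - min(tr0$time); w1 <- tr1$time - min(tr1$time)
  expect_gt(mean(tr1$occ_b["O", w1 > 50 & w1 < 150]),
            mean(tr0$occ_a["O", w0 > 50 & w0 < 150]))
})

test_that("APD is measured correctly on a synthetic trapezoidal AP", {
  # rest -80, linear rise to +20 over 2 ms, plateau 200 ms,
  # linear fall back to -80 over 100 ms
  t <- seq(0, 400, by = 0.5)
  V <- ifelse(t < 2, -80 + 50 * t,
         ifelse(t < 202, 20,
           ifelse(t < 302, 20 - (t - 202), -80)))
  tr <- list(time = t, V = V)
  # APD90: threshold = -80 + 0.1 * 100 = -70; crossing on the ramp at
  # t = 202 + 90; upstroke max-dV/dt at the first rise sample
  expect_equal(apd(tr, 0.9), 292, tolerance = 1)
  expect_equal(apd(tr, 1.0), 302, tolerance = 1)
  expect_error(apd(list(time = t, V = rep(-80, length(t)))), "no action")
})
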