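test_that("the Boltzmann fitter recovers parameters from its own noiseless curve", {
  V <- seq(-100, 40, by = 10)
  I <- 1 / (1 + exp((-10.7 - V) / 8.1))
  bf <- boltzmann_fit(V, I)
  expect_equal(bf$V_half, -10.7, tolerance = 1e-6)
  expect_equal(bf$slope, 8.1, tolerance = 1e-6)
  # fitted curve equals 0.5 at V_half by construction
  expect_equal(1 / (1 + exp((bf$V_half - bf$V_half) / bf$slope)), 0.5)
  expect_error(boltzmann_fit(c(-10, 0), c(0.4, 0.6)), "4")
})

test_that("single-exponential decays are recovered essentially exactly", {
  t <- seq(0, 80, by = 0.5)
  y <- 2.5 * exp(-t / 10) + 0.3
  f <- exp_fit(t, y, n_components = 1)
  expect_equal(f$tau, 10, tolerance = 1e-6)
  expect_equal(f$amplitude, 2.5, tolerance = 1e-6)
  expect_equal(f$offset, 0.3, tolerance = 1e-6)
})

test_that("double-exponential components are recovered and ordered at low noise", {
  set.seed(42)
  t <- seq(0, 300, by = 0.5)
  y <- 0.7 * exp(-t / 5) + 0.3 * exp(-t / 50) +
    rnorm(length(t), sd = 0.001)   # noise SD 0.1% of total amplitude
  f <- exp_fit(t, y, n_components = 2, offset = FALSE)
  expect_lt(f$tau[1], f$tau[2])
  expect_equal(f$tau, c(5, 50), tolerance = 0.01)
  expect_equal(f$amplitude, c(0.7, 0.3), tolerance = 0.01)
})

test_that("amplitude sign constraints keep opposite-signed modes out", {
  t <- seq(0, 100, by = 0.25)
  # decaying inward tail with a small opposite-signed fast mode
  y <- -1 * exp(-t / 40) + 0.03 * exp(-t / 1.5)
  f <- exp_fit(t, y, n_components = 2, offset = FALSE, amp_sign = -1)
  expect_true(all(f$amplitude <= 0))
  expect_equal(max(f$tau), 40, tolerance = 0.05)
})

test_that("simulated deactivation is faster for hERG1b at every tested voltage", {
  cp <- room_cp()
  prot <- make_deactivation_protocol(test_voltages = c(-100, -40),
                                     test_ms = 3000)
  taus <- lapply(c("hERG1a", "hERG1b"), function(iso) {
    traces <- simulate_sweeps("mmodel1", herg_parameters("mmodel1", iso),
                              prot, cp, sample_dt = 1)
    vapply(traces, function(tr) fit_deactivation(tr)$tau, numeric(2))
  })
  expect_true(all(taus[[2]] < taus[[1]]))       # both components, both voltages
  expect_true(all(taus[[1]][1, ] <= taus[[1]][2, ] + 1e-8))
})

test_that("recovery from inactivation is faster for hERG1b", {
  cp <- room_cp()
  prot <- make_recovery_protocol()
  tau <- sapply(c("hERG1a", "hERG1b"), function(iso) {
    traces <- simulate_sweeps("mmodel1", herg_parameters("mmodel1", iso),
                              prot, cp, sample_dt = 0.1)
    vapply(traces, fit_recovery_tau, 0)
  })
  expect_true(all(tau[, "hERG1b"] < tau[, "hERG1a"]))
})
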