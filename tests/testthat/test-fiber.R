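test_that("an unstimulated fiber stays uniformly at rest", {
  m <- surrogate_cell_model(fraction_b = 0.5)
  cfg <- cable_config(n_cells = 5, n_beats = 1, stim_amp = 0,
                      regions = list(all = 1:5))
  f <- simulate_fiber(m, cfg)
  expect_lt(max(abs(f$V - f$V[1, 1])), 0.01)
})

test_that("a stimulated wave activates cells in order of distance", {
  m <- surrogate_cell_model(fraction_b = 0)
  cfg <- cable_config(n_cells = 30, n_beats = 1,
                      regions = list(all = 1:30))
  f <- simulate_fiber(m, cfg)
  act <- apply(f$V, 1, function(v) f$time[which(v > -20)[1]])
  expect_true(all(is.finite(act)))
  expect_true(all(diff(act) >= 0))
})

test_that("halving the time step changes the solution by less than 0.5 mV", {
  m <- surrogate_cell_model(fraction_b = 0)
  cfg1 <- cable_config(n_cells = 5, n_beats = 1, dt_coarse = 0.005,
                       regions = list(all = 1:5))
  cfg2 <- cable_config(n_cells = 5, n_beats = 1, dt_coarse = 0.0025,
                       regions = list(all = 1:5))
  f1 <- simulate_fiber(m, cfg1)
  f2 <- simulate_fiber(m, cfg2)
  n <- min(ncol(f1$V), ncol(f2$V))
  expect_lt(max(abs(f1$V[, 1:n] - f2$V[, 1:n])), 0.5)
})

test_that("time steps violating the diffusion stability bound are rejected", {
  m <- surrogate_cell_model()
  cfg <- cable_config(n_cells = 5, n_beats = 1, dt_coarse = 0.1,
                      regions = list(all = 1:5))
  expect_error(simulate_fiber(m, cfg), "dt")
})

test_that("the pseudo-ECG is zero for uniform Vm and linear in Vm", {
  Vu <- matrix(-80, 20, 50)
  expect_equal(max(abs(pseudo_ecg(Vu, dx = 0.01)$phi)), 0)
  set.seed(8)
  Vm <- matrix(rnorm(20 * 50, -40, 30), 20, 50)
  e1 <- pseudo_ecg(Vm, dx = 0.01)
  e3 <- pseudo_ecg(3 * Vm, dx = 0.01)
  expect_equal(e3$phi, 3 * e1$phi, tolerance = 1e-12)
  expect_error(pseudo_ecg(Vm, ecg_geometry(electrode_offset = 0), dx = 0.01),
               "off the fiber")
})

test_that("the QT measure has known support on a synthetic biphasic pulse", {
  t <- 0:500
  phi <- numeric(501)
  phi[101:200] <- sin(seq(0, pi, length.out = 100))        # R-like wave
  phi[351:400] <- -0.4 * sin(seq(0, pi, length.out = 50))  # T-like wave
  qt <- qt_interval(list(time = t, phi = phi), baseline_tolerance = 0.01)
  expect_equal(qt, 398 - 101, tolerance = 5)
  # invariant under amplitude scaling (proportional tolerance)
  qt2 <- qt_interval(list(time = t, phi = 13 * phi), baseline_tolerance = 0.01)
  expect_equal(qt, qt2)
  expect_error(qt_interval(list(time = t, phi = numeric(501))), "flat|deflection")
})
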