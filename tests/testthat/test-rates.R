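test_that("rate evaluation follows the exponential voltage law", {
  aa_a <- rate_law(alpha = 4.94e-3, beta = 4.31e-2)
  expect_equal(evaluate_rate(aa_a, 0), 4.94e-3)           # exp(0) = 1
  expect_equal(evaluate_rate(aa_a, 40), 2.7699e-2, tolerance = 1e-4)
  # voltage-independent transition: same rate at any potential
  ain_a <- rate_law(alpha = 2.20e-2, beta = 0)
  expect_equal(evaluate_rate(ain_a, -120), 2.20e-2)
  expect_equal(evaluate_rate(ain_a, 40), 2.20e-2)
  # corrections multiply prefactor and exponent coefficient
  expect_equal(evaluate_rate(rate_law(2, 0.01, corr_a = 3, corr_b = 2), 10),
               3 * 2 * exp(2 * 0.01 * 10))
  # vectorized over V, strictly positive
  v <- seq(-120, 60, by = 20)
  expect_true(all(evaluate_rate(aa_a, v) > 0))
  expect_length(evaluate_rate(aa_a, v), length(v))
})

test_that("rate evaluation rejects invalid inputs and overflow", {
  expect_error(rate_law(alpha = -1), "alpha")
  expect_error(rate_law(alpha = 1, corr_a = 0), "corr_a")
  expect_error(evaluate_rate(rate_law(1, 1), 1e6), "overflow|invalid")
  expect_error(evaluate_rate(rate_law(1, 0.05), NaN))
})

test_that("thermodynamic parameterization reproduces the Eyring prefactor and valence slope", {
  kB <- 1.381e-23; h <- 6.626e-34; R <- 8.315; Fd <- 96485
  T <- 296.15
  th <- list(dH = 8e4, dS = 60, z = 1.5)
  law <- rate_law(thermo = th, temperature = T)
  expect_equal(law$alpha,
               (kB * T / h) * exp(th$dS / R - th$dH / (R * T)) / 1000,
               tolerance = 1e-12)
  expect_equal(law$beta, th$z * Fd / (R * T) / 1000, tolerance = 1e-12)
})

test_that("Nernst potential behaves as a ratio law", {
  expect_equal(nernst_potential(120, 120, 296.15), 0)
  expect_equal(nernst_potential(120, 5.4, 296.15), -79.146, tolerance = 1e-4)
  expect_equal(nernst_potential(120, 5.4, 296.15),
               nernst_potential(240, 10.8, 296.15))
  expect_error(nernst_potential(-1, 5.4), "> 0")
})

test_that("conductance scaling matches the temperature and potassium factors", {
  expect_equal(conductance(current_params(T = 310, Ko = 5.4)), 0.024)
  expect_equal(conductance(current_params(T = 310, Ko = 21.6)), 0.048)
  expect_equal(conductance(current_params(T = 296.15, Ko = 5.4)),
               0.0145029, tolerance = 1e-5)
  expect_error(current_params(T = 200), "validity")
})

test_that("IKr current is ohmic in the open probability", {
  cp <- room_cp()
  expect_equal(ikr_current(0, -40, cp), 0)
  expect_equal(ikr_current(0.7, cp$EK, cp), 0)
  expect_equal(ikr_current(0.5, -40, cp), ikr_current(1, -40, cp) / 2)
})
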