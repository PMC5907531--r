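test_that("protocol constructors produce the documented sweep batteries", {
  ssa <- make_ssa_protocol()
  expect_length(ssa$sweep$values, 15)           # -100..+40 by 10
  expect_equal(ssa$segments$voltage[2], -100)   # tail fixed at -100 mV
  expect_equal(ssa$segments$duration, c(1000, 1000))
  expect_length(make_ssa_protocol(increment = 20)$sweep$values, 8)

  env <- make_envelope_protocol()
  expect_length(env$sweep$values, 9)
  expect_equal(env$sweep$values[1], 5)
  expect_equal(env$segments$duration[2], 3000)

  de <- make_deactivation_protocol()
  expect_equal(de$sweep$values, c(-120, -100, -60, -40))
  expect_equal(unlist(de$segments[2, c("duration", "voltage")]),
               c(duration = 5, voltage = -120))
  expect_length(make_deactivation_protocol(-60)$sweep$values, 1)

  rec <- make_recovery_protocol()
  expect_equal(rec$sweep$values, c(-100, -50))
  expect_error(make_recovery_protocol(numeric(0)), "empty")
})

test_that("simulated sweeps have the right sampling and obey the reversal potential", {
  cp <- room_cp()
  p <- herg_parameters("mmodel1", "hERG1a")
  prot <- make_ssa_protocol(step_min = -40, step_max = 0, increment = 20)
  traces <- simulate_sweeps("mmodel1", p, prot, cp, sample_dt = 1)
  expect_length(traces, 3)
  expect_length(traces[[1]]$time, 2000 / 1 + 1)
  # a protocol held at EK everywhere gives identically zero current
  at_ek <- voltage_protocol("ek", data.frame(duration = c(100, 100),
                                             voltage = c(NA, cp$EK)),
                            sweep = list(segment = 1L, field = "voltage",
                                         values = cp$EK),
                            measurement_segment = 2L, holding = cp$EK)
  tr <- simulate_sweeps("mmodel1", p, at_ek, cp, sample_dt = 1)[[1]]
  expect_equal(max(abs(tr$current)), 0)
})

test_that("peak-tail extraction finds the signed extremum", {
  # monotone decaying segment: peak at the first sample
  tr <- structure(list(time = 0:100, current = -exp(-(0:100) / 20)),
                  class = "current_trace",
                  segment_starts = 0, segment_voltages = -100,
                  measurement_segment = 1, EK = -79)
  pk <- peak_tail(tr)
  expect_equal(pk$time, 0)
  expect_equal(pk$current, -1)
  # all-zero trace reports zero at the first sample
  tr$current <- rep(0, 101)
  expect_equal(peak_tail(tr)$magnitude, 0)
  expect_equal(peak_tail(tr)$time, 0)
})

test_that("hooked tails have an interior peak matching a dense-grid argmax", {
  cp <- room_cp()
  p <- herg_parameters("mmodel1", "hERG1a")
  prot <- make_recovery_protocol(-100)
  coarse <- simulate_sweeps("mmodel1", p, prot, cp, sample_dt = 0.1)[[1]]
  pk <- peak_tail(coarse)
  expect_gt(pk$time, 0)                       # interior, not at onset
  dense <- simulate_sweeps("mmodel1", p, prot, cp, sample_dt = 0.01)[[1]]
  pk_dense <- peak_tail(dense)
  expect_lt(abs(pk$time - pk_dense$time), 0.2)
  expect_equal(pk$magnitude, pk_dense$magnitude, tolerance = 1e-3)
})

test_that("normalized curves are invariant under uniform current scaling", {
  cp <- room_cp()
  p <- herg_parameters("mmodel1", "hERG1b")
  env <- make_envelope_protocol(c(10, 50, 200))
  traces <- simulate_sweeps("mmodel1", p, env, cp, sample_dt = 1)
  curve1 <- activation_envelope_curve(traces)
  scaled <- lapply(traces, function(tr) { tr$current <- 7.3 * tr$current; tr })
  curve2 <- activation_envelope_curve(scaled)
  expect_equal(curve1, curve2)
  expect_equal(max(curve1$norm), 1)
  expect_true(all(diff(curve1$norm) >= 0))    # nondecreasing in duration
  # single sweep: the single point is 1
  one <- activation_envelope_curve(traces[2])
  expect_equal(one$norm, 1)
})

test_that("the I-V relationship is bell-shaped with one point per sweep", {
  cp <- room_cp()
  prot <- make_ssa_protocol()
  for (iso in c("hERG1a", "hERG1b")) {
    p <- herg_parameters("mmodel1", iso)
    traces <- simulate_sweeps("mmodel1", p, prot, cp, sample_dt = 1)
    iv <- iv_relationship(traces)
    expect_equal(nrow(iv), length(traces))
    k <- which.max(iv$current)
    expect_gt(k, 1)                # rises then falls: interior maximum
    expect_lt(k, nrow(iv))
    expect_gt(iv$current[k], iv$current[nrow(iv)])
  }
})
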