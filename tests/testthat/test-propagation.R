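test_that("steady state solves the two-state closed form", {
  Q <- two_state_Q(f = 0.3, b = 0.1)
  p <- steady_state(Q)
  expect_equal(unname(p["O"]), 0.3 / 0.4, tolerance = 1e-12)
  expect_lt(max(abs(Q %*% p)), 1e-10)
  expect_equal(sum(p), 1)
})

test_that("steady state agrees with long-time propagation", {
  p <- herg_parameters("mmodel1", "hERG1a")
  Q <- build_generator("mmodel1", p, -80)
  ss <- steady_state(Q)
  traj <- propagate_segment(rep(0.2, 5), Q, duration = 1e5, sample_dt = 1000)
  expect_lt(max(abs(traj[, ncol(traj)] - ss)), 1e-6)
})

test_that("propagation is exact for the two-state relaxation", {
  f <- 0.05; b <- 0.02
  Q <- two_state_Q(f, b)
  p0 <- c(C = 1, O = 0)
  traj <- propagate_segment(p0, Q, duration = 200, sample_dt = 5)
  t <- attr(traj, "time")
  pinf <- f / (f + b)
  expected <- pinf * (1 - exp(-(f + b) * t)) + p0["O"] * exp(-(f + b) * t)
  expect_lt(max(abs(traj["O", ] - expected)), 1e-10)
})

test_that("zero-duration propagation is the identity", {
  Q <- two_state_Q(1, 2)
  out <- propagate_segment(c(0.4, 0.6), Q, 0, sample_dt = 0.1)
  expect_identical(ncol(out), 1L)
  expect_equal(out[, 1], c(C = 0.4, O = 0.6), ignore_attr = TRUE)
})

test_that("probability is conserved and bounded along gating trajectories", {
  for (sch in c("mmodel1", "mmodel2")) {
    p <- herg_parameters(sch, "hERG1b")
    Qh <- build_generator(sch, p, -80)
    p0 <- steady_state(Qh)
    for (V in c(-120, 0, 40)) {
      Q <- build_generator(sch, p, V)
      traj <- propagate_segment(p0, Q, duration = 500, sample_dt = 2)
      expect_lt(max(abs(colSums(traj) - 1)), 1e-9)
      expect_true(all(traj >= -1e-12 & traj <= 1 + 1e-12))
    }
  }
})

test_that("matrix-exponential propagation matches the fine-step Euler oracle", {
  p <- herg_parameters("mmodel1", "hERG1a")
  p0 <- steady_state(build_generator("mmodel1", p, 40))
  Q <- build_generator("mmodel1", p, -100)
  times <- c(50, 200, 1000)
  exact <- propagate_segment(p0, Q, duration = 1000, sample_dt = 50)
  euler <- euler_reference(p0, Q, duration = 1000, dt = 1e-4, times = times)
  for (i in seq_along(times)) {
    col <- which(abs(attr(exact, "time") - times[i]) < 1e-9)
    expect_lt(max(abs(exact[, col] - euler[, i])), 1e-6)
  }
})

test_that("the frozen-voltage RK4 kernel matches the matrix exponential", {
  # the cell engine advances Markov states with this kernel
  sch <- markov_scheme("mmodel1")
  p <- herg_parameters("mmodel1", "hERG1a")
  tr <- hergmarkov:::.spec_matrix(sch, p)
  p0 <- steady_state(build_generator(sch, p, -80))
  for (V in c(-100, 0, 40)) {
    nsteps <- 200L
    dt <- 0.005
    pk <- hergmarkov:::markov_advance(tr, as.numeric(p0), V, dt, nsteps)
    E <- propagate_segment(p0, build_generator(sch, p, V),
                           duration = nsteps * dt, sample_dt = nsteps * dt)
    expect_lt(max(abs(pk - E[, ncol(E)])), 1e-8)
  }
})
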