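test_that("the cost is zero at the data-generating corrections and rises away from them", {
  prob <- small_problem()      # targets generated at identity corrections
  expect_equal(residual_cost(list("bb.a" = 1), prob), 0)
  expect_gt(residual_cost(list("bb.a" = 1.3), prob), 1e-4)
  expect_gt(residual_cost(list("bb.a" = 0.7), prob), 1e-4)
})

test_that("dataset weights scale their cost contribution linearly", {
  prob <- small_problem()
  corr <- list("bb.a" = 1.5)
  c1 <- residual_cost(corr, prob)
  prob2 <- prob
  prob2$weights[2] <- 2
  c2 <- residual_cost(corr, prob2)
  # doubling one weight adds exactly that dataset's unweighted RSS
  rv <- hergmarkov:::.residual_vector(corr, prob)
  lens <- vapply(prob$datasets,
                 function(d) length(hergmarkov:::dataset_target_values(d)), 0L)
  rss2 <- sum(rv[(lens[1] + 1):sum(lens)]^2)
  expect_equal(c2 - c1, rss2, tolerance = 1e-10)
})

test_that("global_fit is deterministic and stays at a true optimum", {
  prob <- small_problem()
  f1 <- global_fit(prob, n_starts = 2, seed = 5)
  f2 <- global_fit(prob, n_starts = 2, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$starts, f2$starts)
  # one start from the true optimum returns it unchanged
  f0 <- global_fit(prob, n_starts = 1, seed = 1)
  expect_lt(f0$cost, 1e-12)
  expect_equal(unname(coef(f0)), 1, tolerance = 1e-4)
})

test_that("a known correction is recovered from noiseless synthetic data", {
  prob <- small_problem(truth_corr = list("bb.a" = 2.0))
  fit <- global_fit(prob, n_starts = 3, seed = 3)
  expect_equal(unname(coef(fit)), 2.0, tolerance = 0.01)
  expect_lt(fit$cost, 1e-8)
})

test_that("global_fit does not disturb the caller's RNG stream", {
  set.seed(99); a <- runif(1)
  set.seed(99)
  prob <- small_problem()
  invisible(global_fit(prob, n_starts = 2, seed = 5))
  expect_identical(runif(1), a)
})

test_that("stability_check flags structurally unidentifiable parameters", {
  # a beta-correction on a voltage-independent transition can have no effect
  prob <- small_problem(free = data.frame(transition = c("bb", "ain"),
                                          factor = c("a", "b")))
  fit <- global_fit(prob, n_starts = 1, seed = 1)
  rep <- stability_check(fit, prob, epsilon = 0.05, floor = 1e-6)
  expect_true(rep$unidentifiable[rep$parameter == "ain.b"])
  expect_false(rep$unidentifiable[rep$parameter == "bb.a"])
  expect_true(all(rep$curvature[!rep$unidentifiable] > 0))
})

test_that("simulation failures are penalized, not fatal", {
  prob <- small_problem()
  # corr_b far outside sensible range provokes rate overflow in simulation
  prob$bounds_b <- c(-100, 100)
  prob$free <- data.frame(transition = "bb", factor = "b")
  expect_silent({
    cost <- suppressMessages(residual_cost(list("bb.b" = -90), prob))
  })
  expect_true(is.finite(cost))
  expect_gt(cost, 1e4)
})
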