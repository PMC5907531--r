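test_that("scheme topologies have the expected states and transitions", {
  m1 <- markov_scheme("mmodel1")
  expect_identical(m1$states, c("C3", "C2", "C1", "O", "I"))
  expect_equal(nrow(m1$transitions), 8)
  expect_length(m1$loops, 0)
  m2 <- markov_scheme("mmodel2")
  expect_equal(nrow(m2$transitions), 10)
  expect_identical(m2$loops[[1]], c("C1", "O", "I"))
  expect_true(m2$transitions$constrained[m2$transitions$label == "ai2"])
})

test_that("the generator matrix is a proper master-equation generator", {
  for (sch in c("mmodel1", "mmodel2")) {
    for (iso in c("hERG1a", "hERG1b")) {
      p <- herg_parameters(sch, iso)
      for (V in c(-120, -80, 0, 40)) {
        Q <- build_generator(sch, p, V)
        expect_lt(max(abs(colSums(Q))), 1e-12)
        off <- Q; diag(off) <- 0
        expect_true(all(off >= 0))
        n_edges <- if (sch == "mmodel1") 8 else 10
        expect_equal(sum(off > 0), n_edges)
      }
    }
  }
  # chain topology: non-adjacent state pairs stay exactly zero
  Q <- build_generator("mmodel1", herg_parameters("mmodel1", "hERG1a"), -20)
  expect_identical(Q["O", "C3"], 0)
  expect_identical(Q["I", "C2"], 0)
  expect_identical(Q["C3", "C1"], 0)
})

test_that("generator entries carry the table rates", {
  # at V = 0 the entry is the bare alpha
  p <- herg_parameters("mmodel2", "hERG1a")
  Q <- build_generator("mmodel2", p, 0)
  expect_equal(Q["O", "C1"], 8.80e-2)
  # missing transition parameters are reported by name
  vals <- data.frame(transition = c("ae", "be", "ain", "bin", "ai", "bi", "aa"),
                     alpha = 0.01, beta = 0)
  expect_error(herg_params("mmodel1", vals), "bb")
})

test_that("microscopic reversibility closes the M-model 2 loop", {
  m1p <- herg_parameters("mmodel1", "hERG1a", resolve = FALSE)
  expect_identical(constrain_reversibility("mmodel1", m1p), m1p)

  sch <- markov_scheme("mmodel2")
  for (iso in c("hERG1a", "hERG1b")) {
    p <- herg_parameters("mmodel2", iso)
    if (iso == "hERG1a") {
      expect_equal(p$alpha[p$transition == "ai2"], 1.1124e-10,
                   tolerance = 1e-4)
    }
    # product of rates around the loop balances at any voltage
    rate <- function(lab, V) {
      r <- p[p$transition == lab, ]
      evaluate_rate(list(alpha = r$alpha, beta = r$beta,
                         corr_a = r$corr_a, corr_b = r$corr_b), V)
    }
    for (V in c(-120, -80, 0, 40, 60)) {
      cw <- rate("aa", V) * rate("bi", V) * rate("ai2", V)
      ccw <- rate("bb", V) * rate("ai", V) * rate("bi2", V)
      expect_lt(abs(cw / ccw - 1), 1e-10)
    }
  }
})

test_that("underdetermined loops are rejected", {
  sch <- markov_scheme("mmodel2")
  sch$transitions$constrained[sch$transitions$label == "bi2"] <- TRUE
  p <- herg_parameters("mmodel2", "hERG1a", resolve = FALSE)
  expect_error(constrain_reversibility(sch, p), "constrained edges")
})

test_that("voltage-independent transitions must have zero beta", {
  vals <- herg_parameters("mmodel1", "hERG1a")
  vals$beta[vals$transition == "ain"] <- 0.01
  expect_error(herg_params("mmodel1", as.data.frame(vals)), "ain")
})
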