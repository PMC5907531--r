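test_that("synthetic datasets are reproducible and honest at zero noise", {
  truth <- herg_parameters("mmodel1", "hERG1b")
  prots <- list(ssa = make_ssa_protocol(increment = 20))
  s1 <- generate_synthetic_dataset(truth, protocols = prots,
                                   noise_sd_fraction = 0.05, seed = 12,
                                   sample_dt = 2)
  s2 <- generate_synthetic_dataset(truth, protocols = prots,
                                   noise_sd_fraction = 0.05, seed = 12,
                                   sample_dt = 2)
  expect_identical(s1$datasets, s2$datasets)
  s3 <- generate_synthetic_dataset(truth, protocols = prots,
                                   noise_sd_fraction = 0.05, seed = 13,
                                   sample_dt = 2)
  expect_false(identical(s1$datasets$ssa$target$I_norm,
                         s3$datasets$ssa$target$I_norm))

  # zero noise reproduces the direct simulation bit-for-bit
  s0 <- generate_synthetic_dataset(truth, protocols = prots,
                                   noise_sd_fraction = 0, seed = 1,
                                   sample_dt = 2)
  direct <- tail_activation_curve(
    simulate_sweeps("mmodel1", truth, prots$ssa, current_params(),
                    sample_dt = 2))
  expect_identical(s0$datasets$ssa$target, direct)
})

test_that("the generator leaves the caller's RNG stream untouched", {
  truth <- herg_parameters("mmodel1", "hERG1a")
  prots <- list(ssa = make_ssa_protocol(increment = 70))
  set.seed(123); ref <- runif(1)
  set.seed(123)
  invisible(generate_synthetic_dataset(truth, protocols = prots,
                                       noise_sd_fraction = 0.02, seed = 5,
                                       sample_dt = 2))
  expect_identical(runif(1), ref)
})
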