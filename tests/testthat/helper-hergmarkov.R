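# shared fixtures built in code

# two-state C <-> O generator with forward rate f (C->O) and backward b
two_state_Q <- function(f, b) {
  matrix(c(-f, f, b, -b), nrow = 2,
         dimnames = list(c("C", "O"), c("C", "O")))
}

room_cp <- function() current_params()   # room-temperature defaults

# a small, fast fitting problem used by several fitting tests:
# SSA (coarse sweep) + a single short deactivation sweep
small_problem <- function(truth_corr = NULL, noise = 0, seed = 1,
                          free = data.frame(transition = "bb", factor = "a")) {
  base <- herg_parameters("mmodel1", "hERG1a")
  truth <- if (is.null(truth_corr)) base else apply_corrections(base, truth_corr)
  prots <- list(ssa = make_ssa_protocol(increment = 20),
                deactivation = make_deactivation_protocol(test_voltages = -100,
                                                          test_ms = 1500))
  syn <- generate_synthetic_dataset(truth, protocols = prots,
                                    noise_sd_fraction = noise, seed = seed,
                                    sample_dt = 2,
                                    deact_grid = c(0, round(exp(seq(log(5), log(1400),
                                                                    length.out = 15)), 1)))
  fit_problem("mmodel1", base, syn$datasets, free = free, sample_dt = 2)
}
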