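#' Seeded synthetic multi-protocol dataset
#'
#' Simulates the four standard protocols from a known ("truth") parameter
#' set, derives the fitted observables (normalized SSA activation curve,
#' envelope activation curve, normalized deactivation time courses,
#' recovery time constants) and adds seeded additive Gaussian noise with
#' standard deviation expressed as a fraction of the per-trace peak: for
#' the normalized curve observables that is the dataset's peak absolute
#' value; each recovery time constant derives from its own trace and is
#' perturbed relative to its own magnitude. Deactivation time courses are
#' sampled on a log-uniform grid, the standard design for multi-exponential
#' decays (it weights fast and slow phases evenly and keeps the datasets
#' comparable in size). With zero noise the targets equal the direct
#' simulation bit-for-bit; regeneration with the same seed is
#' bit-identical. The result plugs straight into \code{\link{fit_problem}}.
#'
#' @param truth A \code{\link{herg_params}} set (the data-generating
#'   kinetics).
#' @param scheme A \code{\link{markov_scheme}} or name (default: the
#'   truth's scheme).
#' @param protocols Named list of \code{\link{voltage_protocol}}s keyed by
#'   dataset kind; defaults to the four standard protocols.
#' @param noise_sd_fraction Noise SD as a fraction of the per-dataset peak
#'   (>= 0).
#' @param seed Integer seed.
#' @param cp A \code{\link{current_params}} object.
#' @param sample_dt Simulation sampling interval (ms).
#' @param deact_grid Time offsets (ms, from the measurement-segment start)
#'   at which the deactivation time course is sampled.
#' @return Object of class \code{"synthetic_dataset"}: list with
#'   \code{datasets} (for \code{\link{fit_problem}}), \code{truth},
#'   \code{seed}, \code{noise_sd_fraction}.
#' @export
generate_synthetic_dataset <- function(truth,
                                       scheme = attr(truth, "scheme"),
                                       protocols = list(
                                         ssa = make_ssa_protocol(),
                                         envelope = make_envelope_protocol(),
                                         deactivation = make_deactivation_protocol(),
                                         recovery = make_recovery_protocol()),
                                       noise_sd_fraction = 0,
                                       seed = 1,
                                       cp = current_params(),
                                       sample_dt = 1,
                                       deact_grid = c(0, round(exp(seq(log(5), log(4000),
                                                                       length.out = 25)), 1))) {
  stopifnot(noise_sd_fraction >= 0)
  if (is.character(scheme)) scheme <- markov_scheme(scheme)

  datasets <- lapply(names(protocols), function(kind) {
    prot <- protocols[[kind]]
    traces <- simulate_sweeps(scheme, truth, prot, cp,
                              sample_dt = .kind_dt(kind, sample_dt))
    target <- switch(kind,
      ssa = tail_activation_curve(traces),
      envelope = activation_envelope_curve(traces),
      deactivation = {
        do.call(rbind, lapply(traces, function(tr) {
          idx <- segment_window(tr, attr(tr, "measurement_segment"))
          t0 <- tr$time[idx[1]]
          y <- tr$current[idx] / max(abs(tr$current[idx]))
          grid <- deact_grid[deact_grid <= tr$time[idx[length(idx)]] - t0]
          data.frame(sweep = attr(tr, "sweep_value"), time = grid,
                     norm = stats::approx(tr$time[idx] - t0, y, xout = grid,
                                          rule = 2)$y)
        }))
      },
      recovery = data.frame(
        V = vapply(traces, function(tr) attr(tr, "sweep_value"), 0),
        tau = vapply(traces, fit_recovery_tau, 0)),
      stop("unknown protocol kind '", kind, "'"))
    names(target) <- names(target)  # keep data.frame
    list(kind = kind, protocol = prot, target = target)
  })
  names(datasets) <- names(protocols)

  if (noise_sd_fraction > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    datasets <- lapply(datasets, function(ds) {
      vals <- dataset_target_values(ds)
      sdv <- if (ds$kind == "recovery") {
        noise_sd_fraction * abs(vals)   # each tau comes from its own trace
      } else {
        noise_sd_fraction * max(abs(vals))
      }
      noisy <- vals + stats::rnorm(length(vals), sd = sdv)
      col <- switch(ds$kind, ssa = "I_norm", envelope = "norm",
                    deactivation = "norm", recovery = "tau")
      ds$target[[col]] <- noisy
      ds
    })
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }

  structure(list(datasets = datasets, truth = truth, seed = seed,
                 noise_sd_fraction = noise_sd_fraction),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d protocol(s) [%s], noise SD = %.3g of peak, seed %d\n",
              length(x$datasets), paste(names(x$datasets), collapse = ", "),
              x$noise_sd_fraction, x$seed))
  invisible(x)
}
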