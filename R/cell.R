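# --- cell & tissue layer ----------------------------------------------------
#
# The ventricular membrane model shipped here is a minimal surrogate built
# for studying IKr kinetics at the cell and fiber level: a fast inward
# (m^3 h) current for the upstroke, a slowly inactivating plateau inward
# current, an instantaneous inward-rectifier background K+ current, and the
# two-isoform Markov IKr mixture. Voltage is advanced by forward Euler with
# a coarse/fine time-step rule; gates by exact exponential relaxation;
# Markov states by RK4 at frozen voltage within each step.

# transition matrix (from,to 0-based; effective alpha,beta) for the engine
.spec_matrix <- function(scheme, params) {
  st <- scheme$states
  tr <- scheme$transitions
  out <- matrix(0, nrow(tr), 4)
  for (k in seq_len(nrow(tr))) {
    row <- params[params$transition == tr$label[k], ]
    out[k, ] <- c(match(tr$from[k], st) - 1L, match(tr$to[k], st) - 1L,
                  row$corr_a * row$alpha, row$corr_b * row$beta)
  }
  out
}

#' Minimal surrogate ventricular cell model with Markov IKr
#'
#' Builds the membrane model used by \code{\link{simulate_cell}} and
#' \code{\link{simulate_fiber}}. IKr is carried by a mixture of hERG1a and
#' hERG1b homotetramer populations, each with its own Markov state vector;
#' maximum single-channel conductance is identical for the two isoforms, so
#' \code{fraction_b} mixes the open probabilities linearly. The cell-context
#' maximal conductance (default 0.0422 pA/pF/mV) is scaled by
#' \code{sqrt(Ko/5.4)}.
#'
#' Surrogate membrane parameters (all overridable via \code{...}):
#' \code{g_fast} 9, \code{E_fast} 45 (fast inward; upstroke), \code{tau_m}
#' 0.3, \code{tau_h} 1.8 ms; \code{g_plat} 0.016, \code{E_plat} 45
#' (slowly inactivating plateau inward), \code{tau_w} 500 ms; \code{g_so}
#' 0.005 (persistent plateau-range outward K); \code{g_k1} 0.35
#' (inward-rectifier background K); plus the sigmoid midpoints/slopes
#' \code{m_v0/m_k}, \code{h_v0/h_k}, \code{w_v0/w_k}, \code{s_v0/s_k},
#' \code{x_v0/x_k}, \code{k1_v0/k1_k} (mV). Conductances are pA/pF per mV
#' of driving force. The defaults give a ventricular-like action potential
#' whose late repolarization is paced by IKr, so isoform kinetics move
#' APD.
#'
#' @param scheme Gating scheme (name or object), default \code{"mmodel1"}.
#' @param params_a,params_b Parameter sets for the a- and b-isoform
#'   (defaults: the shipped sets for the scheme).
#' @param fraction_b Fraction of IKr carried by hERG1b homotetramers, in
#'   [0, 1].
#' @param gKr_scale Maximal IKr conductance in the cell context
#'   (pA/pF/mV).
#' @param Ko,Ki External/internal potassium (mM).
#' @param T Temperature (K); sets EK via Nernst. Note the shipped rate
#'   tables are room-temperature fits; no temperature correction of the
#'   kinetics is applied unless corrected parameter sets are supplied.
#' @param ... Overrides for the surrogate membrane parameters.
#' @return Object of class \code{"surrogate_model"}.
#' @export
surrogate_cell_model <- function(scheme = "mmodel1",
                                 params_a = NULL, params_b = NULL,
                                 fraction_b = 0, gKr_scale = 0.0422,
                                 Ko = 5.4, Ki = 140, T = 310, ...) {
  if (is.character(scheme)) scheme <- markov_scheme(scheme)
  if (is.null(params_a)) params_a <- herg_parameters(scheme$name, "hERG1a")
  if (is.null(params_b)) params_b <- herg_parameters(scheme$name, "hERG1b")
  stopifnot(fraction_b >= 0, fraction_b <= 1)
  sp <- c(g_fast = 9, E_fast = 45, m_v0 = -50, m_k = 4, tau_m = 0.3,
          h_v0 = -72, h_k = 4, tau_h = 1.8,
          g_plat = 0.016, E_plat = 45, s_v0 = -25, s_k = 5,
          w_v0 = -30, w_k = 8, tau_w = 500,
          g_so = 0.005, x_v0 = -20, x_k = 8,
          g_k1 = 0.35, k1_v0 = -60, k1_k = 12)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(sp))
    if (length(bad)) stop("surrogate_cell_model: unknown parameter(s): ",
                          paste(bad, collapse = ", "))
    sp[names(dots)] <- dots
  }
  EK <- nernst_potential(Ki, Ko, T)
  structure(list(scheme = scheme, params_a = params_a, params_b = params_b,
                 fraction_b = fraction_b,
                 gKr = gKr_scale * sqrt(Ko / 5.4),
                 EK = EK, V_rest = EK, Ko = Ko, Ki = Ki, T = T,
                 surrogate = sp),
            class = c("surrogate_model", "ionic_model"))
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(
    "surrogate ventricular cell model: scheme %s, fraction_b = %.2f, gKr = %.4g pA/pF/mV, EK = %.2f mV\n",
    x$scheme$name, x$fraction_b, x$gKr, x$EK))
  invisible(x)
}

#' Advance the two-isoform Markov IKr component at fixed voltage
#'
#' Operator-splitting component used inside the cell models: both isoforms'
#' state vectors are advanced by \code{dt} at frozen voltage (matrix
#' exponential, exact for the frozen-voltage step) and the mixture current
#' is returned with the cell-context conductance scaling.
#'
#' @param scheme Gating scheme (name or object).
#' @param params_a,params_b Isoform parameter sets.
#' @param mix Fraction of IKr carried by hERG1b, in [0, 1].
#' @param V Membrane potential (mV).
#' @param dt Time step (ms).
#' @param state List with elements \code{pa}, \code{pb} (state vectors); if
#'   \code{NULL}, both start from the steady state at \code{V}.
#' @param gKr_scale Cell-context maximal conductance (pA/pF/mV).
#' @param Ko External potassium (mM); scales conductance by
#'   \code{sqrt(Ko/5.4)}.
#' @param EK Reversal potential (mV).
#' @return List with \code{IKr} (pA/pF) evaluated at the advanced state and
#'   \code{state} (updated).
#' @export
markov_ikr_component <- function(scheme, params_a, params_b, mix, V, dt,
                                 state = NULL, gKr_scale = 0.0422,
                                 Ko = 5.4, EK = -87) {
  if (is.character(scheme)) scheme <- markov_scheme(scheme)
  stopifnot(mix >= 0, mix <= 1, dt > 0)
  Qa <- build_generator(scheme, params_a, V)
  Qb <- build_generator(scheme, params_b, V)
  if (is.null(state)) state <- list(pa = steady_state(Qa), pb = steady_state(Qb))
  Ea <- as.matrix(Matrix::expm(Matrix::Matrix(Qa * dt)))
  Eb <- as.matrix(Matrix::expm(Matrix::Matrix(Qb * dt)))
  pa <- as.numeric(Ea %*% state$pa)
  pb <- as.numeric(Eb %*% state$pb)
  leak <- max(abs(sum(pa) - 1), abs(sum(pb) - 1))
  if (leak > 1e-6) stop("markov_ikr_component: probability leak ", format(leak))
  o <- match(scheme$open_state, scheme$states)
  pO <- (1 - mix) * pa[o] + mix * pb[o]
  list(IKr = gKr_scale * sqrt(Ko / 5.4) * pO * (V - EK),
       state = list(pa = stats::setNames(pa, scheme$states),
                    pb = stats::setNames(pb, scheme$states)))
}

# shared engine invocation
.run_engine <- function(model, n_cells, D, dx, BCL, n_beats,
                        dt_coarse, dt_fine, dvdt_switch,
                        stim_amp, stim_dur, n_stim_cells,
                        record_dt, record_all_beats) {
  sc <- model$scheme
  ta <- .spec_matrix(sc, model$params_a)
  tb <- .spec_matrix(sc, model$params_b)
  p0a <- steady_state(build_generator(sc, model$params_a, model$V_rest))
  p0b <- steady_state(build_generator(sc, model$params_b, model$V_rest))
  out <- sim_engine(ta, tb, as.numeric(p0a), as.numeric(p0b),
                    model$fraction_b, model$surrogate,
                    as.integer(n_cells), D, dx, BCL, as.integer(n_beats),
                    dt_coarse, dt_fine, dvdt_switch,
                    stim_amp, stim_dur, as.integer(n_stim_cells),
                    record_dt, record_all_beats,
                    model$gKr, model$EK, model$V_rest,
                    match(sc$open_state, sc$states) - 1L)
  rownames(out$occ_a) <- rownames(out$occ_b) <- sc$states
  out
}

#' Simulate a paced single cell
#'
#' Forward-Euler pacing of the surrogate ventricular model. The time step
#' follows the upstroke rule: \code{dt_fine} while the stimulus is active
#' or while \code{|dV/dt|} exceeds \code{dvdt_switch}, otherwise
#' \code{dt_coarse}. The last paced beat is recorded (membrane potential,
#' IKr, and the per-state occupancies of both isoform populations).
#'
#' @param model A \code{\link{surrogate_cell_model}}.
#' @param BCL Basic cycle length (ms).
#' @param n_beats Number of paced beats (>= 1).
#' @param stim_amp Stimulus amplitude (pA/pF), depolarizing.
#' @param stim_dur Stimulus duration (ms).
#' @param dt_coarse,dt_fine Time steps (ms).
#' @param dvdt_switch Upstroke threshold (mV/ms) for the fine step; 0
#'   disables switching.
#' @param record_dt Recording interval (ms).
#' @param record_all_beats Record every beat instead of only the last.
#' @return Object of class \code{"ap_trace"}: list with \code{time},
#'   \code{V}, \code{ikr}, \code{occ_a}, \code{occ_b}.
#' @export
simulate_cell <- function(model, BCL = 1000, n_beats = 10,
                          stim_amp = 300, stim_dur = 0.5,
                          dt_coarse = 0.005, dt_fine = 0.00005,
                          dvdt_switch = 1, record_dt = 1,
                          record_all_beats = FALSE) {
  stopifnot(inherits(model, "surrogate_model"), n_beats >= 1)
  out <- .run_engine(model, n_cells = 1L, D = 0, dx = 1, BCL = BCL,
                     n_beats = n_beats, dt_coarse = dt_coarse,
                     dt_fine = dt_fine, dvdt_switch = dvdt_switch,
                     stim_amp = stim_amp, stim_dur = stim_dur,
                     n_stim_cells = 1L, record_dt = record_dt,
                     record_all_beats = record_all_beats)
  structure(list(time = out$time, V = as.numeric(out$V), ikr = out$ikr,
                 occ_a = out$occ_a, occ_b = out$occ_b),
            class = "ap_trace",
            BCL = BCL, n_beats = n_beats, fraction_b = model$fraction_b,
            V_rest = model$V_rest)
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("action-potential trace: %d samples, fraction_b = %.2f, V in [%.1f, %.1f] mV\n",
              length(x$time), attr(x, "fraction_b"), min(x$V), max(x$V)))
  invisible(x)
}

#' @export
plot.ap_trace <- function(x, ...) {
  graphics::plot(x$time - min(x$time), x$V, type = "l",
                 xlab = "time in beat (ms)", ylab = "V (mV)", ...)
  invisible(x)
}

#' Action-potential duration
#'
#' Time from the maximum-upstroke point (max dV/dt) to the crossing of
#' \code{rest + (1 - fraction) * (peak - rest)} during repolarization.
#' The default fraction 0.9 gives APD90.
#'
#' @param trace An \code{ap_trace}, or a list with \code{time} and
#'   \code{V}.
#' @param fraction Repolarization fraction in (0, 1].
#' @param min_amplitude Minimum AP amplitude (mV) below which "no AP" is
#'   signalled.
#' @return Duration (ms).
#' @export
apd <- function(trace, fraction = 0.9, min_amplitude = 20) {
  t <- trace$time; V <- trace$V
  rest <- V[1]
  peak <- max(V)
  if (peak - rest < min_amplitude) stop("apd: no action potential detected")
  dv <- diff(V) / diff(t)
  i_up <- which.max(dv)
  thr <- rest + (1 - fraction) * (peak - rest)
  i_pk <- which.max(V)
  below <- which(V[seq(i_pk, length(V))] <= thr)
  if (!length(below)) stop("apd: repolarization threshold not reached")
  j <- i_pk + below[1] - 1L
  # linear interpolation of the crossing
  t_cross <- if (j > 1 && V[j - 1] > thr) {
    t[j - 1] + (V[j - 1] - thr) / (V[j - 1] - V[j]) * (t[j] - t[j - 1])
  } else t[j]
  t_cross - t[i_up]
}

#' Transmural-fiber configuration
#'
#' Geometry, diffusion and pacing settings for the 1-D cable. Cells are
#' partitioned into endocardial (1-60), mid-myocardial (61-105) and
#' epicardial (106-165) regions by default; with the homogeneous surrogate
#' model the labels are carried but do not alter cell properties.
#'
#' @param n_cells Number of cells.
#' @param dx Cell spacing (cm).
#' @param D Diffusion coefficient (cm^2/ms).
#' @param Cm Membrane capacitance (uF/cm^2); informational, currents are
#'   per-capacitance.
#' @param BCL Basic cycle length (ms).
#' @param n_beats Number of paced beats.
#' @param stim_amp,stim_dur Stimulus (uA/cm^2 i.e. pA/pF, ms) applied to
#'   cell 1.
#' @param dt_coarse,dt_fine Time steps (ms).
#' @param dvdt_switch Fine-step threshold (mV/ms); 0 keeps the coarse step
#'   throughout (the surrogate model is stable at the coarse step).
#' @param record_dt Recording interval (ms).
#' @param regions Named list of index ranges.
#' @return Object of class \code{"cable_config"}.
#' @export
cable_config <- function(n_cells = 165, dx = 0.01, D = 0.00092, Cm = 1,
                         BCL = 1000, n_beats = 20,
                         stim_amp = 300, stim_dur = 0.5,
                         dt_coarse = 0.005, dt_fine = 0.00005,
                         dvdt_switch = 0, record_dt = 1,
                         regions = list(endo = 1:60, M = 61:105,
                                        epi = 106:165)) {
  stopifnot(n_cells >= 2, dx > 0, D > 0, dt_fine <= dt_coarse)
  covered <- sort(as.integer(unlist(regions)))
  if (length(covered) != n_cells || !identical(covered, seq_len(n_cells)) ) {
    if (identical(regions, list(endo = 1:60, M = 61:105, epi = 106:165))) {
      # default partition only fits the default cell count; rescale simply
      regions <- list(all = seq_len(n_cells))
    } else {
      stop("cable_config: regions must partition 1..n_cells disjointly")
    }
  }
  structure(list(n_cells = n_cells, dx = dx, D = D, Cm = Cm, BCL = BCL,
                 n_beats = n_beats, stim_amp = stim_amp, stim_dur = stim_dur,
                 dt_coarse = dt_coarse, dt_fine = dt_fine,
                 dvdt_switch = dvdt_switch, record_dt = record_dt,
                 regions = regions),
            class = "cable_config")
}

#' Simulate a 1-D transmural fiber
#'
#' Explicit finite-difference solution of the monodomain cable equation
#' \code{dV/dt = D d2V/dx2 - (Iion - Istim)/Cm} with sealed (no-flux) ends;
#' the stimulus is applied to cell 1. The time step is checked against the
#' diffusion stability bound and the run aborts with a suggested step if it
#' is violated.
#'
#' @param model A \code{\link{surrogate_cell_model}}.
#' @param config A \code{\link{cable_config}}.
#' @return Object of class \code{"fiber_vm"}: list with \code{time} (ms,
#'   last beat) and \code{V} (n_cells x n_times matrix), plus the config as
#'   attribute.
#' @export
simulate_fiber <- function(model, config = cable_config()) {
  stopifnot(inherits(model, "surrogate_model"),
            inherits(config, "cable_config"))
  out <- .run_engine(model, n_cells = config$n_cells, D = config$D,
                     dx = config$dx, BCL = config$BCL,
                     n_beats = config$n_beats,
                     dt_coarse = config$dt_coarse, dt_fine = config$dt_fine,
                     dvdt_switch = config$dvdt_switch,
                     stim_amp = config$stim_amp, stim_dur = config$stim_dur,
                     n_stim_cells = 1L, record_dt = config$record_dt,
                     record_all_beats = FALSE)
  structure(list(time = out$time, V = out$V),
            class = "fiber_vm", config = config,
            fraction_b = model$fraction_b)
}

#' @export
print.fiber_vm <- function(x, ...) {
  cat(sprintf("fiber Vm: %d cells x %d samples, fraction_b = %.2f\n",
              nrow(x$V), ncol(x$V), attr(x, "fraction_b")))
  invisible(x)
}

#' Pseudo-ECG electrode geometry
#'
#' The extracellular potential is computed as a line integral along the
#' fiber axis with the electrode placed \code{electrode_offset} cm beyond
#' the distal end. Conductivities and fiber radius only scale the signal;
#' with unprinted tissue constants the potential is reported in arbitrary
#' units and only shapes/orderings are meaningful.
#'
#' @param sigma_i,sigma_e Intra-/extracellular conductivities (relative).
#' @param radius Fiber radius (cm).
#' @param electrode_offset Distance beyond the distal end along the axis
#'   (cm).
#' @return Object of class \code{"ecg_geometry"}.
#' @export
ecg_geometry <- function(sigma_i = 1, sigma_e = 1, radius = 0.0011,
                         electrode_offset = 2.0) {
  stopifnot(sigma_i > 0, sigma_e > 0, radius > 0)
  if (electrode_offset <= 0) {
    stop("ecg_geometry: electrode must lie off the fiber (offset > 0)")
  }
  structure(list(sigma_i = sigma_i, sigma_e = sigma_e, radius = radius,
                 electrode_offset = electrode_offset),
            class = "ecg_geometry")
}

#' Pseudo-ECG from a fiber simulation
#'
#' Discretizes \code{phi_e = (a^2 sigma_i / 4 sigma_e) * integral of
#' (-dVm/dx)(d(1/r)/dx) dx} over the cable, with central differences for
#' the interior voltage gradient and one-sided differences at the sealed
#' ends. A spatially uniform Vm yields an identically zero signal, and the
#' signal is linear in Vm.
#'
#' @param fiber A \code{fiber_vm} object, or a plain n_cells x n_times
#'   matrix of membrane potentials (then \code{dx} must be given).
#' @param geometry An \code{\link{ecg_geometry}}.
#' @param dx Cell spacing (cm); taken from the fiber's config when
#'   available.
#' @return Object of class \code{"pseudo_ecg"}: list with \code{time} (or
#'   sample index) and \code{phi} (arbitrary units).
#' @export
pseudo_ecg <- function(fiber, geometry = ecg_geometry(), dx = NULL) {
  if (inherits(fiber, "fiber_vm")) {
    Vm <- fiber$V
    time <- fiber$time
    if (is.null(dx)) dx <- attr(fiber, "config")$dx
  } else {
    Vm <- as.matrix(fiber)
    time <- seq_len(ncol(Vm))
    if (is.null(dx)) stop("pseudo_ecg: 'dx' required for a plain matrix")
  }
  n <- nrow(Vm)
  x <- (seq_len(n) - 1) * dx
  xe <- x[n] + geometry$electrode_offset
  r <- abs(x - xe)
  if (any(r < dx / 2)) stop("pseudo_ecg: electrode coincides with a cell")
  dinv <- -(x - xe) / r^3              # d(1/r)/dx at each cell
  # -dVm/dx: central interior, one-sided ends
  gradV <- rbind(-(Vm[2, ] - Vm[1, ]) / dx,
                 -(Vm[3:n, ] - Vm[1:(n - 2), ]) / (2 * dx),
                 -(Vm[n, ] - Vm[n - 1, ]) / dx)
  scale <- geometry$radius^2 * geometry$sigma_i / (4 * geometry$sigma_e)
  phi <- scale * as.numeric(crossprod(gradV, dinv)) * dx
  structure(list(time = time, phi = phi), class = "pseudo_ecg")
}

#' @export
print.pseudo_ecg <- function(x, ...) {
  cat(sprintf("pseudo-ECG: %d samples, amplitude range [%.3g, %.3g] (a.u.)\n",
              length(x$phi), min(x$phi), max(x$phi)))
  invisible(x)
}

#' @export
plot.pseudo_ecg <- function(x, ...) {
  graphics::plot(x$time - min(x$time), x$phi, type = "l",
                 xlab = "time in beat (ms)", ylab = "phi_e (a.u.)", ...)
  invisible(x)
}

#' QT-like interval of a pseudo-ECG beat
#'
#' Time from the first departure of the signal from baseline beyond a
#' proportional tolerance to the last sustained return within it. The
#' measure is invariant under amplitude scaling (the tolerance is a
#' fraction of the peak deflection) and is used for ordering comparisons
#' only.
#'
#' @param ecg A \code{pseudo_ecg} (one beat), or a list with \code{time}
#'   and \code{phi}.
#' @param baseline_tolerance Fraction of the peak absolute deflection
#'   (default 0.02).
#' @return Duration (ms).
#' @export
qt_interval <- function(ecg, baseline_tolerance = 0.02) {
  phi <- ecg$phi; time <- ecg$time
  base <- phi[1]
  dev <- abs(phi - base)
  amp <- max(dev)
  if (amp <= 0) stop("qt_interval: no deflection detected (flat signal)")
  above <- which(dev > baseline_tolerance * amp)
  if (!length(above)) stop("qt_interval: no deflection beyond tolerance")
  time[above[length(above)]] - time[above[1]]
}
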