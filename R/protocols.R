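#' Voltage-clamp protocol
#'
#' A protocol is an ordered list of constant-voltage segments with one sweep
#' variable (a segment's voltage or duration) taking a list of values, plus
#' the index of the segment that is analyzed. Sweeps are initialized at the
#' steady state of the holding potential.
#'
#' @param name Protocol name.
#' @param segments Data frame with columns \code{duration} (ms) and
#'   \code{voltage} (mV); the swept field may be \code{NA}.
#' @param sweep List with \code{segment} (index), \code{field}
#'   (\code{"voltage"} or \code{"duration"}) and \code{values} (sorted).
#' @param measurement_segment Index of the analyzed segment.
#' @param holding Holding potential (mV), default -80.
#' @return An object of class \code{"voltage_protocol"}.
#' @export
voltage_protocol <- function(name, segments, sweep, measurement_segment,
                             holding = -80) {
  stopifnot(is.data.frame(segments),
            all(c("duration", "voltage") %in% names(segments)))
  fixed_dur <- segments$duration[-sweep$segment]
  if (sweep$field == "voltage") fixed_dur <- segments$duration
  if (any(stats::na.omit(fixed_dur) <= 0)) {
    stop("voltage_protocol: segment durations must be > 0")
  }
  if (!length(sweep$values)) stop("voltage_protocol: sweep values must be non-empty")
  if (is.unsorted(sweep$values)) stop("voltage_protocol: sweep values must be sorted")
  stopifnot(sweep$field %in% c("voltage", "duration"),
            sweep$segment >= 1, sweep$segment <= nrow(segments),
            measurement_segment >= 1, measurement_segment <= nrow(segments))
  structure(list(name = name, segments = segments, sweep = sweep,
                 measurement_segment = measurement_segment,
                 holding = holding),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("voltage protocol '%s': hold %g mV, %d segments, %d sweeps (%s of segment %d)\n",
              x$name, x$holding, nrow(x$segments), length(x$sweep$values),
              x$sweep$field, x$sweep$segment))
  invisible(x)
}

# segment table for one sweep value
realize_sweep <- function(protocol, value) {
  seg <- protocol$segments
  seg[[protocol$sweep$field]][protocol$sweep$segment] <- value
  seg
}

#' Steady-state activation (SSA) protocol
#'
#' From a holding potential of -80 mV, 1-s depolarizing steps over a range
#' of voltages are each followed by a 1-s step to -100 mV during which the
#' tail current is recorded.
#'
#' @param step_min,step_max Test-voltage range (mV).
#' @param increment Voltage increment (mV).
#' @return A \code{\link{voltage_protocol}} with the tail segment as the
#'   measurement segment.
#' @export
make_ssa_protocol <- function(step_min = -100, step_max = 40, increment = 10) {
  stopifnot(step_min < step_max, increment > 0)
  voltage_protocol(
    name = "ssa",
    segments = data.frame(duration = c(1000, 1000), voltage = c(NA, -100)),
    sweep = list(segment = 1L, field = "voltage",
                 values = seq(step_min, step_max, by = increment)),
    measurement_segment = 2L
  )
}

#' Envelope-of-tails protocol
#'
#' Channels are activated at +40 mV for a range of durations; the tail
#' current is then recorded at -100 mV for 3 s. The peak tail amplitude
#' traces the time course of activation.
#'
#' @param durations Activating-step durations (ms), positive and sorted.
#' @return A \code{\link{voltage_protocol}}.
#' @export
make_envelope_protocol <- function(durations = c(5, 10, 20, 50, 100, 200, 300, 400, 500)) {
  stopifnot(length(durations) >= 1, all(durations > 0), !is.unsorted(durations))
  voltage_protocol(
    name = "envelope",
    segments = data.frame(duration = c(NA, 3000), voltage = c(40, -100)),
    sweep = list(segment = 1L, field = "duration", values = durations),
    measurement_segment = 2L
  )
}

#' Deactivation protocol
#'
#' Channels are activated at +40 mV, repolarized for 5 ms to -120 mV (to let
#' them recover from inactivation), then held at the test voltage while the
#' deactivating tail is recorded.
#'
#' @param test_voltages Deactivating voltages (mV), within [-140, 0].
#' @param activation_ms Duration of the +40 mV activating step (ms).
#' @param test_ms Duration of the recorded deactivating segment (ms).
#' @return A \code{\link{voltage_protocol}}.
#' @export
make_deactivation_protocol <- function(test_voltages = c(-120, -100, -60, -40),
                                       activation_ms = 1000, test_ms = 5000) {
  if (!length(test_voltages)) stop("make_deactivation_protocol: empty voltage list")
  stopifnot(all(test_voltages >= -140), all(test_voltages <= 0))
  voltage_protocol(
    name = "deactivation",
    segments = data.frame(duration = c(activation_ms, 5, test_ms),
                          voltage = c(40, -120, NA)),
    sweep = list(segment = 3L, field = "voltage",
                 values = sort(test_voltages)),
    measurement_segment = 3L
  )
}

#' Recovery-from-inactivation protocol
#'
#' A 1-s step to +40 mV drives channels into the inactivated state; at the
#' hyperpolarized test voltage the current transiently rises (the "hook") as
#' channels recover into the open state before deactivating. The rising
#' phase of the hook is the analyzed window.
#'
#' @param test_voltages Test voltages (mV), below +40.
#' @param conditioning_ms Duration of the inactivating +40 mV step (ms).
#' @param test_ms Duration of the recorded test segment (ms).
#' @return A \code{\link{voltage_protocol}}.
#' @export
make_recovery_protocol <- function(test_voltages = c(-100, -50),
                                   conditioning_ms = 1000, test_ms = 500) {
  if (!length(test_voltages)) stop("make_recovery_protocol: empty voltage list")
  stopifnot(all(test_voltages < 40))
  voltage_protocol(
    name = "recovery",
    segments = data.frame(duration = c(conditioning_ms, test_ms),
                          voltage = c(40, NA)),
    sweep = list(segment = 2L, field = "voltage",
                 values = sort(test_voltages)),
    measurement_segment = 2L
  )
}

#' Simulate every sweep of a voltage protocol
#'
#' Each sweep starts from the steady state at the holding potential; each
#' constant-voltage segment is propagated with the matrix exponential and
#' the IKr current is computed from the open-state occupancy. The sample at
#' a segment boundary is assigned to the incoming segment's voltage.
#'
#' @param scheme A \code{\link{markov_scheme}} or scheme name.
#' @param params A \code{\link{herg_params}} set (constraints resolved).
#' @param protocol A \code{\link{voltage_protocol}}.
#' @param cp A \code{\link{current_params}} object.
#' @param sample_dt Sampling interval (ms), default 0.1.
#' @param keep_states Keep the full state-occupancy matrix on each trace.
#' @return List of \code{current_trace} objects (one per sweep), each a list
#'   with \code{time} and \code{current} plus condition attributes.
#' @export
simulate_sweeps <- function(scheme, params, protocol, cp,
                            sample_dt = 0.1, keep_states = FALSE) {
  if (is.character(scheme)) scheme <- markov_scheme(scheme)
  open_idx <- match(scheme$open_state, scheme$states)
  Qhold <- build_generator(scheme, params, protocol$holding)
  p_hold <- steady_state(Qhold)
  lapply(protocol$sweep$values, function(val) {
    seg <- realize_sweep(protocol, val)
    p <- p_hold
    time <- numeric(0); current <- numeric(0)
    states <- NULL
    seg_starts <- cumsum(c(0, seg$duration[-nrow(seg)]))
    t0 <- 0
    for (k in seq_len(nrow(seg))) {
      Q <- build_generator(scheme, params, seg$voltage[k])
      traj <- propagate_segment(p, Q, seg$duration[k], sample_dt)
      tt <- attr(traj, "time")
      p <- traj[, ncol(traj)]
      keep <- if (k < nrow(seg)) seq_len(ncol(traj) - 1L) else seq_len(ncol(traj))
      time <- c(time, t0 + tt[keep])
      current <- c(current,
                   ikr_current(traj[open_idx, keep], seg$voltage[k], cp))
      if (keep_states) states <- cbind(states, traj[, keep, drop = FALSE])
      t0 <- t0 + seg$duration[k]
    }
    structure(list(time = time, current = current,
                   states = if (keep_states) states else NULL),
              class = "current_trace",
              protocol = protocol$name,
              sweep_value = val,
              segment_starts = seg_starts,
              segment_voltages = seg$voltage,
              measurement_segment = protocol$measurement_segment,
              temperature = cp$T, Ko = cp$Ko, EK = cp$EK,
              isoform = attr(params, "isoform"),
              scheme = scheme$name)
  })
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current trace: protocol %s, sweep value %s, %d samples over %.5g ms\n",
              attr(x, "protocol"), format(attr(x, "sweep_value")),
              length(x$time), max(x$time)))
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  graphics::plot(x$time, x$current, type = "l", xlab = "time (ms)",
                 ylab = "current (pA/pF)", ...)
  graphics::abline(v = attr(x, "segment_starts")[-1], lty = 3, col = "grey")
  invisible(x)
}

# index window of a segment within a trace (left-closed; last segment
# includes the final sample)
segment_window <- function(trace, segment_index) {
  starts <- attr(trace, "segment_starts")
  if (segment_index < 1 || segment_index > length(starts)) {
    stop("segment index ", segment_index, " out of range")
  }
  lo <- starts[segment_index]
  hi <- if (segment_index < length(starts)) starts[segment_index + 1] else Inf
  idx <- which(trace$time >= lo - 1e-9 & trace$time < hi - 1e-9)
  if (segment_index == length(starts)) {
    idx <- which(trace$time >= lo - 1e-9)
  }
  if (!length(idx)) stop("segment window is empty")
  idx
}

#' Peak tail-current measurement
#'
#' Finds the signed extremum of the current within a segment. Polarity
#' defaults to the sign of the driving force (V - EK) in that segment:
#' tails at voltages below EK are inward (negative) and their peak is the
#' minimum.
#'
#' @param trace A \code{current_trace}.
#' @param segment_index Segment to analyze (default: the protocol's
#'   measurement segment).
#' @param polarity +1 (outward peak), -1 (inward peak), or \code{NULL} to
#'   infer from the driving force.
#' @return List with \code{current} (signed), \code{magnitude}, and
#'   \code{time} (ms, relative to segment start).
#' @export
peak_tail <- function(trace, segment_index = attr(trace, "measurement_segment"),
                      polarity = NULL) {
  idx <- segment_window(trace, segment_index)
  if (is.null(polarity)) {
    V <- attr(trace, "segment_voltages")[segment_index]
    EK <- attr(trace, "EK")
    polarity <- if (!is.null(EK) && is.finite(EK) && V < EK) -1 else 1
  }
  y <- trace$current[idx]
  k <- if (polarity < 0) which.min(y) else which.max(y)
  list(current = y[k], magnitude = abs(y[k]),
       time = trace$time[idx[k]] - trace$time[idx[1]])
}

#' Normalized peak-tail activation curve from SSA sweeps
#'
#' Peak tail-current magnitudes per sweep, normalized to the maximum, as a
#' function of the test-step voltage. This is the curve fitted by
#' \code{\link{boltzmann_fit}}.
#'
#' @param traces List of traces from \code{\link{simulate_sweeps}} on an
#'   SSA-style protocol.
#' @return Data frame with columns \code{V} and \code{I_norm}.
#' @export
tail_activation_curve <- function(traces) {
  mags <- vapply(traces, function(tr) peak_tail(tr)$magnitude, 0)
  if (max(mags) <= 0) stop("tail_activation_curve: all peak tails are zero")
  data.frame(V = vapply(traces, function(tr) attr(tr, "sweep_value"), 0),
             I_norm = mags / max(mags))
}

#' Activation time course from envelope-of-tails sweeps
#'
#' Normalized peak tail amplitude as a function of the activating-step
#' duration. Invariant under uniform current scaling.
#'
#' @param traces List of traces from an envelope protocol.
#' @return Data frame with columns \code{duration} and \code{norm}
#'   (maximum = 1).
#' @export
activation_envelope_curve <- function(traces) {
  if (length(traces) < 1) stop("activation_envelope_curve: no sweeps")
  mags <- vapply(traces, function(tr) peak_tail(tr)$magnitude, 0)
  if (max(mags) <= 0) stop("activation_envelope_curve: all peak tails are zero")
  data.frame(duration = vapply(traces, function(tr) attr(tr, "sweep_value"), 0),
             norm = mags / max(mags))
}

#' Current-voltage relationship at the end of the test step
#'
#' The current at the final sample of the test (swept) segment per sweep.
#' For hERG this is bell-shaped: inward rectification suppresses the current
#' at strongly depolarized potentials.
#'
#' @param traces List of traces from an SSA-style protocol.
#' @return Data frame with columns \code{V} and \code{current}.
#' @export
iv_relationship <- function(traces) {
  vals <- vapply(traces, function(tr) {
    seg <- attr(tr, "protocol")
    idx <- segment_window(tr, 1L)
    tr$current[idx[length(idx)]]
  }, 0)
  data.frame(V = vapply(traces, function(tr) attr(tr, "sweep_value"), 0),
             current = vals)
}
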