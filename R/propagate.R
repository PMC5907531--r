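#' Stationary distribution of a generator matrix
#'
#' Solves \code{Q p = 0} with \code{sum(p) = 1} for an irreducible generator
#' (null-space computation via QR on the augmented system). Used to
#' initialize each sweep at the holding potential.
#'
#' @param Q Generator matrix with columns summing to zero.
#' @return Probability vector (named if Q has dimnames).
#' @export
steady_state <- function(Q) {
  n <- nrow(Q)
  A <- rbind(Q, rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(A, b)
  if (any(!is.finite(p))) stop("steady_state: solve failed (reducible or defective Q?)")
  if (any(p < -1e-9)) {
    stop("steady_state: negative occupancy (min ", format(min(p)),
         "); Q may be reducible")
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  resid <- max(abs(Q %*% p))
  if (resid > 1e-8) stop("steady_state: residual ||Q p|| = ", format(resid))
  stats::setNames(p, rownames(Q))
}

#' Propagate state probabilities over a constant-voltage segment
#'
#' For a time-homogeneous generator the master equation has the exact
#' solution \code{p(t) = expm(Q t) p0}; the segment is advanced by repeated
#' application of the one-step matrix \code{expm(Q * sample_dt)}, so the
#' returned samples are exact (to matrix-exponential accuracy) regardless of
#' the sampling interval.
#'
#' @param p0 Initial probability vector.
#' @param Q Generator matrix (ms^-1).
#' @param duration Segment duration (ms), >= 0.
#' @param sample_dt Sampling interval (ms), > 0.
#' @return Matrix with one column per sample time (including t = 0) and
#'   attribute \code{"time"} holding the sample times; a duration of zero
#'   returns the single column \code{p0}.
#' @export
propagate_segment <- function(p0, Q, duration, sample_dt = 0.1) {
  stopifnot(duration >= 0, sample_dt > 0)
  n <- nrow(Q)
  stopifnot(length(p0) == n)
  if (duration == 0) {
    out <- matrix(p0, ncol = 1, dimnames = list(rownames(Q), NULL))
    attr(out, "time") <- 0
    return(out)
  }
  nsteps <- max(1L, as.integer(round(duration / sample_dt)))
  dt <- duration / nsteps
  E <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
  out <- iterate_states(E, as.numeric(p0), nsteps)
  rownames(out) <- rownames(Q)
  attr(out, "time") <- seq(0, duration, length.out = nsteps + 1L)
  # conservation check: drift flags invalid generators early
  s <- colSums(out)
  if (max(abs(s - 1)) > 1e-9) {
    stop("propagate_segment: probability not conserved (max drift ",
         format(max(abs(s - 1))), ")")
  }
  out
}

#' Fine-step explicit-Euler reference integration
#'
#' Direct explicit-Euler integration of \code{dp/dt = Q p} at a small fixed
#' step, recording the state at the requested checkpoint times. This is the
#' brute-force reference used to validate the matrix-exponential path; it is
#' deliberately independent of \code{\link{propagate_segment}}.
#'
#' @param p0 Initial probability vector.
#' @param Q Generator matrix.
#' @param duration Segment duration (ms).
#' @param dt Euler step (ms), default 1e-4.
#' @param times Checkpoint times within \code{[0, duration]}.
#' @return Matrix with one column per checkpoint.
#' @export
euler_reference <- function(p0, Q, duration, dt = 1e-4,
                            times = duration) {
  out <- euler_states(Q, as.numeric(p0), duration, dt, as.numeric(times))
  rownames(out) <- rownames(Q)
  attr(out, "time") <- times
  out
}
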