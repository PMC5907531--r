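#' Boltzmann fit of a normalized activation curve
#'
#' Least-squares fit of \code{I/Imax = 1 / (1 + exp((V_half - V) / k))} to
#' normalized tail currents. The fitted curve equals 0.5 at \code{V_half}
#' by construction and the slope factor \code{k} is constrained positive.
#'
#' @param V Membrane potentials (mV), at least 4 points spanning the
#'   transition.
#' @param I_norm Normalized currents in [0, 1].
#' @return Object of class \code{"boltzmann_fit"} with \code{V_half},
#'   \code{slope}, \code{residual} (norm) and \code{fitted}.
#' @export
boltzmann_fit <- function(V, I_norm) {
  stopifnot(length(V) == length(I_norm), length(V) >= 4)
  # seed: interpolate the half-activation crossing, generic slope
  v50 <- tryCatch(stats::approx(I_norm, V, xout = 0.5, ties = "ordered")$y,
                  error = function(e) NA_real_)
  if (!is.finite(v50)) v50 <- V[which.min(abs(I_norm - 0.5))]
  dat <- data.frame(V = V, I = I_norm)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ 1 / (1 + exp((Vh - V) / k)), data = dat,
                      start = list(Vh = v50, k = 8),
                      lower = c(Vh = min(V) - 100, k = 1e-3),
                      upper = c(Vh = max(V) + 100, k = 200),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("boltzmann_fit: did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(V_half = unname(co["Vh"]), slope = unname(co["k"]),
                 residual = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit), V = V, I_norm = I_norm),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V_half = %.2f mV, slope k = %.2f mV (residual %.3g)\n",
              x$V_half, x$slope, x$residual))
  invisible(x)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$V, x$I_norm, xlab = "V (mV)", ylab = "I / Imax", ...)
  vv <- seq(min(x$V), max(x$V), length.out = 200)
  graphics::lines(vv, 1 / (1 + exp((x$V_half - vv) / x$slope)))
  invisible(x)
}

# mono- or bi-exponential model evaluated at time t (t relative to window start)
.exp_model <- function(t, A, tau, C) C + as.numeric(exp(-outer(t, 1 / tau)) %*% A)

# linear solve for amplitudes + offset given taus
.exp_amplitudes <- function(t, y, tau) {
  X <- cbind(exp(-outer(t, 1 / tau)), 1)
  qr.solve(X, y)
}

#' Exponential fit of a current time course
#'
#' Fits \code{y(t) = C + sum_i A_i * exp(-t / tau_i)} with one or two
#' components by nonlinear least squares. Time constants are constrained
#' positive and, for two components, returned ordered
#' \code{tau_fast < tau_slow}. Initial time constants come from a
#' log-linear probe of the tail; amplitudes are then solved linearly before
#' the full nonlinear refinement.
#'
#' @param time,current The window to fit; time is shifted to start at 0.
#' @param n_components 1 or 2.
#' @param offset Fit a constant offset (default TRUE).
#' @param amp_sign Optional sign constraint (+1/-1) on all amplitudes.
#'   Constraining amplitudes to the decay direction keeps small
#'   opposite-signed modes (e.g. a residual recovery hook) out of the fit.
#' @return Object of class \code{"exp_fit"} with \code{tau} (ascending),
#'   \code{amplitude}, \code{offset}, \code{residual}, \code{fitted}.
#' @export
exp_fit <- function(time, current, n_components = 2, offset = TRUE,
                    amp_sign = NULL) {
  stopifnot(n_components %in% c(1, 2), length(time) == length(current))
  if (length(time) < 4 + 2 * n_components) stop("exp_fit: window too short")
  t <- time - time[1]
  y <- current
  C0 <- if (offset) y[length(y)] else 0
  dy <- y - C0
  # log-linear probe on the dominant relaxation for a tau seed
  big <- which(abs(dy) > 0.05 * max(abs(dy)))
  big <- big[big <= max(2L, floor(0.8 * length(t)))]
  tau0 <- if (length(big) >= 3) {
    sl <- stats::coef(stats::lm(log(abs(dy[big])) ~ t[big]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  tau0 <- max(tau0, diff(range(t)) / 1e4)

  nc <- n_components
  model_val <- function(par) {
    tau <- par[(nc + 1):(2 * nc)]
    C <- if (offset) par[2 * nc + 1] else 0
    C + as.numeric(exp(-outer(t, 1 / tau)) %*% par[1:nc])
  }
  # Levenberg-Marquardt on the raw residuals: damping survives the
  # degenerate tau_fast -> tau_slow limit that model-frame fitters reject
  try_fit <- function(tau_seed) {
    A0 <- tryCatch(.exp_amplitudes(t, y, tau_seed), error = function(e) NULL)
    if (is.null(A0)) return(NULL)
    amps <- A0[seq_along(tau_seed)]
    if (!is.null(amp_sign)) amps <- amp_sign * abs(amps)
    par <- c(amps, tau_seed, if (offset) unname(A0[length(A0)]))
    lower <- rep(-Inf, length(par))
    upper <- rep(Inf, length(par))
    lower[(nc + 1):(2 * nc)] <- diff(range(t)) * 1e-6
    if (!is.null(amp_sign)) {
      if (amp_sign > 0) lower[1:nc] <- 0 else upper[1:nc] <- 0
    }
    out <- tryCatch(
      minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                         fn = function(p) model_val(p) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out$par))) return(NULL)
    out
  }
  seeds <- if (nc == 1) {
    list(tau0, tau0 / 5, tau0 * 5)
  } else {
    list(c(tau0 / 4, tau0 * 2), c(tau0 / 10, tau0), c(tau0 / 2, tau0 * 8))
  }
  fits <- Filter(Negate(is.null), lapply(seeds, try_fit))
  if (!length(fits)) stop("exp_fit: no seed converged (degenerate window?)")
  rss <- vapply(fits, function(f) sum(f$fvec^2), 0)
  fit <- fits[[which.min(rss)]]
  taus <- fit$par[(nc + 1):(2 * nc)]
  amps <- fit$par[1:nc]
  ord <- order(taus)
  structure(list(tau = taus[ord], amplitude = amps[ord],
                 offset = if (offset) fit$par[2 * nc + 1] else 0,
                 n_components = nc,
                 residual = sqrt(min(rss)),
                 fitted = model_val(fit$par), time = time, current = current),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential fit (%d component%s): tau = %s ms, amplitude = %s, offset = %.4g\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              paste(signif(x$tau, 4), collapse = ", "),
              paste(signif(x$amplitude, 4), collapse = ", "), x$offset))
  invisible(x)
}

#' Deactivation time constants from a simulated trace
#'
#' Double-exponential fit of the deactivating tail in the measurement
#' segment, starting at the segment's peak current (so the residual
#' recovery hook is excluded from the window).
#'
#' @param trace A deactivation-protocol trace.
#' @param n_components Number of exponential components (default 2).
#' @return An \code{\link{exp_fit}} (tau ascending: fast, slow).
#' @export
fit_deactivation <- function(trace, n_components = 2) {
  idx <- segment_window(trace, attr(trace, "measurement_segment"))
  pk <- which.max(abs(trace$current[idx]))
  idx <- idx[pk:length(idx)]
  y <- trace$current[idx]
  sgn <- sign(y[1] - y[length(y)])
  exp_fit(trace$time[idx], y, n_components = n_components,
          amp_sign = if (sgn == 0) NULL else sgn)
}

#' Recovery-from-inactivation time constant
#'
#' Single-exponential fit of the rising ("hooked") phase of the test-segment
#' current, from segment onset to the peak.
#'
#' @param trace A recovery-protocol trace.
#' @return Time constant tau (ms).
#' @export
fit_recovery_tau <- function(trace) {
  idx <- segment_window(trace, attr(trace, "measurement_segment"))
  pk <- which.max(abs(trace$current[idx]))
  if (pk < 6) stop("fit_recovery_tau: rising phase too short to fit")
  win <- idx[1:pk]
  f <- exp_fit(trace$time[win], trace$current[win], n_components = 1)
  f$tau[1]
}
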