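# Physical constants (SI). The Faraday constant is the CODATA value.
.kB <- 1.381e-23   # J/K
.h  <- 6.626e-34   # J s
.Rgas <- 8.315     # J/mol/K
.Faraday <- 96485  # C/mol

#' Voltage-dependent transition rate law
#'
#' A single gating transition's rate is \code{k(V) = a * alpha * exp(b * beta * V)}
#' with \code{alpha} in ms^-1 and \code{beta} in mV^-1. The dimensionless
#' factors \code{corr_a} and \code{corr_b} are the multiplicative corrections
#' that the global-fitting procedure optimizes; at \code{corr_a = corr_b = 1}
#' the law reduces to the base Eyring form. Alternatively \code{alpha} and
#' \code{beta} can be derived from a thermodynamic parameterization
#' (activation enthalpy/entropy and effective valence) at temperature
#' \code{temperature}.
#'
#' @param alpha Rate prefactor (ms^-1); must be positive.
#' @param beta Voltage coefficient (mV^-1). Zero for voltage-independent
#'   transitions.
#' @param corr_a,corr_b Dimensionless multiplicative corrections to
#'   \code{alpha} and \code{beta}; \code{corr_a} must be positive.
#' @param thermo Optional list with elements \code{dH} (J/mol), \code{dS}
#'   (J/mol/K) and \code{z} (effective valence). When supplied, \code{alpha}
#'   and \code{beta} are computed as \code{(kB*T/h) * exp(dS/R - dH/(R*T))}
#'   and \code{z*F/(R*T)} (the latter converted to mV^-1), and any values
#'   passed in \code{alpha}/\code{beta} are ignored.
#' @param temperature Temperature (K) at which \code{thermo} is evaluated.
#' @return An object of class \code{"rate_law"}.
#' @export
rate_law <- function(alpha = NULL, beta = 0, corr_a = 1, corr_b = 1,
                     thermo = NULL, temperature = 296.15) {
  if (!is.null(thermo)) {
    stopifnot(is.list(thermo), all(c("dH", "dS", "z") %in% names(thermo)))
    # kB*T/h has units s^-1; convert to ms^-1
    alpha <- (.kB * temperature / .h) *
      exp(thermo$dS / .Rgas - thermo$dH / (.Rgas * temperature)) / 1000
    # z*F/(R*T) is V^-1; convert to mV^-1
    beta <- thermo$z * .Faraday / (.Rgas * temperature) / 1000
  }
  if (is.null(alpha)) stop("rate_law: 'alpha' is required when 'thermo' is not given")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0) stop("rate_law: 'alpha' must be > 0")
  if (corr_a <= 0) stop("rate_law: 'corr_a' must be > 0")
  structure(list(alpha = alpha, beta = beta, corr_a = corr_a,
                 corr_b = corr_b, thermo = thermo,
                 temperature = temperature),
            class = "rate_law")
}

#' Evaluate a transition rate at a membrane potential
#'
#' Computes \code{corr_a * alpha * exp(corr_b * beta * V)}. For large
#' exponents the computation is guarded in log space and a non-finite result
#' (overflow at extreme voltages) is an error rather than an \code{Inf}.
#'
#' @param law A \code{\link{rate_law}}, or a list/row with fields
#'   \code{alpha}, \code{beta}, \code{corr_a}, \code{corr_b}.
#' @param V Membrane potential (mV); may be a vector.
#' @return Rate(s) in ms^-1, strictly positive.
#' @export
evaluate_rate <- function(law, V) {
  stopifnot(all(is.finite(V)))
  ca <- if (is.null(law$corr_a)) 1 else law$corr_a
  cb <- if (is.null(law$corr_b)) 1 else law$corr_b
  expo <- cb * law$beta * V
  # log-space guard for extreme exponents
  lk <- log(ca * law$alpha) + expo
  if (any(lk > 700)) {
    stop("evaluate_rate: rate overflows at V = ",
         paste(V[lk > 700], collapse = ", "), " mV (invalid parameters)")
  }
  k <- exp(lk)
  if (any(!is.finite(k) | k <= 0)) {
    stop("evaluate_rate: non-finite or non-positive rate (invalid parameters)")
  }
  k
}

#' Potassium reversal potential by the Nernst equation
#'
#' @param Ki Internal (pipette) potassium concentration (mM).
#' @param Ko External (bath) potassium concentration (mM).
#' @param T Temperature (K).
#' @return Reversal potential EK in mV.
#' @export
nernst_potential <- function(Ki, Ko, T = 296.15) {
  if (Ki <= 0 || Ko <= 0) stop("nernst_potential: concentrations must be > 0")
  1000 * .Rgas * T / .Faraday * log(Ko / Ki)
}

#' Current-scaling parameters for the IKr ohmic current
#'
#' Bundles the maximal-conductance scaling \code{gKr = gKr0 * (a*T + b) *
#' sqrt(Ko/5.4)} with the potassium concentrations and reversal potential.
#' With the default coefficients \code{a = 1/35}, \code{b = -55/7} the
#' temperature factor is exactly 1 at T = 310 K. \code{EK} defaults to the
#' Nernst potential from \code{Ki}/\code{Ko} at \code{T}.
#'
#' @param gKr0 Baseline conductance (pA/pF/mV).
#' @param a,b Linear temperature-factor coefficients (K^-1, dimensionless).
#' @param Ko,Ki External/internal potassium (mM).
#' @param T Temperature (K).
#' @param EK Reversal potential (mV); computed by Nernst when \code{NULL}.
#' @return An object of class \code{"current_params"}.
#' @export
current_params <- function(gKr0 = 0.024, a = 1 / 35, b = -55 / 7,
                           Ko = 5.4, Ki = 120, T = 296.15, EK = NULL) {
  stopifnot(gKr0 > 0, Ko > 0, Ki > 0, T > 0)
  if (a * T + b <= 0) {
    stop("current_params: temperature factor a*T + b must be > 0 (T outside model validity)")
  }
  if (is.null(EK)) EK <- nernst_potential(Ki, Ko, T)
  structure(list(gKr0 = gKr0, a = a, b = b, Ko = Ko, Ki = Ki, T = T, EK = EK),
            class = "current_params")
}

#' Temperature- and potassium-scaled maximal IKr conductance
#'
#' \code{gKr = gKr0 * (a*T + b) * sqrt(Ko / 5.4)}.
#'
#' @param cp A \code{\link{current_params}} object.
#' @return Conductance in pA/pF/mV.
#' @export
conductance <- function(cp) {
  fT <- cp$a * cp$T + cp$b
  if (fT <= 0) stop("conductance: a*T + b <= 0 (temperature outside model validity)")
  cp$gKr0 * fT * sqrt(cp$Ko / 5.4)
}

#' Ohmic IKr current density
#'
#' \code{IKr = gKr * pO * (V - EK)}: linear in the open probability and zero
#' at the reversal potential.
#'
#' @param pO Open-state probability in \code{[0, 1]} (vectorized).
#' @param V Membrane potential (mV).
#' @param cp A \code{\link{current_params}} object.
#' @return Current density in pA/pF.
#' @export
ikr_current <- function(pO, V, cp) {
  stopifnot(all(pO >= -1e-12), all(pO <= 1 + 1e-12))
  conductance(cp) * pO * (V - cp$EK)
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("rate law: k(V) = %.4g * %.4g * exp(%.4g * %.4g * V) ms^-1\n",
              x$corr_a, x$alpha, x$corr_b, x$beta))
  invisible(x)
}

#' @export
print.current_params <- function(x, ...) {
  cat(sprintf(
    "IKr current params: gKr0 = %.4g pA/pF/mV, T = %.2f K, Ko = %.2f mM, Ki = %.1f mM, EK = %.2f mV\n  gKr = %.5g pA/pF/mV\n",
    x$gKr0, x$T, x$Ko, x$Ki, x$EK, conductance(x)))
  invisible(x)
}
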