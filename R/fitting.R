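# --- global fitting of rate-correction factors -----------------------------
#
# The quantities optimized are the dimensionless corrections (a_i on alpha,
# b_i on beta) of selected transitions; the base alphas/betas stay fixed.
# Each dataset is a derived observable (normalized activation curve,
# envelope curve, deactivation time course, recovery tau) with a weight; the
# total cost is the weighted sum of squared residuals over all datasets.

#' Apply correction factors to a parameter set
#'
#' Sets the \code{corr_a}/\code{corr_b} columns of selected transitions.
#' Corrections are named \code{"<transition>.<a|b>"}, e.g.
#' \code{list("aa.a" = 0.5, "bb.b" = 1.2)}.
#'
#' @param params A \code{\link{herg_params}} set.
#' @param corrections Named list or vector of correction values.
#' @return The modified parameter set (constraints are not re-resolved;
#'   call \code{\link{constrain_reversibility}} afterwards if the scheme
#'   has loops).
#' @export
apply_corrections <- function(params, corrections) {
  for (nm in names(corrections)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- match(parts[1], params$transition)
    if (is.na(i)) stop("apply_corrections: unknown transition '", parts[1], "'")
    col <- if (parts[2] == "a") "corr_a" else "corr_b"
    params[[col]][i] <- corrections[[nm]]
  }
  params
}

# per-kind sampling interval: the recovery hook peaks within a few ms and
# needs finer sampling than the slower observables
.kind_dt <- function(kind, sample_dt) {
  if (kind == "recovery") min(sample_dt, 0.1) else sample_dt
}

# simulate one dataset's observable; returns a numeric vector aligned with
# the rows of dataset$target
simulate_observable <- function(scheme, params, dataset, cp, sample_dt = 1) {
  kind <- dataset$kind
  traces <- simulate_sweeps(scheme, params, dataset$protocol, cp,
                            sample_dt = .kind_dt(kind, sample_dt))
  switch(kind,
    ssa = {
      curve <- tail_activation_curve(traces)
      curve$I_norm[match(dataset$target$V, curve$V)]
    },
    envelope = {
      curve <- activation_envelope_curve(traces)
      curve$norm[match(dataset$target$duration, curve$duration)]
    },
    deactivation = {
      out <- numeric(nrow(dataset$target))
      for (tr in traces) {
        sv <- attr(tr, "sweep_value")
        rows <- which(dataset$target$sweep == sv)
        if (!length(rows)) next
        idx <- segment_window(tr, attr(tr, "measurement_segment"))
        t0 <- tr$time[idx[1]]
        y <- tr$current[idx]
        y <- y / max(abs(y))                 # per-trace peak normalization
        out[rows] <- stats::approx(tr$time[idx] - t0, y,
                                   xout = dataset$target$time[rows],
                                   rule = 2)$y
      }
      out
    },
    recovery = {
      taus <- vapply(traces, fit_recovery_tau, 0)
      taus[match(dataset$target$V,
                 vapply(traces, function(tr) attr(tr, "sweep_value"), 0))]
    },
    stop("unknown dataset kind '", kind, "'")
  )
}

dataset_target_values <- function(dataset) {
  switch(dataset$kind,
    ssa = dataset$target$I_norm,
    envelope = dataset$target$norm,
    deactivation = dataset$target$norm,
    recovery = dataset$target$tau,
    stop("unknown dataset kind '", dataset$kind, "'"))
}

#' Multi-protocol fitting problem for rate-correction factors
#'
#' Bundles a gating scheme, a base parameter set (fixed alphas/betas), the
#' target datasets with weights, and the free correction factors with their
#' bounds. Corrections on the prefactor (\code{corr_a}) are optimized in
#' log space; corrections on the voltage coefficient (\code{corr_b}) in
#' linear space.
#'
#' @param scheme A \code{\link{markov_scheme}} or name.
#' @param base_params A \code{\link{herg_params}} set (the initial-guess
#'   alphas/betas).
#' @param datasets List of datasets, each a list with \code{kind}
#'   (\code{"ssa"}, \code{"envelope"}, \code{"deactivation"},
#'   \code{"recovery"}), \code{protocol} (a
#'   \code{\link{voltage_protocol}}) and \code{target} (data frame; see
#'   \code{\link{generate_synthetic_dataset}} for the layouts).
#' @param free Data frame with columns \code{transition} and \code{factor}
#'   (\code{"a"} or \code{"b"}) naming the free corrections.
#' @param weights Positive per-dataset weights (default all 1).
#' @param bounds_a,bounds_b Bounds on corr_a and corr_b; both must contain
#'   1 (the identity correction).
#' @param cp A \code{\link{current_params}} object.
#' @param sample_dt Simulation sampling interval (ms) used during fitting.
#' @return Object of class \code{"fit_problem"}.
#' @export
fit_problem <- function(scheme, base_params, datasets, free,
                        weights = NULL, bounds_a = c(0.01, 100),
                        bounds_b = c(0.2, 5), cp = current_params(),
                        sample_dt = 1) {
  if (is.character(scheme)) scheme <- markov_scheme(scheme)
  if (!length(datasets)) stop("fit_problem: at least one dataset is required")
  if (is.null(weights)) weights <- rep(1, length(datasets))
  if (length(weights) != length(datasets) || any(weights <= 0)) {
    stop("fit_problem: weights must be positive, one per dataset")
  }
  stopifnot(is.data.frame(free), all(c("transition", "factor") %in% names(free)),
            all(free$factor %in% c("a", "b")))
  if (bounds_a[1] > 1 || bounds_a[2] < 1 || bounds_b[1] > 1 || bounds_b[2] < 1) {
    stop("fit_problem: bounds must contain 1 (the identity correction)")
  }
  bad <- setdiff(free$transition, base_params$transition)
  if (length(bad)) stop("fit_problem: unknown free transition(s): ",
                        paste(bad, collapse = ", "))
  structure(list(scheme = scheme, base_params = base_params,
                 datasets = datasets, free = free, weights = weights,
                 bounds_a = bounds_a, bounds_b = bounds_b, cp = cp,
                 sample_dt = sample_dt),
            class = "fit_problem")
}

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf("fit problem: scheme %s, %d dataset(s) [%s], %d free correction(s)\n",
              x$scheme$name, length(x$datasets),
              paste(vapply(x$datasets, `[[`, "", "kind"), collapse = ", "),
              nrow(x$free)))
  invisible(x)
}

.free_names <- function(problem) {
  paste0(problem$free$transition, ".", problem$free$factor)
}

# theta (optimizer space) <-> corrections (natural space)
.theta_to_corr <- function(problem, theta) {
  corr <- ifelse(problem$free$factor == "a", exp(theta), theta)
  stats::setNames(as.list(corr), .free_names(problem))
}
.theta_bounds <- function(problem) {
  lo <- ifelse(problem$free$factor == "a", log(problem$bounds_a[1]),
               problem$bounds_b[1])
  hi <- ifelse(problem$free$factor == "a", log(problem$bounds_a[2]),
               problem$bounds_b[2])
  list(lower = lo, upper = hi)
}

# weighted residual vector at a correction setting; simulation failures
# yield a large finite penalty residual (logged), not an exception
.residual_vector <- function(corrections, problem, penalty = 1e3) {
  params <- apply_corrections(problem$base_params, corrections)
  params <- constrain_reversibility(problem$scheme, params)
  unlist(lapply(seq_along(problem$datasets), function(d) {
    ds <- problem$datasets[[d]]
    target <- dataset_target_values(ds)
    sim <- tryCatch(
      simulate_observable(problem$scheme, params, ds, problem$cp,
                          problem$sample_dt),
      error = function(e) {
        message("simulation failed (penalized): ", conditionMessage(e))
        NULL
      })
    if (is.null(sim) || length(sim) != length(target) || any(!is.finite(sim))) {
      return(rep(penalty * sqrt(problem$weights[d]), length(target)))
    }
    sqrt(problem$weights[d]) * (sim - target)
  }))
}

#' Weighted sum-of-squares cost of a correction setting
#'
#' \code{sum_d w_d * sum_i (sim_i - target_i)^2} over all datasets.
#' Simulation failure at the proposed corrections contributes a large
#' finite penalty rather than raising an error.
#'
#' @param corrections Named list/vector of corrections
#'   (\code{"<transition>.<a|b>"}).
#' @param problem A \code{\link{fit_problem}}.
#' @return Non-negative scalar.
#' @export
residual_cost <- function(corrections, problem) {
  sum(.residual_vector(corrections, problem)^2)
}

#' Multi-start global fit of correction factors
#'
#' Runs a bounded local least-squares minimization from \code{n_starts}
#' initial points: the identity correction plus seeded log-uniform (for
#' \code{corr_a}) and uniform (for \code{corr_b}) perturbations within the
#' bounds. The best-cost run is returned. Reruns with the same seed and
#' problem are bit-identical; the caller's RNG state is untouched.
#'
#' The default local method is bounded PORT quasi-Newton
#' (\code{\link[stats]{nlminb}}) on the weighted sum of squares.
#' Levenberg-Marquardt on the stacked residuals
#' (\code{minpack.lm::nls.lm}) is available via \code{method} for problems
#' whose observables do not themselves run a Levenberg-Marquardt fit (the
#' recovery-tau extraction does; the minpack backend cannot be nested).
#'
#' @param problem A \code{\link{fit_problem}}.
#' @param n_starts Number of starts (>= 1); the first is the identity.
#' @param seed Integer seed for the start generator.
#' @param start_spread Log-range (base 10) of the corr_a perturbations and
#'   half-range of the corr_b perturbations, intersected with the bounds.
#' @param method \code{"nlminb"} (default) or \code{"nls.lm"}.
#' @param control Control list for the chosen method.
#' @return Object of class \code{"herg_fit"}.
#' @export
global_fit <- function(problem, n_starts = 10, seed = 1,
                       start_spread = c(1, 0.5),
                       method = c("nlminb", "nls.lm"),
                       control = list()) {
  stopifnot(inherits(problem, "fit_problem"), n_starts >= 1)
  method <- match.arg(method)
  nb <- .theta_bounds(problem)
  npar <- nrow(problem$free)
  theta_id <- ifelse(problem$free$factor == "a", 0, 1)

  # seeded start matrix without disturbing the global RNG
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  starts <- matrix(theta_id, nrow = n_starts, ncol = npar, byrow = TRUE)
  if (n_starts > 1) {
    for (s in 2:n_starts) {
      for (j in seq_len(npar)) {
        if (problem$free$factor[j] == "a") {
          lo <- max(nb$lower[j], -start_spread[1] * log(10))
          hi <- min(nb$upper[j], start_spread[1] * log(10))
        } else {
          lo <- max(nb$lower[j], 1 - start_spread[2])
          hi <- min(nb$upper[j], 1 + start_spread[2])
        }
        starts[s, j] <- stats::runif(1, lo, hi)
      }
    }
  }
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }

  fn_resid <- function(theta) .residual_vector(.theta_to_corr(problem, theta), problem)
  fn_cost <- function(theta) sum(fn_resid(theta)^2)
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    runs[[s]] <- tryCatch(
      if (method == "nls.lm") {
        r <- minpack.lm::nls.lm(par = starts[s, ], lower = nb$lower,
                                upper = nb$upper, fn = fn_resid,
                                control = do.call(minpack.lm::nls.lm.control, control))
        list(par = r$par, cost = sum(r$fvec^2), info = r$info,
             message = r$message, niter = r$niter)
      } else {
        r <- stats::nlminb(start = starts[s, ], objective = fn_cost,
                           lower = nb$lower, upper = nb$upper,
                           control = control)
        list(par = r$par, cost = r$objective, info = r$convergence,
             message = r$message, niter = r$iterations)
      },
      error = function(e) e)
  }
  ok <- vapply(runs, function(r) !inherits(r, "error"), TRUE)
  if (!any(ok)) {
    stop("global_fit: all starts failed: ",
         paste(vapply(runs, conditionMessage, ""), collapse = "; "))
  }
  costs <- rep(Inf, n_starts)
  costs[ok] <- vapply(runs[ok], function(r) r$cost, 0)
  best <- which.min(costs)
  fit <- runs[[best]]
  corrections <- .theta_to_corr(problem, fit$par)
  eff <- constrain_reversibility(
    problem$scheme, apply_corrections(problem$base_params, corrections))
  per_ds <- {
    rv <- .residual_vector(corrections, problem)
    lens <- vapply(problem$datasets, function(d) length(dataset_target_values(d)), 0L)
    split(rv, rep(seq_along(lens), lens))
  }
  structure(list(
    corrections = stats::setNames(unlist(corrections), .free_names(problem)),
    params = eff,
    cost = costs[best],
    per_dataset_rss = vapply(per_ds, function(r) sum(r^2), 0),
    residuals = per_ds,
    best_start = best,
    start_costs = costs,
    starts = starts,
    convergence = list(info = fit$info, message = fit$message,
                       niter = fit$niter, method = method),
    n_starts = n_starts, seed = seed,
    problem = problem),
    class = "herg_fit")
}

#' @export
print.herg_fit <- function(x, ...) {
  cat(sprintf("hERG correction-factor fit: %d start(s), best start %d, cost %.6g\n",
              x$n_starts, x$best_start, x$cost))
  print(round(x$corrections, 5))
  invisible(x)
}

#' @export
summary.herg_fit <- function(object, ...) {
  cat(sprintf("Global fit of %d correction factor(s), scheme %s\n",
              length(object$corrections), object$problem$scheme$name))
  cat(sprintf("  seed %d, %d starts; best cost %.6g at start %d (%s)\n",
              object$seed, object$n_starts, object$cost, object$best_start,
              object$convergence$message))
  cat("  corrections:\n")
  print(round(object$corrections, 5))
  cat("  per-dataset weighted RSS:\n")
  kinds <- vapply(object$problem$datasets, `[[`, "", "kind")
  print(stats::setNames(signif(object$per_dataset_rss, 4), kinds))
  invisible(object)
}

#' @export
coef.herg_fit <- function(object, ...) object$corrections

#' @export
residuals.herg_fit <- function(object, ...) object$residuals

#' @export
predict.herg_fit <- function(object, ...) {
  lapply(object$problem$datasets, function(ds) {
    simulate_observable(object$problem$scheme, object$params, ds,
                        object$problem$cp, object$problem$sample_dt)
  })
}

#' Post-fit identifiability check
#'
#' Perturbs each fitted correction by \code{+/- epsilon} (relative) and
#' reports the cost change and a finite-difference curvature. Parameters
#' whose perturbation changes the cost by less than \code{floor} in both
#' directions are flagged as unidentifiable at this optimum.
#'
#' @param result A \code{\link{global_fit}} result.
#' @param problem The \code{\link{fit_problem}} it came from.
#' @param epsilon Relative perturbation (default 0.05).
#' @param floor Minimum cost change considered identifying (default 1e-6).
#' @return Data frame with one row per parameter: cost changes up/down,
#'   curvature, and the \code{unidentifiable} flag.
#' @export
stability_check <- function(result, problem = result$problem,
                            epsilon = 0.05, floor = 1e-6) {
  c0 <- residual_cost(as.list(result$corrections), problem)
  nm <- names(result$corrections)
  out <- data.frame(parameter = nm, value = unname(result$corrections),
                    dcost_up = NA_real_, dcost_down = NA_real_,
                    curvature = NA_real_, unidentifiable = NA)
  for (i in seq_along(nm)) {
    up <- as.list(result$corrections); dn <- as.list(result$corrections)
    up[[i]] <- up[[i]] * (1 + epsilon)
    dn[[i]] <- dn[[i]] * (1 - epsilon)
    cu <- residual_cost(up, problem); cd <- residual_cost(dn, problem)
    out$dcost_up[i] <- cu - c0
    out$dcost_down[i] <- cd - c0
    out$curvature[i] <- (cu + cd - 2 * c0) / epsilon^2
    out$unidentifiable[i] <- abs(cu - c0) < floor && abs(cd - c0) < floor
  }
  attr(out, "cost0") <- c0
  out
}
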