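#' Markov gating scheme for hERG1 channels
#'
#' Constructs one of the two shipped 5-state gating topologies. States are
#' ordered \code{C3, C2, C1, O, I}. M-model 1 is the linear chain
#' \code{C3 <-> C2 <-> C1 <-> O <-> I} (8 directed transitions). M-model 2
#' adds a direct closed-to-inactivated edge \code{C1 <-> I}, closing the
#' 3-cycle \code{C1, O, I}; the reverse edge \code{I -> C1} is constrained
#' by microscopic reversibility (see \code{\link{constrain_reversibility}}).
#'
#' Transition labels follow the field's convention: \code{ae}/\code{be}
#' early activation/deactivation (C3<->C2), \code{ain}/\code{bin} the
#' voltage-independent intermediate step (C2<->C1), \code{aa}/\code{bb} late
#' activation/deactivation (C1<->O), \code{bi}/\code{ai}
#' inactivation/recovery (O<->I). The extra M-model 2 edge C1->I is labeled
#' \code{bi2} and its constrained reverse I->C1 \code{ai2}.
#'
#' @param name \code{"mmodel1"} or \code{"mmodel2"}.
#' @return An object of class \code{"markov_scheme"} with elements
#'   \code{states}, \code{open_state}, \code{transitions} (data frame with
#'   \code{label}, \code{from}, \code{to}, \code{voltage_dependent},
#'   \code{constrained}) and \code{loops}.
#' @export
markov_scheme <- function(name = c("mmodel1", "mmodel2")) {
  name <- match.arg(name)
  tr <- data.frame(
    label = c("ae", "be", "ain", "bin", "aa", "bb", "bi", "ai"),
    from  = c("C3", "C2", "C2", "C1", "C1", "O", "O", "I"),
    to    = c("C2", "C3", "C1", "C2", "O", "C1", "I", "O"),
    voltage_dependent = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    constrained = FALSE,
    stringsAsFactors = FALSE
  )
  loops <- list()
  if (name == "mmodel2") {
    tr <- rbind(tr, data.frame(
      label = c("bi2", "ai2"),
      from  = c("C1", "I"),
      to    = c("I", "C1"),
      voltage_dependent = TRUE,
      constrained = c(FALSE, TRUE),
      stringsAsFactors = FALSE
    ))
    loops <- list(c("C1", "O", "I"))
  }
  structure(list(name = name,
                 states = c("C3", "C2", "C1", "O", "I"),
                 open_state = "O",
                 inactivated_state = "I",
                 transitions = tr,
                 loops = loops),
            class = "markov_scheme")
}

#' @export
print.markov_scheme <- function(x, ...) {
  cat(sprintf("Markov gating scheme '%s': states %s (open: %s)\n",
              x$name, paste(x$states, collapse = " "), x$open_state))
  cat(sprintf("  %d directed transitions", nrow(x$transitions)))
  if (length(x$loops)) {
    cat(sprintf("; loop(s): %s",
                paste(vapply(x$loops, paste, "", collapse = "-"), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Per-transition rate parameters for a scheme and isoform
#'
#' A parameter set holds one row per directed transition with \code{alpha}
#' (ms^-1), \code{beta} (mV^-1) and correction factors \code{corr_a},
#' \code{corr_b} (both default 1). Constrained transitions (M-model 2's
#' I->C1) may be absent on construction and are filled in by
#' \code{\link{constrain_reversibility}}.
#'
#' @param scheme A \code{\link{markov_scheme}} or scheme name.
#' @param values Data frame with columns \code{transition}, \code{alpha},
#'   \code{beta} and optionally \code{corr_a}, \code{corr_b}.
#' @param isoform \code{"hERG1a"} or \code{"hERG1b"} (free-form allowed for
#'   synthetic sets).
#' @param temperature Temperature of validity (K).
#' @param resolve Resolve constrained transitions by loop closure (default
#'   TRUE for schemes with loops).
#' @return An object of class \code{"herg_params"}: a data frame of rate
#'   laws with attributes \code{scheme}, \code{isoform}, \code{temperature}.
#' @export
herg_params <- function(scheme, values, isoform = "synthetic",
                        temperature = 296.15, resolve = TRUE) {
  if (is.character(scheme)) scheme <- markov_scheme(scheme)
  stopifnot(inherits(scheme, "markov_scheme"))
  req <- c("transition", "alpha", "beta")
  if (!all(req %in% names(values))) {
    stop("herg_params: 'values' needs columns ", paste(req, collapse = ", "))
  }
  if (is.null(values$corr_a)) values$corr_a <- 1
  if (is.null(values$corr_b)) values$corr_b <- 1
  tr <- scheme$transitions
  free <- tr$label[!tr$constrained]
  missing_free <- setdiff(free, values$transition)
  if (length(missing_free)) {
    stop("herg_params: missing parameter(s) for transition(s): ",
         paste(missing_free, collapse = ", "))
  }
  unknown <- setdiff(values$transition, tr$label)
  if (length(unknown)) {
    stop("herg_params: unknown transition(s) for scheme '", scheme$name,
         "': ", paste(unknown, collapse = ", "))
  }
  bad <- values$transition[values$alpha <= 0 | !is.finite(values$alpha)]
  if (length(bad)) {
    stop("herg_params: non-positive alpha for transition(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(values$corr_a <= 0)) stop("herg_params: corr_a must be > 0")
  # voltage-independent transitions must have beta = 0
  vi <- tr$label[!tr$voltage_dependent]
  off <- intersect(vi, values$transition[values$beta != 0])
  if (length(off)) {
    stop("herg_params: transitions ", paste(off, collapse = ", "),
         " are voltage-independent; beta must be 0")
  }
  p <- values[match(tr$label, values$transition), , drop = FALSE]
  p$transition <- tr$label
  rownames(p) <- tr$label
  p <- p[, c("transition", "alpha", "beta", "corr_a", "corr_b")]
  out <- structure(p, class = c("herg_params", "data.frame"),
                   scheme = scheme$name, isoform = isoform,
                   temperature = temperature)
  if (resolve && length(scheme$loops)) out <- constrain_reversibility(scheme, out)
  out
}

#' @export
print.herg_params <- function(x, ...) {
  cat(sprintf("hERG rate parameters: scheme %s, isoform %s, T = %.2f K\n",
              attr(x, "scheme"), attr(x, "isoform"), attr(x, "temperature")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

# effective rate for one labeled transition at voltage V
.transition_rate <- function(params, label, V) {
  row <- params[params$transition == label, ]
  if (nrow(row) != 1L || is.na(row$alpha)) {
    stop("missing rate parameters for transition '", label, "'")
  }
  evaluate_rate(list(alpha = row$alpha, beta = row$beta,
                     corr_a = row$corr_a, corr_b = row$corr_b), V)
}

#' Resolve microscopic-reversibility constraints
#'
#' For every loop of the scheme, the product of rates traversed clockwise
#' must equal the product traversed counterclockwise at every voltage. With
#' rates of the form \code{alpha * exp(beta * V)} this closure must hold for
#' the \code{alpha} products and the signed \code{beta} sums jointly. The
#' single constrained edge on each loop (I->C1 in M-model 2) is derived from
#' the others; schemes without loops are returned unchanged.
#'
#' @param scheme A \code{\link{markov_scheme}}.
#' @param params A \code{\link{herg_params}} set in which all loop rates but
#'   the constrained edge are present (effective values, corrections folded
#'   in, are used; the derived edge is stored with unit corrections).
#' @return The parameter set with constrained transitions filled in.
#' @export
constrain_reversibility <- function(scheme, params) {
  if (is.character(scheme)) scheme <- markov_scheme(scheme)
  if (!length(scheme$loops)) return(params)
  tr <- scheme$transitions
  for (loop in scheme$loops) {
    n <- length(loop)
    # directed edges around the loop, forward (clockwise) and reverse
    fwd <- data.frame(from = loop, to = loop[c(2:n, 1)])
    rev <- data.frame(from = loop[c(2:n, 1)], to = loop)
    lab_of <- function(e) {
      i <- which(tr$from == e$from & tr$to == e$to)
      if (length(i) != 1L) stop("constrain_reversibility: loop edge ",
                                e$from, "->", e$to, " not in scheme")
      tr$label[i]
    }
    labs_f <- vapply(seq_len(n), function(i) lab_of(fwd[i, ]), "")
    labs_r <- vapply(seq_len(n), function(i) lab_of(rev[i, ]), "")
    con_f <- tr$constrained[match(labs_f, tr$label)]
    con_r <- tr$constrained[match(labs_r, tr$label)]
    ncon <- sum(con_f) + sum(con_r)
    if (ncon != 1L) {
      stop("constrain_reversibility: loop ", paste(loop, collapse = "-"),
           " has ", ncon, " constrained edges; exactly one is required ",
           "(underdetermined or overdetermined loop)")
    }
    # effective alpha and beta (corrections folded in) for each edge
    eff <- function(lab) {
      row <- params[params$transition == lab, ]
      if (is.na(row$alpha)) stop("constrain_reversibility: free edge '", lab,
                                 "' has no parameters")
      c(a = row$corr_a * row$alpha, b = row$corr_b * row$beta)
    }
    solve_edge <- function(lab_this, labs_same, labs_opp) {
      other_same <- setdiff(labs_same, lab_this)
      va <- vapply(other_same, function(l) eff(l)["a"], 0)
      vb <- vapply(other_same, function(l) eff(l)["b"], 0)
      oa <- vapply(labs_opp, function(l) eff(l)["a"], 0)
      ob <- vapply(labs_opp, function(l) eff(l)["b"], 0)
      list(alpha = prod(oa) / prod(va), beta = sum(ob) - sum(vb))
    }
    if (any(con_f)) {
      lab <- labs_f[con_f]
      sol <- solve_edge(lab, labs_f, labs_r)
    } else {
      lab <- labs_r[con_r]
      sol <- solve_edge(lab, labs_r, labs_f)
    }
    i <- match(lab, params$transition)
    params$alpha[i] <- sol$alpha
    params$beta[i] <- sol$beta
    params$corr_a[i] <- 1
    params$corr_b[i] <- 1
  }
  params
}

#' Assemble the master-equation generator matrix
#'
#' Builds the rate matrix Q (ms^-1) at a fixed voltage under the convention
#' \code{dp/dt = Q p}, with \code{Q[j, i]} the i->j rate for \code{j != i}
#' and columns summing to zero. Entries for non-adjacent state pairs are
#' exactly zero.
#'
#' @param scheme A \code{\link{markov_scheme}}.
#' @param params A \code{\link{herg_params}} with constrained transitions
#'   resolved.
#' @param V Membrane potential (mV).
#' @return A dense \code{n x n} matrix with state dimnames.
#' @export
build_generator <- function(scheme, params, V) {
  if (is.character(scheme)) scheme <- markov_scheme(scheme)
  st <- scheme$states
  n <- length(st)
  Q <- matrix(0, n, n, dimnames = list(st, st))
  tr <- scheme$transitions
  for (k in seq_len(nrow(tr))) {
    i <- match(tr$from[k], st)
    j <- match(tr$to[k], st)
    row <- params[params$transition == tr$label[k], ]
    if (nrow(row) != 1L || is.na(row$alpha)) {
      stop("build_generator: missing parameters for transition '",
           tr$label[k], "'")
    }
    Q[j, i] <- Q[j, i] + .transition_rate(params, tr$label[k], V)
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}
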