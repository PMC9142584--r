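#' Nearest-neighbour isoform transition probabilities
#'
#' Container for the pair (p43, p34) of a two-state Markov description of
#' isoform succession along a fibril axis: `p43` is the probability that a
#' 4R monomer is followed by a 3R monomer, `p34` the probability that a 3R
#' monomer is followed by a 4R monomer. The complements p44 = 1 - p43 and
#' p33 = 1 - p34 are always derived, never stored. Probabilities are
#' fractions in \[0, 1\] everywhere in the API; percent appears only at I/O
#' boundaries.
#'
#' The pair (0, 0) is legal but degenerate (two non-mixing homopolymers;
#' the stationary mole fraction is then undefined) and is flagged by
#' [is_degenerate()]; operations that need a unique stationary state raise
#' an error on it.
#'
#' @param p43 Probability in \[0, 1\] that a 4R monomer is followed by 3R.
#' @param p34 Probability in \[0, 1\] that a 3R monomer is followed by 4R.
#' @param p43_err,p34_err Optional symmetric 1-sigma uncertainties.
#'
#' @return An object of class `transition_probs`.
#' @examples
#' p <- transition_probs(0.37, 0.56, p43_err = 0.03, p34_err = 0.02)
#' stationary_fraction(p)
#' mixing_quotient(p)
#' @export
transition_probs <- function(p43, p34, p43_err = NA_real_, p34_err = NA_real_) {
  check_probability(p43, "p43")
  check_probability(p34, "p34")
  for (e in list(p43_err, p34_err)) {
    if (!is.na(e) && (!is.numeric(e) || e < 0)) {
      abort("Uncertainties must be nonnegative numbers (or NA).")
    }
  }
  structure(
    list(p43 = as.numeric(p43), p34 = as.numeric(p34),
         p43_err = as.numeric(p43_err), p34_err = as.numeric(p34_err)),
    class = "transition_probs"
  )
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1], got %s.",
                  name, deparse(x)))
  }
  invisible(x)
}

#' @rdname transition_probs
#' @param x,p A `transition_probs` object.
#' @export
is_degenerate <- function(p) {
  stopifnot(inherits(p, "transition_probs"))
  p$p43 == 0 && p$p34 == 0
}

#' @rdname transition_probs
#' @param ... Ignored.
#' @export
print.transition_probs <- function(x, ...) {
  fmt <- function(v, e) {
    if (is.na(e)) sprintf("%.4f", v) else sprintf("%.4f +/- %.4f", v, e)
  }
  cat("Two-state isoform transition probabilities\n")
  cat("  p(4R -> 3R):", fmt(x$p43, x$p43_err),
      " [p(4R -> 4R) =", sprintf("%.4f]", 1 - x$p43), "\n")
  cat("  p(3R -> 4R):", fmt(x$p34, x$p34_err),
      " [p(3R -> 3R) =", sprintf("%.4f]", 1 - x$p34), "\n")
  if (is_degenerate(x)) cat("  (degenerate: no mixing, chi4 undefined)\n")
  invisible(x)
}

#' @method tidy transition_probs
#' @export
tidy.transition_probs <- function(x, ...) {
  tibble(
    term = c("p43", "p34", "p44", "p33"),
    estimate = c(x$p43, x$p34, 1 - x$p43, 1 - x$p34),
    std.error = c(x$p43_err, x$p34_err, x$p43_err, x$p34_err)
  )
}

#' Equivalent (chi4, Q) parameterization of isoform mixing
#'
#' A two-state Markov chain over \{4R, 3R\} is equivalently described by its
#' stationary 4R mole fraction `chi4` and the mixing quotient
#' `Q = p34 p43 / (p44 p33)`, an analogue of an equilibrium constant of
#' mixing: Q > 1 favours alternation, Q < 1 favours homotypic (block-like)
#' contacts, and Q = 1 is composition-agnostic mixing (p34 = p44 = chi4).
#'
#' @param chi4 Stationary 4R mole fraction in \[0, 1\].
#' @param Q Nonnegative mixing quotient.
#' @param chi4_err,Q_err Optional symmetric 1-sigma uncertainties.
#' @return An object of class `mixing_descriptors`.
#' @seealso [descriptors_to_probabilities()] for the inverse conversion.
#' @export
mixing_descriptors <- function(chi4, Q, chi4_err = NA_real_, Q_err = NA_real_) {
  check_probability(chi4, "chi4")
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q) || Q < 0) {
    abort("`Q` must be a single nonnegative number.")
  }
  structure(
    list(chi4 = as.numeric(chi4), Q = as.numeric(Q),
         chi4_err = as.numeric(chi4_err), Q_err = as.numeric(Q_err)),
    class = "mixing_descriptors"
  )
}

#' @export
print.mixing_descriptors <- function(x, ...) {
  fmt <- function(v, e) {
    if (is.na(e)) sprintf("%.4f", v) else sprintf("%.4f +/- %.4f", v, e)
  }
  cat("Isoform mixing descriptors\n")
  cat("  chi4 (4R mole fraction):", fmt(x$chi4, x$chi4_err), "\n")
  cat("  Q    (mixing quotient): ", fmt(x$Q, x$Q_err), "\n")
  invisible(x)
}

#' @method tidy mixing_descriptors
#' @export
tidy.mixing_descriptors <- function(x, ...) {
  tibble(term = c("chi4", "Q"),
         estimate = c(x$chi4, x$Q),
         std.error = c(x$chi4_err, x$Q_err))
}

#' Stationary 4R mole fraction of the two-state mixing model
#'
#' Under the assumption that the isoform composition is constant along the
#' fibril, balance of the 4R <-> 3R interconversion fluxes fixes the 4R mole
#' fraction at `chi4 = p34 / (p34 + p43)`. When input uncertainties are
#' available the returned uncertainty is first-order (Gaussian) propagated:
#' `err = sqrt((p43 e34)^2 + (p34 e43)^2) / (p34 + p43)^2`.
#'
#' @param p A [transition_probs()] object.
#' @return A one-row tibble with columns `chi4`, `chi4_err`.
#' @examples
#' stationary_fraction(transition_probs(0.37, 0.56)) # chi4 = 0.602
#' @export
stationary_fraction <- function(p) {
  stopifnot(inherits(p, "transition_probs"))
  if (is_degenerate(p)) {
    abort(paste("Degenerate transition probabilities p43 = p34 = 0:",
                "every composition is stationary, chi4 is undefined."))
  }
  s <- p$p34 + p$p43
  chi4 <- p$p34 / s
  err <- NA_real_
  if (!is.na(p$p43_err) && !is.na(p$p34_err)) {
    err <- sqrt((p$p43 * p$p34_err)^2 + (p$p34 * p$p43_err)^2) / s^2
  }
  tibble(chi4 = chi4, chi4_err = err)
}

#' Mixing quotient of the two-state mixing model
#'
#' Computes `Q = p34 p43 / ((1 - p43)(1 - p34))`, the analogue of an
#' equilibrium constant for converting homotypic (4-4, 3-3) interfaces into
#' heterotypic ones. A perfectly alternating fibril (p43 = p34 = 1) has
#' infinite Q and raises an error. First-order uncertainty propagation as
#' in [stationary_fraction()].
#'
#' @inheritParams stationary_fraction
#' @return A one-row tibble with columns `Q`, `Q_err`.
#' @examples
#' mixing_quotient(transition_probs(0.37, 0.56)) # Q = 0.747
#' @export
mixing_quotient <- function(p) {
  stopifnot(inherits(p, "transition_probs"))
  if (p$p43 == 1 || p$p34 == 1) {
    abort(paste("p43 = 1 or p34 = 1 describes perfect 4R-3R alternation:",
                "the mixing quotient Q is infinite."))
  }
  Q <- p$p34 * p$p43 / ((1 - p$p43) * (1 - p$p34))
  err <- NA_real_
  if (!is.na(p$p43_err) && !is.na(p$p34_err)) {
    dQ43 <- p$p34 / ((1 - p$p34) * (1 - p$p43)^2)
    dQ34 <- p$p43 / ((1 - p$p43) * (1 - p$p34)^2)
    err <- sqrt((dQ43 * p$p43_err)^2 + (dQ34 * p$p34_err)^2)
  }
  tibble(Q = Q, Q_err = err)
}

#' Convert (chi4, Q) descriptors back to transition probabilities
#'
#' Inverts the map (p43, p34) -> (chi4, Q). Eliminating
#' p34 = p43 chi4 / (1 - chi4) from the definition of Q leaves the
#' quadratic `r (Q - 1) p43^2 - Q (1 + r) p43 + Q = 0` with
#' r = chi4 / (1 - chi4); the root inside (0, 1) is selected (for Q = 1 the
#' equation is linear and gives the agnostic solution p43 = 1 - chi4). A
#' bisection fallback (tolerance 1e-12) guards against degenerate
#' discriminants. The result round-trips with [stationary_fraction()] and
#' [mixing_quotient()] to better than 1e-9.
#'
#' @param d A [mixing_descriptors()] object, or `chi4` given as a number
#'   with `Q` supplied via the second argument.
#' @param Q Mixing quotient when `d` is given as a bare chi4 value.
#' @return A [transition_probs()] object.
#' @examples
#' descriptors_to_probabilities(mixing_descriptors(0.602, 0.7475))
#' @export
descriptors_to_probabilities <- function(d, Q = NULL) {
  if (!inherits(d, "mixing_descriptors")) {
    d <- mixing_descriptors(d, Q)
  }
  chi4 <- d$chi4
  Q <- d$Q
  if (chi4 <= 0 || chi4 >= 1 || Q <= 0) {
    abort(sprintf(
      "No transition probabilities in (0,1)^2 exist for (chi4 = %g, Q = %g): need 0 < chi4 < 1 and Q > 0.",
      chi4, Q))
  }
  r <- chi4 / (1 - chi4)
  if (abs(Q - 1) < 1e-14) {
    p43 <- 1 / (1 + r) # = 1 - chi4, agnostic mixing
  } else {
    a <- r * (Q - 1)
    b <- -Q * (1 + r)
    cc <- Q
    disc <- b^2 - 4 * a * cc
    p43 <- NA_real_
    if (disc >= 0) {
      roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
      ok <- roots > 0 & roots < 1 & (r * roots) > 0 & (r * roots) < 1
      if (any(ok)) p43 <- roots[ok][1]
    }
    if (is.na(p43)) {
      f <- function(x) r * (Q - 1) * x^2 - Q * (1 + r) * x + Q
      lo <- 1e-15
      hi <- min(1, 1 / r) - 1e-15
      if (f(lo) * f(hi) > 0) {
        abort(sprintf(
          "No transition probabilities in (0,1)^2 satisfy (chi4 = %g, Q = %g).",
          chi4, Q))
      }
      p43 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    }
  }
  p34 <- r * p43
  if (p34 <= 0 || p34 >= 1 || p43 <= 0 || p43 >= 1) {
    abort(sprintf(
      "No transition probabilities in (0,1)^2 satisfy (chi4 = %g, Q = %g).",
      chi4, Q))
  }
  transition_probs(p43, p34)
}

#' Stationarity (detailed-balance) residual
#'
#' Net 4R flux imbalance `chi4 * p43 - (1 - chi4) * p34` when the fibril
#' composition is `chi4`: zero exactly when `chi4` is the stationary mole
#' fraction of `p`. (The printed one-step composition recursion in the
#' source literature of this model family contains a typo; the flux-balance
#' form used here is the one consistent with the stationary solution
#' chi4 = p34 / (p34 + p43).)
#'
#' @param chi4 Candidate 4R mole fraction in \[0, 1\].
#' @inheritParams stationary_fraction
#' @return A single number; 0 iff `chi4` is stationary.
#' @export
stationarity_residual <- function(chi4, p) {
  stopifnot(inherits(p, "transition_probs"))
  check_probability(chi4, "chi4")
  chi4 * p$p43 - (1 - chi4) * p$p34
}

#' Derive both mixing descriptors (with uncertainties) from probabilities
#'
#' Convenience wrapper bundling [stationary_fraction()] and
#' [mixing_quotient()] into a [mixing_descriptors()] object.
#'
#' @inheritParams stationary_fraction
#' @return A [mixing_descriptors()] object.
#' @export
probabilities_to_descriptors <- function(p) {
  cf <- stationary_fraction(p)
  mq <- mixing_quotient(p)
  mixing_descriptors(cf$chi4, mq$Q, chi4_err = cf$chi4_err, Q_err = mq$Q_err)
}

#' JSON serialization of mixing parameterizations
#'
#' Writes/reads the plain JSON forms
#' `{"p43": ..., "p34": ..., "p43_err": ..., "p34_err": ...}` and
#' `{"chi4": ..., "Q": ..., ...}`.
#'
#' @param x A `transition_probs` or `mixing_descriptors` object.
#' @param path File path; for `write_mixing_json()` the destination, for
#'   `read_mixing_json()` the source.
#' @return `read_mixing_json()` returns the reconstructed object (class
#'   chosen by the fields present).
#' @export
write_mixing_json <- function(x, path) {
  stopifnot(inherits(x, "transition_probs") || inherits(x, "mixing_descriptors"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_mixing_json
#' @export
read_mixing_json <- function(path) {
  raw <- jsonlite::read_json(path)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  if (!is.null(raw$p43)) {
    transition_probs(num(raw$p43), num(raw$p34),
                     p43_err = num(raw$p43_err), p34_err = num(raw$p34_err))
  } else if (!is.null(raw$chi4)) {
    mixing_descriptors(num(raw$chi4), num(raw$Q),
                       chi4_err = num(raw$chi4_err), Q_err = num(raw$Q_err))
  } else {
    abort(sprintf("File '%s' has neither (p43, p34) nor (chi4, Q) fields.", path))
  }
}
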