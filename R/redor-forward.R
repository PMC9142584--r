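#' Heteronuclear second moment from a distance list
#'
#' Van Vleck second moment of n 13C-15N dipolar couplings,
#' `M2 = (1/5) * sum_i (3000 Hz / r_i^3)^2`, with r_i in Angstrom and
#' 3000 Hz the 13C-15N dipolar coupling constant at 1 Angstrom. Additive
#' over disjoint distance lists; an empty list gives 0.
#'
#' @param distances Numeric vector of internuclear distances in Angstrom
#'   (all > 0); may be empty.
#' @return Second moment in Hz^2.
#' @examples
#' second_moment(4.1) # ~379 Hz^2
#' @export
second_moment <- function(distances) {
  if (length(distances) == 0) return(0)
  if (!is.numeric(distances) || any(is.na(distances)) || any(distances <= 0)) {
    abort("All distances must be positive numbers (Angstrom).")
  }
  sum((3000 / distances^3)^2) / 5
}

#' Gaussian REDOR dephasing curve from a second moment
#'
#' Multi-spin REDOR dephasing in the second-moment (Gaussian)
#' approximation: `S/S0(t) = exp(-4 M2 t^2 / (3 pi^2))`. Equals 1 at t = 0
#' and is monotone nonincreasing; depends on M2 and t only through M2 t^2.
#' The approximation absorbs powder averaging, finite pulses, 13C chemical
#' shifts, and 13C-13C couplings.
#'
#' @param M2 Second moment in Hz^2 (>= 0).
#' @param times_s Mixing times in seconds (vectorized).
#' @return S/S0 values in (0, 1\].
#' @export
gaussian_dephasing <- function(M2, times_s) {
  if (!is.numeric(M2) || length(M2) != 1L || is.na(M2) || M2 < 0) {
    abort("`M2` must be a single nonnegative number (Hz^2).")
  }
  exp(-4 * M2 * times_s^2 / (3 * pi^2))
}

#' Packing-mode probabilities of the flanking-neighbour labeling
#'
#' For a 15N-labeled monomer observed in a parallel-in-register stack
#' where each neighbour is 13C-labeled independently with probability
#' `pNC`, the four packing modes N-N-N, N-N-C, C-N-N, C-N-C (identities of
#' the preceding and succeeding neighbour) occur with probabilities
#' `(1-p)^2, p(1-p), (1-p)p, p^2`, which sum to 1.
#'
#' @param pNC Probability in \[0, 1\] that a neighbour is 13C-labeled.
#' @return Named numeric vector `c(NNN, NNC, CNN, CNC)`.
#' @export
packing_mode_weights <- function(pNC) {
  check_probability(pNC, "pNC")
  c(NNN = (1 - pNC)^2, NNC = pNC * (1 - pNC),
    CNN = (1 - pNC) * pNC, CNC = pNC^2)
}

#' 15N-centric spin geometry of the cross-beta stack
#'
#' Distance lists from a reference backbone amide 15N to the carbon atoms
#' of the hydrogen-bonded neighbour chain above ("succeeding", +z) and
#' below ("preceding", -z), truncated at `cutoff_radius`. The
#' `nat_abund_rate` is the Gaussian rate constant k (s^-2) of the
#' natural-abundance background decay `exp(-k t^2)` that an all-15N sample
#' shows; see [nat_abund_rate_from_anchor()].
#'
#' @param distances_succeeding,distances_preceding Distances in Angstrom.
#' @param cutoff_radius Truncation radius in Angstrom.
#' @param nat_abund_rate Background Gaussian rate constant in s^-2.
#' @return An object of class `spin_geometry`.
#' @export
spin_geometry <- function(distances_succeeding, distances_preceding,
                          cutoff_radius = 5.8,
                          nat_abund_rate = nat_abund_rate_from_anchor()) {
  for (d in list(distances_succeeding, distances_preceding)) {
    if (length(d) > 0 && (any(d <= 0) || any(d > cutoff_radius + 1e-9))) {
      abort("All distances must be positive and within `cutoff_radius`.")
    }
  }
  structure(
    list(distances_succeeding = as.numeric(distances_succeeding),
         distances_preceding = as.numeric(distances_preceding),
         cutoff_radius = cutoff_radius,
         nat_abund_rate = nat_abund_rate),
    class = "spin_geometry")
}

#' @export
print.spin_geometry <- function(x, ...) {
  cat("15N-centric spin geometry\n")
  cat(sprintf("  succeeding chain: %d carbons, %s\n",
              length(x$distances_succeeding),
              if (length(x$distances_succeeding)) {
                sprintf("%.2f-%.2f A", min(x$distances_succeeding),
                        max(x$distances_succeeding))
              } else "none"))
  cat(sprintf("  preceding chain:  %d carbons, %s\n",
              length(x$distances_preceding),
              if (length(x$distances_preceding)) {
                sprintf("%.2f-%.2f A", min(x$distances_preceding),
                        max(x$distances_preceding))
              } else "none"))
  cat(sprintf("  cutoff radius %.2f A, background rate %.1f s^-2\n",
              x$cutoff_radius, x$nat_abund_rate))
  invisible(x)
}

#' Background decay rate anchored to a reference dephasing value
#'
#' The natural-abundance 13C background is modelled as a Gaussian decay
#' `exp(-k t^2)` (the same functional family as the second-moment curve)
#' whose single rate constant is fixed by one anchor: an all-15N sample
#' dephasing to `ratio` at `t_ms`. The default anchor (0.84 at 25 ms)
#' gives k ~ 279 s^-2.
#'
#' @param ratio Anchor S/S0 value in (0, 1\].
#' @param t_ms Anchor mixing time in ms.
#' @return Rate constant k in s^-2.
#' @export
nat_abund_rate_from_anchor <- function(ratio = 0.84, t_ms = 25) {
  stopifnot(ratio > 0, ratio <= 1, t_ms > 0)
  -log(ratio) / (t_ms / 1000)^2
}

#' Natural-abundance background curve
#'
#' @param times_ms Mixing times in ms.
#' @param rate Gaussian rate constant in s^-2 (default anchored to 0.84 at
#'   25 ms).
#' @return A tibble `time_ms`, `ratio`.
#' @export
nat_abund_curve <- function(times_ms, rate = nat_abund_rate_from_anchor()) {
  tibble(time_ms = times_ms, ratio = exp(-rate * (times_ms / 1000)^2))
}

#' Predicted REDOR curve for a statistical labeling mixture
#'
#' Weights the Gaussian dephasing of the four packing modes by their
#' probabilities: `S/S0(t) = w_NNN + w_NNC G(M2_succ, t) + w_CNN
#' G(M2_prec, t) + w_CNC G(M2_succ + M2_prec, t)`. The N-N-N mode does not
#' dephase; the C-N-C second moment is the sum of both one-sided moments
#' (second moments are additive over spins). The result is monotone
#' nonincreasing in t and, at fixed t > 0 with nonempty geometry, strictly
#' decreasing in `pNC`. The natural-abundance background is *not* included
#' here; it enters synthesis via [generate_calibration_series()] and
#' analysis via [natural_abundance_correct()].
#'
#' @param pNC Probability that a neighbour monomer is 13C-labeled.
#' @param geom A [spin_geometry()].
#' @param times_ms Mixing times in ms.
#' @param cnc_radius Optional tighter truncation radius (Angstrom) applied
#'   to both distance lists for the C-N-C mode only (the two-sided mode is
#'   sometimes truncated earlier so its spin count matches a reference
#'   simulation set).
#' @return A tibble `time_ms`, `ratio` of class `tbl_df`.
#' @export
mixture_curve <- function(pNC, geom, times_ms, cnc_radius = NULL) {
  stopifnot(inherits(geom, "spin_geometry"))
  w <- packing_mode_weights(pNC)
  t_s <- times_ms / 1000
  m2_succ <- second_moment(geom$distances_succeeding)
  m2_prec <- second_moment(geom$distances_preceding)
  if (is.null(cnc_radius)) {
    m2_cnc <- m2_succ + m2_prec
  } else {
    m2_cnc <- second_moment(
      c(geom$distances_succeeding[geom$distances_succeeding <= cnc_radius],
        geom$distances_preceding[geom$distances_preceding <= cnc_radius]))
  }
  ratio <- w[["NNN"]] +
    w[["NNC"]] * gaussian_dephasing(m2_succ, t_s) +
    w[["CNN"]] * gaussian_dephasing(m2_prec, t_s) +
    w[["CNC"]] * gaussian_dephasing(m2_cnc, t_s)
  tibble(time_ms = times_ms, ratio = ratio)
}

#' Divide out the natural-abundance background of a measured curve
#'
#' Pointwise division of a measured curve by the reference curve of an
#' all-15N (0 % 13C) sample, removing the dephasing caused by
#' natural-abundance 13C. Per-point noise, when present, is propagated by
#' the quotient rule
#' `sigma_out = |r_c/r_ref| sqrt((s_c/r_c)^2 + (s_ref/r_ref)^2)`.
#'
#' @param curve,reference Tibbles with columns `time_ms`, `ratio` and
#'   optionally `sigma`, on identical time grids.
#' @return A corrected curve tibble (`time_ms`, `ratio`, `sigma` if
#'   available).
#' @export
natural_abundance_correct <- function(curve, reference) {
  check_curve(curve)
  check_curve(reference)
  if (nrow(curve) != nrow(reference) ||
      !isTRUE(all.equal(curve$time_ms, reference$time_ms, tolerance = 1e-9))) {
    abort("`curve` and `reference` must share the same mixing-time grid.")
  }
  if (any(reference$ratio <= 0)) {
    abort("Reference ratios must all be > 0 for background division.")
  }
  out <- tibble(time_ms = curve$time_ms,
                ratio = curve$ratio / reference$ratio)
  s_c <- curve[["sigma"]]
  s_r <- reference[["sigma"]]
  if (!is.null(s_c) || !is.null(s_r)) {
    s_c <- s_c %||% rep(0, nrow(curve))
    s_r <- s_r %||% rep(0, nrow(reference))
    out$sigma <- abs(out$ratio) *
      sqrt((s_c / curve$ratio)^2 + (s_r / reference$ratio)^2)
  }
  out
}

# internal: validate a REDOR curve tibble
check_curve <- function(curve, require_sigma = FALSE) {
  if (!is.data.frame(curve) || !all(c("time_ms", "ratio") %in% names(curve))) {
    abort("A REDOR curve needs columns `time_ms` and `ratio`.")
  }
  if (is.unsorted(curve$time_ms, strictly = TRUE) || any(curve$time_ms < 0)) {
    abort("`time_ms` must be strictly increasing and nonnegative.")
  }
  if (require_sigma && is.null(curve[["sigma"]])) {
    abort("This operation needs a `sigma` column of per-point noise.")
  }
  invisible(curve)
}

#' Default REDOR mixing-time grid
#'
#' 28 mixing times from 0.1 to 25 ms, rotor-synchronized at 20 kHz MAS
#' (all points are multiples of the 0.05 ms rotor period), with 18 points
#' on the 8-25 ms analysis window used by the interpolation estimator.
#'
#' @return Numeric vector of mixing times in ms.
#' @export
default_time_grid <- function() {
  c(0.1, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, seq(8, 25, by = 1))
}
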