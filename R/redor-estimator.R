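#' Average replicate REDOR curves
#'
#' Pointwise mean over replicates measured on a shared mixing-time grid;
#' per-point noise is combined as rms / sqrt(n).
#'
#' @param curves Either a long tibble with columns `replicate`, `time_ms`,
#'   `ratio` (optionally `sigma`), or a list of curve tibbles.
#' @return A single curve tibble `time_ms`, `ratio` (and `sigma`).
#' @export
average_replicates <- function(curves) {
  if (is.data.frame(curves)) {
    if (!"replicate" %in% names(curves)) {
      curves$replicate <- 1L
    }
  } else {
    curves <- purrr::imap_dfr(curves, function(cv, i) {
      check_curve(cv)
      dplyr::mutate(cv, replicate = i)
    })
  }
  counts <- dplyr::count(curves, .data$time_ms)
  if (length(unique(counts$n)) != 1L) {
    abort("Replicate curves must share the same mixing-time grid.")
  }
  has_sigma <- "sigma" %in% names(curves) && !all(is.na(curves$sigma))
  out <- curves |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      sigma = if (has_sigma) sqrt(mean(.data$sigma^2)) / sqrt(dplyr::n()) else NA_real_,
      ratio = mean(.data$ratio),
      .groups = "drop") |>
    dplyr::arrange(.data$time_ms) |>
    dplyr::select("time_ms", "ratio", "sigma", "n_rep")
  out
}

#' Interpolate a labeling probability between two calibration curves
#'
#' At each mixing time i in the analysis window, the measured S/S0 value
#' is linearly interpolated between the two bracketing calibration curves
#' with known 13C fractions (expressed in percent):
#' `p_i = (meas_i - high_i) / (low_i - high_i) * (low% - high%) + high%`,
#' where `low` is the smaller 13C fraction (which dephases less and so has
#' the *higher* S/S0). The per-point values are averaged over the window
#' (default 8-25 ms) and returned as a fraction; the uncertainty comes
#' from [propagate_error()]. Points where the two calibration curves
#' coincide (zero denominator) are excluded with a warning; per-point
#' values falling outside the bracket are retained, not clipped (clipping
#' would bias the mean), but an error advising wider brackets is raised if
#' most of the window lies outside the span.
#'
#' @param measured A curve tibble `time_ms`, `ratio` (optionally `sigma`).
#' @param cal A calibration set: long tibble with columns `fraction`,
#'   `time_ms`, `ratio` (optionally `sigma`) on the measured grid.
#' @param low_frac,high_frac The two bracketing 13C fractions present in
#'   `cal`, `low_frac < high_frac`.
#' @param window Analysis window in ms, `c(t_min, t_max)`, inclusive.
#' @return A one-row tibble of class `probability_estimate`: `p`, `err`,
#'   `low_frac`, `high_frac`, `t_min`, `t_max`, `n_points`.
#' @export
interpolate_probability <- function(measured, cal, low_frac, high_frac,
                                    window = c(8, 25)) {
  check_curve(measured)
  if (!all(c("fraction", "time_ms", "ratio") %in% names(cal))) {
    abort("`cal` must be a long tibble with columns fraction, time_ms, ratio.")
  }
  if (!(low_frac < high_frac)) abort("`low_frac` must be < `high_frac`.")
  pick <- function(f) {
    cv <- dplyr::filter(cal, abs(.data$fraction - f) < 1e-9) |>
      dplyr::arrange(.data$time_ms)
    if (nrow(cv) == 0) {
      abort(sprintf("Calibration set has no curve at fraction %g.", f))
    }
    cv
  }
  lo <- pick(low_frac)
  hi <- pick(high_frac)
  if (!isTRUE(all.equal(lo$time_ms, measured$time_ms, tolerance = 1e-9)) ||
      !isTRUE(all.equal(hi$time_ms, measured$time_ms, tolerance = 1e-9))) {
    abort("Measured and calibration curves must share the mixing-time grid.")
  }
  in_win <- measured$time_ms >= window[1] & measured$time_ms <= window[2]
  if (!any(in_win)) abort("The analysis window contains no mixing times.")
  m <- measured$ratio[in_win]
  l <- lo$ratio[in_win]
  h <- hi$ratio[in_win]
  d <- l - h
  usable <- abs(d) > .Machine$double.eps^0.5
  if (!all(usable)) {
    warn(sprintf(
      "%d window point(s) excluded: bracketing calibration curves coincide there.",
      sum(!usable)))
  }
  if (!any(usable)) {
    abort("All window points have coincident calibration curves; cannot interpolate.")
  }
  gap_pp <- (high_frac - low_frac) * 100
  # per-point interpolation on the percent scale, as in the calibration method
  p_i <- (m[usable] - h[usable]) / d[usable] * (low_frac * 100 - high_frac * 100) +
    high_frac * 100
  p <- mean(p_i) / 100
  outside <- p_i / 100 < low_frac - (high_frac - low_frac) |
    p_i / 100 > high_frac + (high_frac - low_frac)
  if (mean(outside) > 0.5) {
    abort(paste("The measured curve lies outside the calibration span over",
                "most of the analysis window; re-run with wider brackets."))
  }
  err <- NA_real_
  if (!is.null(measured[["sigma"]]) || !is.null(lo[["sigma"]]) ||
      !is.null(hi[["sigma"]])) {
    z <- function(s, n) if (is.null(s)) rep(0, n) else ifelse(is.na(s), 0, s)
    err <- propagate_error(
      eps_measured = z(measured[["sigma"]], nrow(measured))[in_win][usable],
      eps_low = z(lo[["sigma"]], nrow(lo))[in_win][usable],
      eps_high = z(hi[["sigma"]], nrow(hi))[in_win][usable],
      measured = m[usable], low = l[usable], high = h[usable],
      gap_pp = gap_pp)
  }
  structure(
    tibble(p = p, err = err, low_frac = low_frac, high_frac = high_frac,
           t_min = window[1], t_max = window[2], n_points = sum(usable)),
    class = c("probability_estimate", "tbl_df", "tbl", "data.frame"))
}

#' Propagate spectral noise through the calibration interpolation
#'
#' First-order (Gaussian) propagation of the per-point spectral noise of
#' the measured curve and both calibration curves through the linear
#' interpolation, on the percent scale. With d_i the calibration gap
#' `low_i - high_i` at point i, the per-point variance (in units of the
#' bracket width) is
#' `(eps_meas/d)^2 + ((meas - low) eps_high / d^2)^2 +
#'  ((meas - high) eps_low / d^2)^2`,
#' and the reported uncertainty is the bracket width in percentage points
#' (10 for a 0.30/0.40 bracket) times the rms of these per-point sigmas
#' over the window, returned as a fraction. Note this is the rms
#' *per-point* uncertainty: no 1/sqrt(n) reduction is applied for the
#' window average, making the estimate conservative for the mean (see the
#' methods vignette).
#'
#' @param eps_measured,eps_low,eps_high Per-point noise of the measured
#'   and bracketing calibration curves over the window.
#' @param measured,low,high The corresponding S/S0 values.
#' @param gap_pp Bracket width in percentage points (e.g. 10).
#' @return Uncertainty as a fraction (percentage points / 100).
#' @export
propagate_error <- function(eps_measured, eps_low, eps_high,
                            measured, low, high, gap_pp = 10) {
  d <- low - high
  if (any(abs(d) <= .Machine$double.eps^0.5)) {
    abort("Zero calibration gap in `propagate_error`; exclude those points first.")
  }
  var_i <- (eps_measured / d)^2 +
    ((measured - low) * eps_high / d^2)^2 +
    ((measured - high) * eps_low / d^2)^2
  (gap_pp * sqrt(mean(var_i))) / 100
}

#' Estimate both transition probabilities from a full REDOR dataset
#'
#' Runs the complete extraction: (1) optional natural-abundance correction
#' of every measured and calibration curve by pointwise division with the
#' 0 %-13C reference curve, (2) replicate averaging per labeling scheme,
#' (3) per-scheme calibration interpolation over the analysis window with
#' the scheme's bracketing fractions, and (4) conversion of the two
#' recovered probabilities to the stationary 4R fraction and mixing
#' quotient with first-order error propagation.
#'
#' The labeling scheme named in `scheme_p43` (default `"4N3C"`: 4R carries
#' 15N, 3R carries 13C) measures p43; the reverse scheme measures p34.
#'
#' @param measured Long tibble with columns `scheme`, `replicate`,
#'   `time_ms`, `ratio` (optionally `sigma`).
#' @param cal Calibration set: long tibble `fraction`, `time_ms`, `ratio`
#'   (optionally `sigma`), including fraction 0 when `na_correct = TRUE`.
#' @param brackets Named list of `c(low, high)` bracketing fractions per
#'   scheme, e.g. `list("4N3C" = c(0.3, 0.4), "3N4C" = c(0.5, 0.6))`.
#' @param window Analysis window in ms.
#' @param na_correct Divide out the fraction-0 reference curve first?
#' @param scheme_p43 Name of the scheme measuring p43.
#' @return An object of class `mixing_fit`; see [tidy.mixing_fit()].
#' @export
estimate_full_dataset <- function(measured, cal,
                                  brackets = list("4N3C" = c(0.30, 0.40),
                                                  "3N4C" = c(0.50, 0.60)),
                                  window = c(8, 25),
                                  na_correct = TRUE,
                                  scheme_p43 = "4N3C") {
  stopifnot(all(c("scheme", "time_ms", "ratio") %in% names(measured)))
  schemes <- unique(measured$scheme)
  if (!all(schemes %in% names(brackets))) {
    abort("Every measured scheme needs an entry in `brackets`.")
  }
  if (length(schemes) != 2) {
    abort("Expected exactly two labeling schemes (one per transition probability).")
  }
  if (!scheme_p43 %in% schemes) {
    abort(sprintf("`scheme_p43` ('%s') is not among the measured schemes.", scheme_p43))
  }
  if (na_correct) {
    ref <- dplyr::filter(cal, abs(.data$fraction) < 1e-9) |>
      dplyr::arrange(.data$time_ms)
    if (nrow(ref) == 0) {
      abort("Natural-abundance correction requested but the calibration set has no fraction-0 reference curve.")
    }
    correct_one <- function(cv) natural_abundance_correct(cv, ref)
    cal <- cal |>
      dplyr::filter(.data$fraction > 1e-9) |>
      dplyr::group_by(.data$fraction) |>
      dplyr::group_modify(~ correct_one(dplyr::arrange(.x, .data$time_ms))) |>
      dplyr::ungroup()
    if (!"replicate" %in% names(measured)) measured$replicate <- 1L
    measured <- measured |>
      dplyr::group_by(.data$scheme, .data$replicate) |>
      dplyr::group_modify(~ correct_one(dplyr::arrange(.x, .data$time_ms))) |>
      dplyr::ungroup()
  }
  per_scheme <- purrr::map(schemes, function(sc) {
    avg <- average_replicates(dplyr::filter(measured, .data$scheme == sc))
    br <- brackets[[sc]]
    interpolate_probability(avg, cal, br[1], br[2], window = window)
  })
  names(per_scheme) <- schemes
  est_p43 <- per_scheme[[scheme_p43]]
  est_p34 <- per_scheme[[setdiff(schemes, scheme_p43)]]
  probs <- transition_probs(
    min(max(est_p43$p, 0), 1), min(max(est_p34$p, 0), 1),
    p43_err = est_p43$err, p34_err = est_p34$err)
  desc <- probabilities_to_descriptors(probs)
  structure(
    list(probabilities = probs, descriptors = desc,
         estimates = dplyr::bind_rows(
           purrr::imap(per_scheme, ~ dplyr::mutate(as_tibble(.x), scheme = .y,
                                                   .before = 1))),
         window = window, brackets = brackets, na_correct = na_correct,
         scheme_p43 = scheme_p43),
    class = "mixing_fit")
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat("REDOR calibration-interpolation fit\n")
  cat(sprintf("  window %g-%g ms; brackets: %s\n", x$window[1], x$window[2],
              paste(sprintf("%s in [%.2f, %.2f]", names(x$brackets),
                            vapply(x$brackets, `[`, 0, 1),
                            vapply(x$brackets, `[`, 0, 2)), collapse = "; ")))
  print(x$probabilities)
  print(x$descriptors)
  invisible(x)
}

#' Tidy and summarize a REDOR mixing fit
#'
#' `tidy()` returns one row per fitted quantity (p43, p34, chi4, Q) with
#' its propagated standard error; `glance()` returns a one-row summary of
#' the fit setup.
#'
#' @param x A `mixing_fit` from [estimate_full_dataset()].
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy mixing_fit
#' @export
tidy.mixing_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::filter(tidy(x$probabilities), .data$term %in% c("p43", "p34")),
    tidy(x$descriptors))
}

#' @rdname tidy.mixing_fit
#' @rdname tidy.mixing_fit
#' @method glance mixing_fit
#' @export
glance.mixing_fit <- function(x, ...) {
  tibble(
    n_schemes = nrow(x$estimates), t_min = x$window[1], t_max = x$window[2],
    n_points = sum(x$estimates$n_points), na_correct = x$na_correct)
}

#' Labeled-monomer fraction from 1D spectral intensity ratios
#'
#' Quantifies the 13C-labeled monomer fraction from one-dimensional
#' spectral intensities normalized to a double-labeled (equal 13C and 15N
#' content) reference sample: `fraction = r_C / (r_C + r_N)` where `r_C`
#' and `r_N` are the sample/reference intensity ratios of the 13C and 15N
#' spectra. The caller maps the labeled fraction to an isoform fraction
#' according to the labeling scheme. A default uncertainty of 0.03 is
#' attached, the scale estimated for intensity-ratio quantification.
#'
#' @param r_C,r_N Positive sample/reference intensity ratios.
#' @param uncertainty Symmetric uncertainty to attach (default 0.03).
#' @return A one-row tibble `fraction`, `err`.
#' @export
fraction_from_intensities <- function(r_C, r_N, uncertainty = 0.03) {
  if (!is.numeric(r_C) || !is.numeric(r_N) || any(r_C <= 0) || any(r_N <= 0)) {
    abort("Intensity ratios must be positive.")
  }
  tibble(fraction = r_C / (r_C + r_N), err = uncertainty)
}
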