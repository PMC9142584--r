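#' Configuration for the synthetic REDOR data generator
#'
#' Bundles everything the generator needs to emulate a complete
#' experimental campaign: the spin geometry of the cross-beta stack, the
#' mixing-time grid (default 28 points from 0.1 to 25 ms with 18 on the
#' 8-25 ms analysis window), the calibration 13C fractions (default 0 to
#' 0.7 in steps of 0.1), the true transition probabilities of the
#' mixed-isoform samples, the number of independently fibrillized
#' replicates per labeling scheme (default 2), the per-point
#' signal-to-noise ratio, and the natural-abundance background anchored so
#' the 0 %-13C reference dephases to 0.84 at 25 ms.
#'
#' The default `snr = 3000` places the propagated uncertainty of the
#' recovered probabilities near the +-0.02-0.03 scale of a careful
#' experimental campaign. The nominal value is high because the packaged
#' second-moment geometry dephases far less than real samples, so the
#' bracketing calibration curves are separated by only ~0.001-0.01 S/S0
#' units over the analysis window (see the methods vignette). Use
#' `snr = Inf` for noiseless data.
#'
#' @param geometry A [spin_geometry()]; defaults to the packaged synthetic
#'   fixture [default_spin_geometry()].
#' @param times_ms Mixing-time grid in ms.
#' @param fractions Calibration 13C fractions (must include 0 for the
#'   natural-abundance reference).
#' @param p43,p34 True transition probabilities of the seeded samples.
#' @param replicates Replicates per labeling scheme.
#' @param snr Per-point signal-to-noise ratio (noise sigma = 1/snr on both
#'   S and S0); `Inf` for noiseless curves.
#' @param nat_abund_anchor `c(ratio, t_ms)` anchor of the background decay.
#' @param cnc_radius Truncation radius for the C-N-C packing mode.
#' @param seed Master seed; fixed seeds give bit-identical datasets.
#' @return A list of class `synthesis_config`.
#' @export
synthesis_config <- function(geometry = default_spin_geometry(),
                             times_ms = default_time_grid(),
                             fractions = seq(0, 0.7, by = 0.1),
                             p43 = 0.37, p34 = 0.56,
                             replicates = 2,
                             snr = 3000,
                             nat_abund_anchor = c(ratio = 0.84, t_ms = 25),
                             cnc_radius = attr(geometry, "cnc_radius") %||% 5.5,
                             seed = 1L) {
  stopifnot(inherits(geometry, "spin_geometry"))
  fractions <- round(fractions, 10) # so seq()-built fractions compare exactly
  if (is.unsorted(fractions, strictly = TRUE) || any(fractions < 0) ||
      any(fractions > 1)) {
    abort("`fractions` must be strictly increasing within [0, 1].")
  }
  check_probability(p43, "p43")
  check_probability(p34, "p34")
  if (!is.numeric(snr) || snr <= 0) abort("`snr` must be positive (may be Inf).")
  structure(
    list(geometry = geometry, times_ms = times_ms, fractions = fractions,
         p43 = p43, p34 = p34, replicates = as.integer(replicates),
         snr = snr,
         nat_abund_rate = nat_abund_rate_from_anchor(nat_abund_anchor[[1]],
                                                     nat_abund_anchor[[2]]),
         cnc_radius = cnc_radius, seed = as.integer(seed)),
    class = "synthesis_config")
}

# internal: noiseless model curve including background for one pNC
.true_curve <- function(cfg, pNC) {
  mc <- mixture_curve(pNC, cfg$geometry, cfg$times_ms,
                      cnc_radius = cfg$cnc_radius)
  mc$ratio <- mc$ratio * exp(-cfg$nat_abund_rate * (cfg$times_ms / 1000)^2)
  mc
}

# internal: add spectral noise on S and S0 and form the ratio; uses the
# current RNG state. sigma is reported by the quotient rule at the noisy
# S, S0 values, as it would be estimated from measured spectra.
.noisy_curve <- function(true_ratio, times_ms, snr) {
  if (!is.finite(snr)) {
    return(tibble(time_ms = times_ms, S = true_ratio, S0 = rep(1, length(times_ms)),
                  ratio = true_ratio, sigma = rep(0, length(times_ms))))
  }
  eps <- 1 / snr
  S0 <- 1 + rnorm(length(times_ms), sd = eps)
  S <- true_ratio + rnorm(length(times_ms), sd = eps)
  ratio <- S / S0
  sigma <- abs(ratio) * sqrt((eps / S)^2 + (eps / S0)^2)
  tibble(time_ms = times_ms, S = S, S0 = S0, ratio = ratio, sigma = sigma)
}

#' Generate a synthetic calibration curve family
#'
#' For every 13C fraction f in the configuration, generates the curve
#' `mixture_curve(f) * background` plus spectral noise at the configured
#' S/N. Mirroring the experimental design, each calibration curve is
#' returned as the average of `cfg$replicates` independently noisy samples
#' (per-point noise combined as rms / sqrt(n)). The fraction-0 curve
#' dephases only through the natural-abundance background (to 0.84 at
#' 25 ms under the default anchor); noiseless curves are pointwise
#' ordered: larger f dephases faster.
#'
#' @param cfg A [synthesis_config()].
#' @return A long tibble `fraction`, `time_ms`, `ratio`, `sigma`, `n_rep`.
#' @export
generate_calibration_series <- function(cfg) {
  stopifnot(inherits(cfg, "synthesis_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  purrr::map_dfr(cfg$fractions, function(f) {
    truth <- .true_curve(cfg, f)
    reps <- purrr::map_dfr(seq_len(cfg$replicates), function(r) {
      dplyr::mutate(.noisy_curve(truth$ratio, cfg$times_ms, cfg$snr),
                    replicate = r)
    })
    dplyr::mutate(average_replicates(reps), fraction = f, .before = 1)
  })
}

#' Generate synthetic mixed-isoform ("seeded") REDOR datasets
#'
#' Generates replicate curves for both labeling schemes of a seeded
#' mixed-isoform experiment: scheme `"4N3C"` (4R carries 15N, 3R carries
#' 13C) dephases with neighbour-labeling probability `pNC = p43`, scheme
#' `"3N4C"` with `pNC = p34`. Geometry, grid, background and S/N are
#' shared with the calibration series; replicate noise is independent.
#' The RNG stream is offset from the calibration stream so the two
#' datasets are independent but jointly reproducible from the master
#' seed.
#'
#' @inheritParams generate_calibration_series
#' @return A long tibble `scheme`, `replicate`, `time_ms`, `S`, `S0`,
#'   `ratio`, `sigma`.
#' @export
generate_seeded_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthesis_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1000L)
  schemes <- c("4N3C" = cfg$p43, "3N4C" = cfg$p34)
  purrr::imap_dfr(schemes, function(pNC, sc) {
    truth <- .true_curve(cfg, pNC)
    purrr::map_dfr(seq_len(cfg$replicates), function(r) {
      dplyr::mutate(.noisy_curve(truth$ratio, cfg$times_ms, cfg$snr),
                    scheme = sc, replicate = r, .before = 1)
    })
  })
}

#' Write a synthetic dataset bundle to disk
#'
#' Writes the calibration family and seeded curves as CSV plus a manifest
#' JSON recording the configuration and the truth values, so test
#' harnesses can check recovery without regenerating.
#'
#' @param cfg A [synthesis_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cal <- generate_calibration_series(cfg)
  seeded <- generate_seeded_dataset(cfg)
  readr::write_csv(cal, file.path(dir, "calibration.csv"))
  readr::write_csv(seeded, file.path(dir, "seeded.csv"))
  manifest <- list(
    truth = list(p43 = cfg$p43, p34 = cfg$p34),
    fractions = cfg$fractions, replicates = cfg$replicates,
    snr = cfg$snr, nat_abund_rate = cfg$nat_abund_rate,
    cnc_radius = cfg$cnc_radius, seed = cfg$seed,
    times_ms = cfg$times_ms,
    geometry = list(
      distances_succeeding = cfg$geometry$distances_succeeding,
      distances_preceding = cfg$geometry$distances_preceding,
      cutoff_radius = cfg$geometry$cutoff_radius,
      nat_abund_rate = cfg$geometry$nat_abund_rate))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
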