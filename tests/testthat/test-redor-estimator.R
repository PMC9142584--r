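make_noiseless_set <- function(fractions = c(0, seq(0.1, 0.7, by = 0.1))) {
  cfg <- noiseless_config(fractions = fractions)
  list(cfg = cfg,
       cal = generate_calibration_series(cfg),
       meas = generate_seeded_dataset(cfg))
}

test_that("replicate averaging is the pointwise mean with rms/sqrt(n) noise", {
  cv <- tibble::tibble(time_ms = c(1, 2, 3), ratio = c(0.9, 0.8, 0.7),
                       sigma = c(0.02, 0.02, 0.02))
  same <- average_replicates(list(cv, cv))
  expect_equal(same$ratio, cv$ratio)
  expect_equal(same$sigma, cv$sigma / sqrt(2))
  two <- average_replicates(list(
    tibble::tibble(time_ms = 1:3, ratio = rep(0.8, 3)),
    tibble::tibble(time_ms = 1:3, ratio = rep(0.6, 3))))
  expect_equal(two$ratio, rep(0.7, 3))
  expect_error(average_replicates(list(
    cv, tibble::tibble(time_ms = c(1, 2), ratio = c(1, 1)))), "grid")
})

test_that("interpolation is exact at the calibration endpoints and midpoint", {
  s <- make_noiseless_set()
  lo <- dplyr::filter(s$cal, fraction == 0.3)
  hi <- dplyr::filter(s$cal, fraction == 0.4)
  est_lo <- interpolate_probability(lo, s$cal, 0.3, 0.4)
  expect_equal(est_lo$p, 0.3, tolerance = 1e-12)
  est_hi <- interpolate_probability(hi, s$cal, 0.3, 0.4)
  expect_equal(est_hi$p, 0.4, tolerance = 1e-12)
  mid <- tibble::tibble(time_ms = lo$time_ms, ratio = (lo$ratio + hi$ratio) / 2)
  est_mid <- interpolate_probability(mid, s$cal, 0.3, 0.4)
  expect_equal(est_mid$p, 0.35, tolerance = 1e-12)
  expect_equal(est_mid$n_points, 18)
})

test_that("noiseless curves generated at intermediate fractions are recovered", {
  # background switched off so bare forward-model curves match the family
  cfg <- noiseless_config(nat_abund_anchor = c(ratio = 1, t_ms = 25))
  cal <- generate_calibration_series(cfg)
  g <- cfg$geometry
  for (truth in c(0.32, 0.35, 0.38)) {
    mc <- mixture_curve(truth, g, cfg$times_ms, cnc_radius = cfg$cnc_radius)
    est <- interpolate_probability(mc, cal, 0.3, 0.4)
    expect_equal(est$p, truth, tolerance = 0.005)
  }
  # recovered p is monotone in the generating fraction
  rec <- sapply(seq(0.31, 0.39, by = 0.02), function(f) {
    mc <- mixture_curve(f, g, cfg$times_ms, cnc_radius = cfg$cnc_radius)
    interpolate_probability(mc, cal, 0.3, 0.4)$p
  })
  expect_true(all(diff(rec) > 0))
})

test_that("degenerate calibration points are excluded and spans are policed", {
  tg <- c(8, 10, 12)
  cal <- dplyr::bind_rows(
    tibble::tibble(fraction = 0.3, time_ms = tg, ratio = c(0.9, 0.8, 0.7)),
    tibble::tibble(fraction = 0.4, time_ms = tg, ratio = c(0.9, 0.7, 0.6)))
  meas <- tibble::tibble(time_ms = tg, ratio = c(0.9, 0.75, 0.65))
  expect_warning(est <- interpolate_probability(meas, cal, 0.3, 0.4,
                                                window = c(8, 12)),
                 "excluded")
  expect_equal(est$n_points, 2)
  expect_equal(est$p, 0.35, tolerance = 1e-12)
  # every point coincident -> error
  flat <- dplyr::mutate(cal, ratio = 0.8)
  expect_error(suppressWarnings(
    interpolate_probability(meas, flat, 0.3, 0.4, window = c(8, 12))),
    "coincident")
  # measured far outside the bracket -> advice to widen
  s <- make_noiseless_set()
  far <- mixture_curve(0.7, s$cfg$geometry, s$cfg$times_ms,
                       cnc_radius = s$cfg$cnc_radius)
  expect_error(interpolate_probability(far, s$cal, 0.3, 0.4), "wider")
})

test_that("error propagation reduces to the constant-gap closed form", {
  n <- 18
  expect_equal(propagate_error(rep(0, n), rep(0, n), rep(0, n),
                               rep(0.8, n), rep(0.9, n), rep(0.7, n)), 0)
  # only measured-curve noise over a constant gap d: err = gap_pp * eps / d
  eps <- 0.004
  d <- 0.05
  err <- propagate_error(rep(eps, n), rep(0, n), rep(0, n),
                         measured = rep(0.8, n), low = rep(0.85, n),
                         high = rep(0.85 - d, n))
  expect_equal(err, 10 * eps / d / 100, tolerance = 1e-12)
})

test_that("propagated errors track per-point Monte-Carlo SDs within 25%", {
  g <- default_spin_geometry()
  tg <- default_time_grid()
  win <- tg[tg >= 8 & tg <= 25]
  bg <- exp(-nat_abund_rate_from_anchor() * (win / 1000)^2)
  truth <- function(f) mixture_curve(f, g, win, cnc_radius = 5.5)$ratio * bg
  m0 <- truth(0.37)
  l0 <- truth(0.30)
  h0 <- truth(0.40)
  withr::with_seed(2024, {
    for (snr in c(5000, 10000, 20000)) {
      eps <- sqrt(2) / snr
      nrep <- 500
      sd_pt <- vapply(seq_along(win), function(i) {
        dm <- rnorm(nrep, 0, eps)
        dl <- rnorm(nrep, 0, eps)
        dh <- rnorm(nrep, 0, eps)
        p_i <- oracle_interp(m0[i] + dm, l0[i] + dl, h0[i] + dh, 30, 40)
        sd(p_i) / 100
      }, 0)
      mc <- sqrt(mean(sd_pt^2))
      analytic <- propagate_error(rep(eps, length(win)), rep(eps, length(win)),
                                  rep(eps, length(win)), m0, l0, h0)
      expect_lt(abs(analytic / mc - 1), 0.25)
    }
  })
})

test_that("the full-dataset estimator recovers the generating probabilities", {
  s <- make_noiseless_set()
  fit <- estimate_full_dataset(s$meas, s$cal)
  expect_equal(fit$probabilities$p43, 0.37, tolerance = 0.01)
  expect_equal(fit$probabilities$p34, 0.56, tolerance = 0.01)
  expect_equal(fit$descriptors$chi4, 0.56 / 0.93, tolerance = 0.01)
  expect_equal(fit$descriptors$Q, 0.7475, tolerance = 0.02)
  td <- tidy(fit)
  expect_identical(td$term, c("p43", "p34", "chi4", "Q"))
  expect_equal(glance(fit)$n_points, 36)
  # symmetric truth
  cfg2 <- noiseless_config(p43 = 0.5, p34 = 0.5)
  fit2 <- estimate_full_dataset(
    generate_seeded_dataset(cfg2), generate_calibration_series(cfg2),
    brackets = list("4N3C" = c(0.4, 0.6), "3N4C" = c(0.4, 0.6)))
  expect_equal(fit2$descriptors$chi4, 0.5, tolerance = 0.01)
  expect_equal(fit2$descriptors$Q, 1, tolerance = 0.05)
})

test_that("swapping which isoform carries 15N swaps the recovered probabilities", {
  cfg_a <- noiseless_config()
  cfg_b <- noiseless_config(p43 = cfg_a$p34, p34 = cfg_a$p43)
  fit_a <- estimate_full_dataset(generate_seeded_dataset(cfg_a),
                                 generate_calibration_series(cfg_a))
  fit_b <- estimate_full_dataset(
    generate_seeded_dataset(cfg_b), generate_calibration_series(cfg_b),
    brackets = list("4N3C" = c(0.50, 0.60), "3N4C" = c(0.30, 0.40)))
  expect_equal(fit_b$probabilities$p43, fit_a$probabilities$p34, tolerance = 1e-9)
  expect_equal(fit_b$probabilities$p34, fit_a$probabilities$p43, tolerance = 1e-9)
})

test_that("reported error bars are conservative but cover the truth", {
  runs <- 200
  ests <- matrix(NA_real_, runs, 2)
  errs <- matrix(NA_real_, runs, 2)
  for (s in seq_len(runs)) {
    cfg <- synthesis_config(seed = 10000 + s)
    fit <- estimate_full_dataset(generate_seeded_dataset(cfg),
                                 generate_calibration_series(cfg))
    ests[s, ] <- c(fit$probabilities$p43, fit$probabilities$p34)
    errs[s, ] <- c(fit$probabilities$p43_err, fit$probabilities$p34_err)
  }
  cover43 <- mean(abs(ests[, 1] - 0.37) <= errs[, 1])
  cover34 <- mean(abs(ests[, 2] - 0.56) <= errs[, 2])
  expect_gte(cover43, 0.60)
  expect_gte(cover34, 0.60)
  # the window-rms error is conservative relative to the scatter of the mean
  expect_gte(median(errs[, 1]), sd(ests[, 1]))
  expect_gte(median(errs[, 2]), sd(ests[, 2]))
})

test_that("intensity-ratio quantification is exact arithmetic", {
  expect_equal(fraction_from_intensities(1, 1)$fraction, 0.5)
  expect_equal(fraction_from_intensities(1.5, 1.0)$fraction, 0.6)
  expect_equal(fraction_from_intensities(1, 1)$err, 0.03)
  # constructed inverse: intensities built from chi4 = 0.62 recover it exactly
  chi4 <- 0.62
  r_C <- chi4 / 0.5
  r_N <- (1 - chi4) / 0.5
  expect_equal(fraction_from_intensities(r_C, r_N)$fraction, chi4)
  expect_error(fraction_from_intensities(-1, 1), "positive")
})
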