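test_that("second moment matches hand arithmetic and is additive", {
  expect_equal(second_moment(numeric(0)), 0)
  expect_equal(second_moment(4.1), (3000 / 4.1^3)^2 / 5, tolerance = 1e-12)
  expect_equal(second_moment(c(3.9, 3.9)), 2 * second_moment(3.9), tolerance = 1e-12)
  expect_equal(second_moment(c(4.1, 5.2)),
               second_moment(4.1) + second_moment(5.2), tolerance = 1e-12)
  expect_error(second_moment(c(4, -1)), "positive")
})

test_that("Gaussian dephasing has the right limits, scaling, and small-t expansion", {
  expect_equal(gaussian_dephasing(0, c(0, 0.01, 0.025)), rep(1, 3))
  expect_equal(gaussian_dephasing(379, 0.025),
               exp(-4 * 379 * 0.025^2 / (3 * pi^2)), tolerance = 1e-12)
  expect_equal(round(gaussian_dephasing(379, 0.025), 4), 0.9685)
  # depends on M2 t^2 only
  expect_equal(gaussian_dephasing(400, 0.01), gaussian_dephasing(1600, 0.005))
  # monotone nonincreasing, 1 at t = 0
  g <- gaussian_dephasing(800, seq(0, 0.025, length.out = 50))
  expect_equal(g[1], 1)
  expect_true(all(diff(g) <= 0))
  # single weak coupling: quadratic expansion correct to second order
  m2 <- second_moment(8.0)
  t <- seq(0, 0.025, length.out = 20)
  x <- 4 * m2 * t^2 / (3 * pi^2)
  expect_lt(max(abs(gaussian_dephasing(m2, t) - (1 - x))), max(x^2) / 2 + 1e-15)
})

test_that("packing-mode weights are the binomial products and always sum to 1", {
  expect_equal(unname(packing_mode_weights(0)), c(1, 0, 0, 0))
  expect_equal(unname(packing_mode_weights(0.5)), rep(0.25, 4))
  expect_equal(unname(packing_mode_weights(0.3)), c(0.49, 0.21, 0.21, 0.09))
  for (p in seq(0, 1, by = 0.05)) {
    expect_equal(sum(packing_mode_weights(p)), 1, tolerance = 1e-14)
  }
})

test_that("mixture curves collapse to the expected limits and order by 13C fraction", {
  g <- default_spin_geometry()
  tg <- default_time_grid()
  expect_length(tg, 28)
  expect_equal(sum(tg >= 8 & tg <= 25), 18)
  # no labeled neighbours: no dephasing
  expect_equal(mixture_curve(0, g, tg)$ratio, rep(1, length(tg)))
  # one-sided geometry at pNC = 1 reduces to the succeeding-side Gaussian
  g1 <- spin_geometry(g$distances_succeeding, numeric(0))
  expect_equal(mixture_curve(1, g1, tg)$ratio,
               gaussian_dephasing(second_moment(g$distances_succeeding), tg / 1000),
               tolerance = 1e-12)
  # pointwise ordering: higher labeled fraction dephases faster
  fr <- seq(0.1, 0.7, by = 0.1)
  curves <- sapply(fr, function(f) mixture_curve(f, g, tg, cnc_radius = 5.5)$ratio)
  for (j in seq_len(ncol(curves) - 1)) {
    expect_true(all(curves[tg > 0, j + 1] < curves[tg > 0, j]))
  }
  # monotone in mixing time
  expect_true(all(apply(curves, 2, function(cv) all(diff(cv) <= 0))))
})

test_that("the C-N-C radius override prunes only the two-sided mode", {
  g <- default_spin_geometry()
  tg <- default_time_grid()
  full <- mixture_curve(0.5, g, tg)
  pruned <- mixture_curve(0.5, g, tg, cnc_radius = 5.5)
  # pruning removes couplings, so the pruned curve dephases less
  expect_true(all(pruned$ratio[-1] >= full$ratio[-1]))
  # the pruned C-N-C second moment equals the truncated-list sum
  m2p <- second_moment(c(g$distances_succeeding[g$distances_succeeding <= 5.5],
                         g$distances_preceding[g$distances_preceding <= 5.5]))
  w <- packing_mode_weights(0.5)
  manual <- w[["NNN"]] +
    w[["NNC"]] * gaussian_dephasing(second_moment(g$distances_succeeding), tg / 1000) +
    w[["CNN"]] * gaussian_dephasing(second_moment(g$distances_preceding), tg / 1000) +
    w[["CNC"]] * gaussian_dephasing(m2p, tg / 1000)
  expect_equal(pruned$ratio, manual, tolerance = 1e-14)
})

test_that("natural-abundance division is an exact inverse with quotient-rule noise", {
  tg <- default_time_grid()
  bg <- nat_abund_curve(tg)
  expect_equal(bg$ratio[tg == 25], 0.84, tolerance = 1e-12)
  ideal <- mixture_curve(0.4, default_spin_geometry(), tg)
  observed <- tibble::tibble(time_ms = tg, ratio = ideal$ratio * bg$ratio)
  corrected <- natural_abundance_correct(observed, bg)
  expect_equal(corrected$ratio, ideal$ratio, tolerance = 1e-12)
  # self-division gives exactly 1
  self <- natural_abundance_correct(observed, observed)
  expect_equal(self$ratio, rep(1, length(tg)))
  # quotient rule on sigmas
  a <- tibble::tibble(time_ms = c(1, 2), ratio = c(0.8, 0.6), sigma = c(0.02, 0.02))
  b <- tibble::tibble(time_ms = c(1, 2), ratio = c(0.9, 0.8), sigma = c(0.01, 0.01))
  cc <- natural_abundance_correct(a, b)
  expect_equal(cc$sigma[1],
               (0.8 / 0.9) * sqrt((0.02 / 0.8)^2 + (0.01 / 0.9)^2), tolerance = 1e-12)
  expect_error(natural_abundance_correct(a, b[1, ]), "grid")
  bad <- tibble::tibble(time_ms = c(1, 2), ratio = c(0.9, 0))
  expect_error(natural_abundance_correct(a, bad), "> 0")
})
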