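test_that("corner frequencies follow the capacitor-matching conditions", {
  cp <- circuit_params(R_s = 1, R_ct = 100, C_dl = 1e-3, R = 150,
                       R_1 = 10, C = 2e-9, C_1 = 5e-13)
  lad <- corner_frequencies(cp)
  expect_equal(lad$omega_12, 1 / (1e-3 * 111), tolerance = 1e-12)
  expect_equal(lad$omega_12, 9.009009, tolerance = 1e-6)
  expect_equal(lad$omega_23, 1 / (1e-3 * 11), tolerance = 1e-12)
  expect_equal(lad$omega_34, 1 / (2e-9 * 160), tolerance = 1e-12)
  expect_equal(lad$omega_45, 1 / (2e-9 * 150), tolerance = 1e-12)
  rpar <- 10 * 150 / 160
  expect_equal(lad$omega_56, 1 / (5e-13 * rpar), tolerance = 1e-12)
  expect_equal(lad$omega_67, (1 + rpar) / (5e-13 * rpar * 1),
               tolerance = 1e-12)
  expect_equal(unlist(lad[7:10]),
               c(plateau_1 = 111, plateau_3 = 11,
                 plateau_5 = 1 + rpar, plateau_7 = 1), tolerance = 1e-12)
  # medium-only ladder: cell entries undefined
  lm <- corner_frequencies(as_medium_params(cp))
  expect_true(is.na(lm$omega_34) && is.na(lm$omega_45) &&
                is.na(lm$plateau_5))
  expect_equal(lm$omega_56, 1 / (5e-13 * 10), tolerance = 1e-12)
})

test_that("corners sit at the 3 dB deviations of the exact spectrum", {
  # all six corners mutually >= 3 decades apart, which needs tiny k and p:
  # the pole-zero gap within each dispersion is set by resistance ratios
  cp <- circuit_params(R_s = 1e-4, R_ct = 1e6, C_dl = 1e-4, R = 0.1,
                       R_1 = 100, C = 1e-9, C_1 = 1e-15)
  lad <- corner_frequencies(cp)
  expect_true(lad$well_separated)
  expect_true(all(diff(log10(unlist(lad[1:6]))) >= 3))
  cases <- list(list(lad$omega_12, lad$plateau_1, FALSE),
                list(lad$omega_23, lad$plateau_3, TRUE),
                list(lad$omega_34, lad$plateau_3, FALSE),
                list(lad$omega_45, lad$plateau_5, TRUE),
                list(lad$omega_56, lad$plateau_5, FALSE),
                list(lad$omega_67, lad$plateau_7, TRUE))
  for (cs in cases) {
    lw <- corner_3db_crossing(cp, plateau = cs[[2]],
                              omega_expected = cs[[1]], above = cs[[3]])
    expect_lt(abs(10^lw / cs[[1]] - 1), 0.05)
  }
})

test_that("bilinear dispersion phase depth and peak location", {
  expect_equal(min_phase(5, 5), 0)
  expect_equal(min_phase(1, 2), -19.47122, tolerance = 1e-6)
  expect_equal(min_phase(1e-12, 1), -90, tolerance = 1e-4)
  expect_error(min_phase(2, 1), "omega_pole")
  expect_equal(peak_frequency(1, 1), 1)
  expect_equal(peak_frequency(10, 1000), 100)
  expect_error(peak_frequency(-1, 2), "omega_pole")
  # brute-force argmin of the bilinear phase on a dense log grid
  wp <- 100; wz <- 3.7e4
  w <- 10^seq(0, 7, length.out = 2e5)
  ph <- Arg((1 + 1i * w / wz) / (1 + 1i * w / wp))
  w_min <- w[which.min(ph)]
  expect_equal(peak_frequency(wp, wz), w_min, tolerance = 1e-3)
  expect_equal(min_phase(wp, wz), min(ph) * 180 / pi, tolerance = 1e-6)
})

test_that("phi4 matches its bounds and limits", {
  expect_equal(phi4(1), -19.47122, tolerance = 1e-6)
  expect_gt(phi4(1), -20)                   # practical lower bound, R >= R_1
  expect_equal(phi4(1e-9), -90, tolerance = 1e-4)
  expect_equal(phi4(1e12), 0, tolerance = 1e-4)
  expect_error(phi4(-1), "k")
  # strictly increasing towards 0 with k
  kk <- 10^seq(-3, 3, length.out = 50)
  expect_true(all(diff(phi4(kk)) > 0))
})

test_that("phi6 matches its bounds and limits", {
  expect_equal(phi6(1, 0.01), -74.05763, tolerance = 1e-6)
  expect_lt(phi6(1, 0.01), -74)             # upper bound at k = 1, p = 0.01
  expect_equal(phi6(1, 1e9), 0, tolerance = 1e-3)
  expect_equal(phi6(1, 1e-12), -90, tolerance = 1e-4)
  expect_error(phi6(1, 0), "p")
  pp <- 10^seq(-4, 2, length.out = 50)
  expect_true(all(diff(phi6(2, pp)) > 0))
})

test_that("omega4 is the geometric mean of the cell-branch pole and zero", {
  expect_equal(omega4(1, 1, 1), 1 / sqrt(2), tolerance = 1e-12)
  for (k in c(0.05, 0.3, 1, 4, 50)) {
    R_1 <- 80; C <- 3e-9; R <- k * R_1
    expect_equal(omega4(C, R_1, k),
                 peak_frequency(1 / (C * (R + R_1)), 1 / (C * R)),
                 tolerance = 1e-12)
  }
  expect_equal(omega4(1 / 7, 7 * 3, 2), omega4(1, 3, 2), tolerance = 1e-12)
})

test_that("omega6 approximates the exact region-6 geometric mean at small p", {
  expect_equal(omega6(1, 1, 1, 0.01), 14.0028, tolerance = 1e-4)
  expect_equal(omega6(1 / 7, 7 * 5, 2, 0.02), omega6(1, 5, 2, 0.02),
               tolerance = 1e-12)
  # exact form: sqrt(omega_56 * omega_67); Eq-form converges to it as p -> 0
  expect_equal(omega6(1, 1, 1, 1e-6), omega6_exact(1, 1, 1, 1e-6),
               tolerance = 1e-3)
  expect_equal(omega6_exact(1, 1, 1, 0.01), 14.28286, tolerance = 1e-4)
  cp <- reference_params()
  k <- cp$R / cp$R_1; p <- cp$R_s / cp$R_1
  lad <- corner_frequencies(cp)
  expect_equal(omega6_exact(cp$C_1, cp$R_1, k, p),
               sqrt(lad$omega_56 * lad$omega_67), tolerance = 1e-12)
})

test_that("z5 plateau magnitude and its monotonicity", {
  expect_equal(z5_magnitude(100, 1, 0.01), 51)
  expect_equal(z5_magnitude(100, 1e9, 1e-9), 100, tolerance = 1e-6)
  kk <- seq(0.1, 10, length.out = 30)
  expect_true(all(diff(z5_magnitude(50, kk, 0.02)) > 0))
  pp <- seq(0.001, 0.5, length.out = 30)
  expect_true(all(diff(z5_magnitude(50, 2, pp)) > 0))
})

test_that("phase peaks are capacitance-independent, corners are not", {
  base <- reference_params()
  m0 <- metrics_from_params(base)
  for (scale in 10^seq(-3, 3, by = 2)) {
    cp <- base
    cp$C <- base$C * scale
    cp$C_1 <- base$C_1 * scale
    m <- metrics_from_params(cp)
    expect_equal(m$phi4, m0$phi4, tolerance = 1e-12)
    expect_equal(m$phi6, m0$phi6, tolerance = 1e-12)
    expect_equal(m$f4, m0$f4 / scale, tolerance = 1e-12)
  }
})

test_that("asymptotic Bode skeleton has the seven-region shape", {
  cp <- reference_params()
  bode <- asymptotic_bode(cp)
  expect_equal(nrow(bode), 7)
  expect_equal(bode$slope_db_dec, c(0, -20, 0, -20, 0, -20, 0))
  expect_equal(bode$level_lo_db[1],
               20 * log10(cp$R_s + cp$R_ct + cp$R_1), tolerance = 1e-12)
  expect_equal(asymptotic_bode(as_medium_params(cp))$slope_db_dec,
               c(0, -20, 0, -20, 0))
  # skeleton vs exact magnitude: <= 3.1 dB at corners, <= 0.5 dB at
  # plateau midpoints
  lad <- corner_frequencies(cp)
  corners <- unlist(lad[1:6]) / (2 * pi)
  exact_db <- function(f) 20 * log10(Mod(evaluate_impedance(cp, f)$z))
  gap_corners <- abs(asymptotic_magnitude_db(bode, corners) -
                       exact_db(corners))
  expect_true(all(gap_corners <= 3.1))
  mids <- sqrt(c(corners[2] * corners[3], corners[4] * corners[5]))
  gap_mids <- abs(asymptotic_magnitude_db(bode, mids) - exact_db(mids))
  expect_true(all(gap_mids <= 0.5))
})

test_that("analytic region-4 peak matches the numeric peak of the exact circuit", {
  cp <- reference_params()
  m <- metrics_from_params(cp)
  pk <- numeric_phase_peaks(cp)
  expect_equal(nrow(pk), 3)
  expect_lt(abs(pk$phi_min[2] - m$phi4), 1.5)
  expect_lt(abs(pk$f_peak[2] / m$f4 - 1), 0.15)
})
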