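test_that("detection metrics reproduce hand-computed closed forms", {
  cp <- circuit_params(R_s = 2, R_ct = 4e4, C_dl = 2e-6, R = 240,
                       R_1 = 120, C = 3e-9, C_1 = 4e-12)
  med <- circuit_params(R_s = 2, R_ct = 4e4, C_dl = 2e-6, R_1 = 120,
                        C_1 = 4e-12, cell_branch = FALSE)
  m <- metrics_from_params(cp, medium_reference = med)
  # spreadsheet-style arithmetic, written out independently
  k <- 240 / 120                                   # 2
  p <- 2 / 120
  kf <- k / (k + 1)                                # 2/3
  expect_equal(m$k, 2)
  expect_equal(m$p, 1 / 60)
  expect_equal(m$phi4,
               (atan(sqrt(2 / 3)) - atan(sqrt(3 / 2))) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(m$f4, (1 / (3e-9 * 120)) * sqrt(1 / 6) / (2 * pi),
               tolerance = 1e-12)
  expect_equal(m$phi6,
               (atan(sqrt(p / (p + kf))) - atan(sqrt((p + kf) / p))) *
                 180 / pi, tolerance = 1e-12)
  expect_equal(m$f6,
               (1 / (4e-12 * 120)) * sqrt(1 / (p * (p + kf))) / (2 * pi),
               tolerance = 1e-12)
  expect_equal(m$z5, 120 * (p + kf), tolerance = 1e-12)
  expect_equal(m$d, 120 * (p + kf) / 122, tolerance = 1e-12)
})

test_that("k is scale-free and d is 1 against a matching region-5 level", {
  for (scale in c(1, 13, 400)) {
    cp <- circuit_params(1 * scale, 100 * scale, 1e-6 / scale,
                         R = 70 * scale, R_1 = 70 * scale,
                         C = 2e-9 / scale, C_1 = 5e-13 / scale)
    m <- metrics_from_params(cp)
    expect_equal(m$k, 1)
  }
  cp <- reference_params()
  m <- metrics_from_params(cp, medium_z5 = z5_magnitude(
    cp$R_1, cp$R / cp$R_1, cp$R_s / cp$R_1))
  expect_equal(m$d, 1)
  expect_error(metrics_from_params(as_medium_params(cp)), "cell branch")
})

test_that("phase-peak finding: resistor, single dispersion, full circuit", {
  f <- log_freq_grid(10, 1e8, 12)
  flat <- impedance_spectrum(f, complex(real = rep(50, length(f)),
                                        imaginary = rep(-1e-9, length(f))))
  expect_equal(nrow(find_phase_peaks(flat)), 0)
  # single bilinear dispersion with known pole/zero
  wp <- 2 * pi * 1e3; wz <- 2 * pi * 1e5
  z <- 50 * (1 + 1i * 2 * pi * f / wz) / (1 + 1i * 2 * pi * f / wp)
  pk <- find_phase_peaks(impedance_spectrum(f, z))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$phi_min, min_phase(wp, wz), tolerance = 0.01)
  expect_equal(pk$f_peak, peak_frequency(wp, wz) / (2 * pi),
               tolerance = 0.01)
  # full circuit: exactly three negative-phase dispersions
  cp <- reference_params()
  sp <- evaluate_impedance(cp, log_freq_grid(points_per_decade = 20))
  pk <- find_phase_peaks(sp)
  m <- metrics_from_params(cp)
  expect_equal(nrow(pk), 3)
  expect_lt(abs(pk$phi_min[2] - m$phi4), 1.5)
  expect_lt(abs(pk$phi_min[3] - m$phi6), 1.5)
  # band restriction and empty band
  expect_equal(nrow(find_phase_peaks(sp, band = c(1e3, 1e7))), 1)
  expect_equal(nrow(find_phase_peaks(sp, band = c(1, 2))), 0)
})

test_that("delta_phi4 compares series on a shared concentration ladder", {
  mk <- function(phi4s) suspension_series(
    "X", "Y", seq_along(phi4s), metrics = data.frame(phi4 = phi4s))
  a <- mk(c(-30, -40))
  b <- mk(c(-33, -48))
  expect_equal(delta_phi4(a, b)$delta_phi4, c(3, 8))
  expect_equal(delta_phi4(a, a)$delta_phi4, c(0, 0))
  c3 <- mk(c(-1, -2, -3))
  expect_error(delta_phi4(a, c3), "ladder")
})

test_that("a media change grows delta_phi4 with concentration", {
  cc <- c(0.2, 0.5, 1)
  quiet <- function(pr) {
    pr$agglomeration_cv <- 0; pr$noise_mag_cv <- 0
    pr$noise_phase_sd_deg <- 0; pr
  }
  ms <- generate_series(quiet(preset("MSK8", "MS")), cc, seed = 3)
  pb <- generate_series(quiet(preset("MSK8", "PB")), cc, seed = 3)
  dp <- delta_phi4(ms, pb)
  expect_true(all(diff(dp$delta_phi4) > 0))
})

test_that("sensitivity curve: limits, medium conductivity, monotonicity", {
  R_1 <- 100; p <- 0.01
  ref <- R_1 * (p + 1)                  # cell-free region-5 level
  kk <- 10^seq(-2, 4, length.out = 40)
  curve <- sensitivity_curve(p, kk, medium_z5 = ref, R_1 = R_1)
  expect_true(all(curve$d < 1))
  expect_equal(curve$d[length(kk)], 1, tolerance = 1e-3)
  expect_true(all(diff(curve$d) > 0))
  # higher-conductivity medium reference (halved R_1, doubled p): every d
  # moves closer to 1, i.e. smaller deviation
  p2 <- 2 * p
  curve2 <- sensitivity_curve(p2, kk, medium_z5 = (R_1 / 2) * (p2 + 1),
                              R_1 = R_1 / 2)
  expect_true(all(abs(1 - curve2$d) < abs(1 - curve$d)))
  expect_error(sensitivity_curve(-1, kk, ref, R_1), "p")
})
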