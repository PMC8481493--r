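# Independent oracle: compose the two circuit blocks impedance-by-impedance
# with explicit series/parallel steps (a different route than the package's
# admittance-sum evaluation).
series_z <- function(...) Reduce(`+`, list(...))
parallel_z <- function(a, b) (a * b) / (a + b)

oracle_impedance <- function(params, f) {
  w <- 2 * pi * f
  jw <- 1i * w
  z_cdl <- 1 / (params$C_dl * jw^params$alpha_dl)
  randles <- series_z(params$R_s, parallel_z(params$R_ct, z_cdl))
  z_c1 <- 1 / (jw * params$C_1)
  debye <- if (params$cell_branch) {
    cell <- series_z(params$R, 1 / (jw * params$C))
    parallel_z(parallel_z(params$R_1, cell), z_c1)
  } else {
    parallel_z(params$R_1, z_c1)
  }
  series_z(randles, debye)
}

# textbook parameter set with the dispersion groups ~3 decades apart
reference_params <- function() {
  circuit_params(R_s = 1, R_ct = 2e4, C_dl = 1e-6,
                 R = 150, R_1 = 100, C = 5e-10, C_1 = 2e-12)
}

# random parameter set with the three dispersions centred ~3 decades apart
# and R_s orders of magnitude below R_1 (the regime where the closed-form
# peak expressions hold)
random_separated_params <- function() {
  R_1 <- 10^stats::runif(1, 1.7, 2.7)
  k <- 10^stats::runif(1, -0.3, 0.7)
  p <- 10^stats::runif(1, -3, log10(0.02))
  R_s <- p * R_1
  R <- k * R_1
  R_ct <- R_1 * 10^stats::runif(1, 1.5, 2.5)
  omega_23 <- 10^stats::runif(1, 2.9, 3.5)
  C_dl <- 1 / (omega_23 * (R_s + R_1))
  omega_34 <- omega_23 * 10^stats::runif(1, 2.7, 3.3)
  C <- 1 / (omega_34 * (R + R_1))
  Rpar <- R_1 * R / (R_1 + R)
  omega_56 <- omega_34 * 10^stats::runif(1, 2.7, 3.3) * (1 + 1 / k)
  C_1 <- 1 / (omega_56 * Rpar)
  circuit_params(R_s = R_s, R_ct = R_ct, C_dl = C_dl, R = R, R_1 = R_1,
                 C = C, C_1 = C_1)
}

# numeric phase minima of the exact circuit on a dense log grid,
# highest-frequency peaks last
numeric_phase_peaks <- function(params, f_min = 1e-2, f_max = 1e12,
                                points_per_decade = 40) {
  sp <- evaluate_impedance(params,
                           log_freq_grid(f_min, f_max, points_per_decade))
  find_phase_peaks(sp)
}

# frequency at which exact |Z| crosses a 3 dB offset from a plateau,
# searched within a bracket around an expected corner (rad/s in, rad/s out)
corner_3db_crossing <- function(params, plateau, omega_expected,
                                above = FALSE) {
  target <- plateau * if (above) sqrt(2) else 1 / sqrt(2)
  g <- function(lw) {
    f <- 10^lw / (2 * pi)
    Mod(evaluate_impedance(params, f)$z) - target
  }
  lw0 <- log10(omega_expected)
  stats::uniroot(g, c(lw0 - 1.2, lw0 + 1.2), tol = 1e-10)$root
}
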