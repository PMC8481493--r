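#' Pole/zero ladder of the seven-region Bode skeleton
#'
#' For an ideal double layer (`alpha_dl = 1`) the circuit's magnitude
#' spectrum splits into seven regions separated by three pole/zero pairs,
#' one per capacitor. Each corner is the angular frequency at which a
#' capacitor's impedance matches the resistance it shunts:
#' \describe{
#'   \item{omega_12}{`1 / (C_dl (R_s + R_ct + R_1))` — pole of the largest
#'     capacitor against the region-1 plateau.}
#'   \item{omega_23}{`1 / (C_dl (R_s + R_1))` — zero where the double-layer
#'     impedance becomes negligible against `R_s + R_1`.}
#'   \item{omega_34}{`1 / (C (R + R_1))` — pole of the cell capacitance.}
#'   \item{omega_45}{`1 / (C R)` — zero where the cell branch is governed
#'     by R.}
#'   \item{omega_56}{`1 / (C_1 (R_1 || R))` — pole of the water-polarization
#'     capacitance shunting the Debye resistances.}
#'   \item{omega_67}{`(R_s + R_1 || R) / (C_1 (R_1 || R) R_s)` — zero where
#'     only `R_s` remains.}
#' }
#' The four plateau levels are `R_s + R_ct + R_1` (region 1), `R_s + R_1`
#' (region 3), `R_s + R_1 || R` (region 5) and `R_s` (region 7). For a
#' medium-only circuit the cell corners and the region-5 plateau are
#' returned as `NA` and `omega_56`, `omega_67` use `R_1` alone.
#'
#' @param params A [circuit_params()] with `alpha_dl = 1`.
#' @return A list of class `pole_zero_ladder` with elements `omega_12` ...
#'   `omega_67` (rad/s), `plateau_1`, `plateau_3`, `plateau_5`, `plateau_7`
#'   (ohm), and `well_separated` (logical: all adjacent defined corners at
#'   least `10^2.5` apart; the closed-form peak expressions degrade below
#'   that).
#' @export
corner_frequencies <- function(params) {
  validate_circuit_params(params)
  if (params$alpha_dl != 1)
    stop("closed-form corner frequencies require alpha_dl = 1",
         call. = FALSE)
  Rs <- params$R_s; Rct <- params$R_ct; R1 <- params$R_1
  Cdl <- params$C_dl; C1 <- params$C_1
  if (params$cell_branch) {
    R <- params$R; C <- params$C
    Rpar <- R1 * R / (R1 + R)
    o34 <- 1 / (C * (R + R1))
    o45 <- 1 / (C * R)
    p5 <- Rs + Rpar
  } else {
    Rpar <- R1
    o34 <- NA_real_
    o45 <- NA_real_
    p5 <- NA_real_
  }
  ladder <- structure(list(
    omega_12 = 1 / (Cdl * (Rs + Rct + R1)),
    omega_23 = 1 / (Cdl * (Rs + R1)),
    omega_34 = o34,
    omega_45 = o45,
    omega_56 = 1 / (C1 * Rpar),
    omega_67 = (Rs + Rpar) / (C1 * Rpar * Rs),
    plateau_1 = Rs + Rct + R1,
    plateau_3 = Rs + R1,
    plateau_5 = p5,
    plateau_7 = Rs), class = "pole_zero_ladder")
  # separation between dispersion groups (not between the pole and zero of
  # one dispersion, whose ratio is fixed by the resistances)
  gaps <- if (params$cell_branch)
    c(ladder$omega_34 / ladder$omega_23, ladder$omega_56 / ladder$omega_45)
  else ladder$omega_56 / ladder$omega_23
  ladder$well_separated <- all(log10(gaps) >= 2.5)
  ladder
}

#' @export
print.pole_zero_ladder <- function(x, ...) {
  cat("<pole_zero_ladder>",
      if (!isTRUE(x$well_separated)) " [corners not well separated]",
      "\n", sep = "")
  o <- unlist(x[1:6])
  cat("  corners (rad/s): ",
      paste(names(o), formatC(o, digits = 4, format = "g"),
            sep = " = ", collapse = ", "), "\n", sep = "")
  p <- unlist(x[7:10])
  cat("  plateaus (ohm):  ",
      paste(names(p), formatC(p, digits = 4, format = "g"),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Minimum phase of a single bilinear dispersion
#'
#' A dispersion `(1 + j*omega/omega_zero) / (1 + j*omega/omega_pole)` with
#' the pole below the zero has a bell-shaped negative phase on a log axis.
#' Its minimum is
#' `arctan(sqrt(omega_pole/omega_zero)) - arctan(sqrt(omega_zero/omega_pole))`,
#' attained at the geometric mean of pole and zero.
#'
#' @param omega_pole,omega_zero Angular frequencies, rad/s, with
#'   `omega_pole <= omega_zero`.
#' @return Phase minimum in degrees (in `[-90, 0]`).
#' @examples
#' min_phase(1, 2)   # -19.47 deg
#' @export
min_phase <- function(omega_pole, omega_zero) {
  check_positive(omega_pole, "omega_pole")
  check_positive(omega_zero, "omega_zero")
  if (any(omega_pole > omega_zero))
    stop("omega_pole must not exceed omega_zero", call. = FALSE)
  bilinear_min_phase(omega_pole / omega_zero)
}

# phase depth of a bilinear dispersion from the pole/zero ratio r <= 1
bilinear_min_phase <- function(r) {
  (atan(sqrt(r)) - atan(sqrt(1 / r))) * 180 / pi
}

#' Peak frequency of a bilinear dispersion
#'
#' @inheritParams min_phase
#' @return The geometric mean `sqrt(omega_pole * omega_zero)`, rad/s.
#' @export
peak_frequency <- function(omega_pole, omega_zero) {
  check_positive(omega_pole, "omega_pole")
  check_positive(omega_zero, "omega_zero")
  sqrt(omega_pole * omega_zero)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0))
    stop("'", field, "' must be finite and strictly positive", call. = FALSE)
  invisible(x)
}

#' Phase-peak depths and frequencies in terms of the resistance ratios
#'
#' With `k = R / R_1` (cells vs solution) and `p = R_s / R_1` (series vs
#' solution) the two high-frequency phase peaks have closed forms that are
#' independent of the capacitances:
#' \itemize{
#'   \item `phi4(k) = arctan(sqrt(k/(k+1))) - arctan(sqrt((k+1)/k))`
#'   \item `phi6(k, p) = arctan(sqrt(p/(p+k/(k+1)))) -
#'     arctan(sqrt((p+k/(k+1))/p))`
#'   \item `omega4(C, R_1, k) = (1/(C R_1)) sqrt(1/(k (k+1)))`
#'   \item `omega6(C_1, R_1, k, p) = (1/(C_1 R_1)) sqrt(1/(p (p+k/(k+1))))`
#'     (the small-p form of the exact geometric mean, see
#'     [omega6_exact()])
#'   \item `z5_magnitude(R_1, k, p) = R_1 (p + k/(k+1))` — the region-5
#'     plateau.
#' }
#' `phi4` is bounded below by about -20 degrees once `R >= R_1` (k >= 1)
#' and tends to -90 degrees as k tends to 0; `phi6` is close to -90 degrees
#' whenever `R_s` is orders of magnitude below `R_1`.
#'
#' @param k Ratio `R / R_1`, dimensionless, > 0. Vectorized.
#' @param p Ratio `R_s / R_1`, dimensionless, > 0. Vectorized.
#' @param C,C_1 Capacitances, farad.
#' @param R_1 Solution resistance, ohm.
#' @return `phi4`, `phi6`: degrees; `omega4`, `omega6`: rad/s;
#'   `z5_magnitude`: ohm.
#' @examples
#' phi4(1)          # about -19.5 deg: the practical lower bound
#' phi6(1, 0.01)    # about -74 deg
#' @export
phi4 <- function(k) {
  check_positive(k, "k")
  bilinear_min_phase(k / (k + 1))
}

#' @rdname phi4
#' @export
phi6 <- function(k, p) {
  check_positive(k, "k")
  check_positive(p, "p")
  bilinear_min_phase(p / (p + k / (k + 1)))
}

#' @rdname phi4
#' @export
omega4 <- function(C, R_1, k) {
  check_positive(C, "C"); check_positive(R_1, "R_1"); check_positive(k, "k")
  (1 / (C * R_1)) * sqrt(1 / (k * (k + 1)))
}

#' @rdname phi4
#' @export
omega6 <- function(C_1, R_1, k, p) {
  check_positive(C_1, "C_1"); check_positive(R_1, "R_1")
  check_positive(k, "k"); check_positive(p, "p")
  (1 / (C_1 * R_1)) * sqrt(1 / (p * (p + k / (k + 1))))
}

#' Exact region-6 peak frequency
#'
#' Geometric mean of the exact region-6 pole and zero,
#' `sqrt(omega_56 * omega_67)`; [omega6()] is its small-p approximation and
#' the published interface, this form serves as the internal oracle.
#'
#' @inheritParams phi4
#' @return Angular frequency, rad/s.
#' @export
omega6_exact <- function(C_1, R_1, k, p) {
  check_positive(C_1, "C_1"); check_positive(R_1, "R_1")
  check_positive(k, "k"); check_positive(p, "p")
  kf <- k / (k + 1)
  sqrt((1 / (C_1 * R_1 * kf)) * (p + kf) / (C_1 * R_1 * kf * p))
}

#' @rdname phi4
#' @export
z5_magnitude <- function(R_1, k, p) {
  check_positive(R_1, "R_1"); check_positive(k, "k"); check_positive(p, "p")
  R_1 * (p + k / (k + 1))
}

#' Piecewise-linear asymptotic Bode magnitude skeleton
#'
#' The seven-region straight-line approximation of `20*log10 |Z|`: flat
#' plateaus in regions 1, 3, 5 and 7, and -20 dB/decade roll-offs in
#' regions 2, 4 and 6, with breakpoints at the ladder corners. For a
#' medium-only circuit regions 3-5 merge and five segments are returned.
#'
#' @param params A [circuit_params()] with `alpha_dl = 1`.
#' @param f_min,f_max Band edges, Hz, for the outermost segments.
#' @return A `data.frame` with one row per region: `region`,
#'   `slope_db_dec`, `f_lo`, `f_hi` (Hz), `level_lo_db`, `level_hi_db`
#'   (dB-ohm at the segment ends).
#' @export
asymptotic_bode <- function(params, f_min = 4, f_max = 2e10) {
  lad <- corner_frequencies(params)
  if (params$cell_branch) {
    corners <- c(lad$omega_12, lad$omega_23, lad$omega_34, lad$omega_45,
                 lad$omega_56, lad$omega_67) / (2 * pi)
    plateaus <- c(lad$plateau_1, lad$plateau_3, lad$plateau_5, lad$plateau_7)
    regions <- 1:7
  } else {
    corners <- c(lad$omega_12, lad$omega_23, lad$omega_56, lad$omega_67) /
      (2 * pi)
    plateaus <- c(lad$plateau_1, lad$plateau_3, lad$plateau_7)
    regions <- c(1, 2, 3, 6, 7)
  }
  f_lo <- c(min(f_min, corners[1] / 10), corners)
  f_hi <- c(corners, max(f_max, corners[length(corners)] * 10))
  n <- length(regions)
  slope <- rep(c(0, -20), length.out = 2 * length(plateaus) - 1)
  lev_db <- 20 * log10(plateaus)
  level_lo <- level_hi <- numeric(n)
  ip <- 1
  for (i in seq_len(n)) {
    if (slope[i] == 0) {
      level_lo[i] <- level_hi[i] <- lev_db[ip]
    } else {
      level_lo[i] <- lev_db[ip]
      level_hi[i] <- lev_db[ip + 1]
      ip <- ip + 1
    }
  }
  data.frame(region = regions, slope_db_dec = slope, f_lo = f_lo,
             f_hi = f_hi, level_lo_db = level_lo, level_hi_db = level_hi)
}

#' Evaluate the asymptotic skeleton at given frequencies
#'
#' @param bode A data frame from [asymptotic_bode()].
#' @param frequency Frequencies, Hz.
#' @return Approximate `20*log10 |Z|` in dB-ohm.
#' @export
asymptotic_magnitude_db <- function(bode, frequency) {
  validate_freq_grid(frequency)
  out <- numeric(length(frequency))
  for (i in seq_along(frequency)) {
    f <- frequency[i]
    row <- which(bode$f_lo <= f & f <= bode$f_hi)[1]
    if (is.na(row)) row <- if (f < bode$f_lo[1]) 1L else nrow(bode)
    if (bode$slope_db_dec[row] == 0) {
      out[i] <- bode$level_lo_db[row]
    } else {
      frac <- log10(f / bode$f_lo[row]) /
        log10(bode$f_hi[row] / bode$f_lo[row])
      out[i] <- bode$level_lo_db[row] +
        frac * (bode$level_hi_db[row] - bode$level_lo_db[row])
    }
  }
  out
}
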