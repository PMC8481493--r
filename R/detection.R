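#' Detection metrics of a suspension from its circuit parameters
#'
#' Computes the full analytic observable set used to compare suspensions:
#' the resistance ratios `k = R/R_1` and `p = R_s/R_1`, the region-4 and
#' region-6 phase-peak depths and frequencies, the region-5 plateau
#' magnitude, and (when a medium reference is supplied) the deviation
#' `d = |Z|5_suspension / |Z|5_medium`. The medium denominator is the
#' cell-free region-5 level `R_s + R_1` of the reference circuit; pass a
#' measured plateau via `medium_z5` to override it.
#'
#' @param params A [circuit_params()] with the cell branch present.
#' @param medium_reference Optional [circuit_params()] of the cell-free
#'   medium (its cell branch, if present, is ignored).
#' @param medium_z5 Optional measured region-5 magnitude of the medium,
#'   ohm; takes precedence over `medium_reference`.
#' @return A list of class `detection_metrics`: `k`, `p`, `phi4` (deg),
#'   `f4` (Hz), `phi6` (deg), `f6` (Hz), `z5` (ohm), `d` (dimensionless or
#'   `NA`).
#' @examples
#' cp <- circuit_params(1, 2e4, 1e-6, 150, 100, 2e-9, 5e-12)
#' metrics_from_params(cp, medium_reference = as_medium_params(cp))
#' @export
metrics_from_params <- function(params, medium_reference = NULL,
                                medium_z5 = NULL) {
  validate_circuit_params(params)
  if (!params$cell_branch)
    stop("detection metrics are undefined for a medium-only circuit ",
         "(cell branch absent)", call. = FALSE)
  k <- params$R / params$R_1
  p <- params$R_s / params$R_1
  z5 <- z5_magnitude(params$R_1, k, p)
  d <- NA_real_
  if (!is.null(medium_z5)) {
    check_positive(medium_z5, "medium_z5")
    d <- z5 / medium_z5
  } else if (!is.null(medium_reference)) {
    validate_circuit_params(medium_reference)
    d <- z5 / (medium_reference$R_s + medium_reference$R_1)
  }
  structure(list(
    k = k, p = p,
    phi4 = phi4(k),
    f4 = omega4(params$C, params$R_1, k) / (2 * pi),
    phi6 = phi6(k, p),
    f6 = omega6(params$C_1, params$R_1, k, p) / (2 * pi),
    z5 = z5, d = d), class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat("<detection_metrics>\n")
  cat(sprintf("  k = %.4g, p = %.4g\n", x$k, x$p))
  cat(sprintf("  phi4 = %.2f deg at f4 = %.4g Hz\n", x$phi4, x$f4))
  cat(sprintf("  phi6 = %.2f deg at f6 = %.4g Hz\n", x$phi6, x$f6))
  cat(sprintf("  |Z|5 = %.4g ohm, d = %.4g\n", x$z5, x$d))
  invisible(x)
}

#' Locate negative phase peaks in a spectrum
#'
#' Finds local minima of the phase over log-frequency and refines each by
#' a three-point parabolic interpolation in (log10 f, phase). Peaks
#' shallower than `min_depth_deg` are suppressed as noise. A grid of at
#' least 10 points per decade is recommended for reliable refinement.
#'
#' @param spectrum An [impedance_spectrum()].
#' @param band Optional frequency interval `c(f_lo, f_hi)` in Hz restricting
#'   the search; default is the full grid.
#' @param min_depth_deg Minimum depth (degrees below zero) for a minimum to
#'   count as a peak; default 1.
#' @return A `data.frame` with one row per peak, sorted by frequency:
#'   `f_peak`, `phi_min` (refined), `f_grid`, `phi_grid` (raw grid
#'   minimum). Zero rows when no peak qualifies.
#' @export
find_phase_peaks <- function(spectrum, band = NULL, min_depth_deg = 1) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequency
  ph <- spectrum_phase(spectrum)
  keep <- rep(TRUE, length(f))
  if (!is.null(band)) {
    stopifnot(length(band) == 2L, band[1] <= band[2])
    keep <- f >= band[1] & f <= band[2]
  }
  f <- f[keep]; ph <- ph[keep]
  empty <- data.frame(f_peak = numeric(0), phi_min = numeric(0),
                      f_grid = numeric(0), phi_grid = numeric(0))
  n <- length(f)
  if (n < 3L) return(empty)
  mid <- 2:(n - 1L)
  is_min <- ph[mid] < ph[mid - 1L] & ph[mid] <= ph[mid + 1L] &
    ph[mid] < -abs(min_depth_deg)
  idx <- mid[is_min]
  if (length(idx) == 0L) return(empty)
  out <- lapply(idx, function(i) {
    lf <- log10(f[(i - 1L):(i + 1L)])
    y <- ph[(i - 1L):(i + 1L)]
    # vertex of the parabola through the three bracketing points
    denom <- (lf[1] - lf[2]) * (lf[1] - lf[3]) * (lf[2] - lf[3])
    a <- (lf[3] * (y[2] - y[1]) + lf[2] * (y[1] - y[3]) +
            lf[1] * (y[3] - y[2])) / denom
    b <- (lf[3]^2 * (y[1] - y[2]) + lf[2]^2 * (y[3] - y[1]) +
            lf[1]^2 * (y[2] - y[3])) / denom
    if (is.finite(a) && a > 0) {
      lv <- -b / (2 * a)
      cc <- y[2] - a * lf[2]^2 - b * lf[2]
      data.frame(f_peak = 10^lv, phi_min = a * lv^2 + b * lv + cc,
                 f_grid = f[i], phi_grid = ph[i])
    } else {
      data.frame(f_peak = f[i], phi_min = ph[i], f_grid = f[i],
                 phi_grid = ph[i])
    }
  })
  out <- do.call(rbind, out)
  out[order(out$f_peak), , drop = FALSE]
}

#' Per-concentration mean deviation in phi4 between two suspension series
#'
#' The pairwise discriminability statistic: at each shared concentration,
#' the mean absolute difference of the region-4 phase depth between the two
#' series. Aggregating over several pairs of series is an unweighted mean
#' of these per-pair values.
#'
#' @param series_a,series_b Objects of class `suspension_series` (see
#'   [generate_series()] or [suspension_series()]) sharing the same
#'   concentration ladder.
#' @return A `data.frame` with columns `concentration` and `delta_phi4`
#'   (degrees, non-negative).
#' @export
delta_phi4 <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "suspension_series"),
            inherits(series_b, "suspension_series"))
  ca <- series_a$concentrations; cb <- series_b$concentrations
  if (length(ca) != length(cb) || any(abs(ca - cb) > 1e-12 * pmax(ca, 1)))
    stop("series do not share the same concentration ladder", call. = FALSE)
  pa <- series_a$metrics$phi4
  pb <- series_b$metrics$phi4
  data.frame(concentration = ca, delta_phi4 = abs(pa - pb))
}

#' Hand-built suspension series
#'
#' Container pairing a labelled concentration ladder with per-concentration
#' metrics (and optionally true parameters and spectra). [generate_series()]
#' produces these from a preset; this constructor admits externally fitted
#' results into the same comparison machinery.
#'
#' @param cell_type,medium Labels.
#' @param concentrations Strictly increasing numeric vector (relative
#'   units).
#' @param metrics A `data.frame` with one row per concentration; must
#'   contain at least a `phi4` column for [delta_phi4()].
#' @param truth Optional list of [circuit_params()] per concentration.
#' @param spectra Optional list of [impedance_spectrum()] per concentration.
#' @return An object of class `suspension_series`.
#' @export
suspension_series <- function(cell_type, medium, concentrations, metrics,
                              truth = NULL, spectra = NULL) {
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing", call. = FALSE)
  if (nrow(metrics) != length(concentrations))
    stop("metrics must have one row per concentration", call. = FALSE)
  structure(list(cell_type = cell_type, medium = medium,
                 concentrations = as.numeric(concentrations),
                 metrics = metrics, truth = truth, spectra = spectra),
            class = "suspension_series")
}

#' @export
print.suspension_series <- function(x, ...) {
  cat("<suspension_series> ", x$cell_type, " in ", x$medium, ", ",
      length(x$concentrations), " concentrations\n", sep = "")
  print(cbind(concentration = x$concentrations, x$metrics))
  invisible(x)
}

#' Deviation-versus-k sensitivity curve
#'
#' Evaluates `d(k) = R_1 (p + k/(k+1)) / medium_z5` over a grid of k
#' values. With the cell-free reference `medium_z5 = R_1 (p + 1)`, d is
#' below 1 for all finite k and rises towards 1 as k grows; a
#' lower-conductivity medium (larger `R_1` for the same electrode `R_s`,
#' hence smaller p) pushes d further from 1, i.e. larger deviation.
#'
#' @param p Ratio `R_s / R_1` of the suspension, > 0.
#' @param k_grid Positive k values.
#' @param medium_z5 Region-5 magnitude of the cell-free medium, ohm.
#' @param R_1 Solution resistance of the suspension, ohm.
#' @return A `data.frame` with columns `k` and `d`.
#' @export
sensitivity_curve <- function(p, k_grid, medium_z5, R_1) {
  check_positive(p, "p"); check_positive(k_grid, "k_grid")
  check_positive(medium_z5, "medium_z5"); check_positive(R_1, "R_1")
  data.frame(k = k_grid, d = z5_magnitude(R_1, k_grid, p) / medium_z5)
}
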