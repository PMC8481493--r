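#' Circuit parameters of the unified Randles-Debye model
#'
#' Constructs and validates the lumped-parameter set of the unified
#' equivalent circuit for a cell suspension: a Randles electrode block
#' (series resistance `R_s`, charge-transfer resistance `R_ct` shunted by a
#' double-layer capacitance `C_dl`, optionally generalized to a constant
#' phase element via `alpha_dl`) in series with an extended Debye block
#' describing the suspension dielectrics (solution resistance `R_1`, the
#' cell branch `R` + `C` in series, and the water-polarization capacitance
#' `C_1`, all in parallel).
#'
#' A cell-free medium is represented by `cell_branch = FALSE`, in which case
#' `R` and `C` may be `NA`; sentinel values such as infinite resistances are
#' deliberately rejected so that validation stays strict.
#'
#' @param R_s Series (solution-access) resistance, ohm.
#' @param R_ct Charge-transfer resistance, ohm.
#' @param C_dl Double-layer capacitance, farad. When `alpha_dl < 1` this is
#'   the CPE coefficient Q in `Z = 1 / (Q (j*omega)^alpha)`.
#' @param R Resistance of the cells, ohm (cell branch).
#' @param R_1 Resistance of the solution, ohm.
#' @param C Capacitance due to the presence of cells, farad (cell branch).
#' @param C_1 Water-polarization capacitance, farad.
#' @param alpha_dl CPE exponent in (0, 1]; 1 recovers an ideal capacitor.
#'   All closed-form asymptotics require `alpha_dl = 1`.
#' @param cell_branch Logical; `FALSE` marks a medium-only circuit with the
#'   R-C cell branch absent.
#'
#' @return An object of class `circuit_params` (a named list).
#' @examples
#' cp <- circuit_params(R_s = 1, R_ct = 2e4, C_dl = 1e-6,
#'                      R = 150, R_1 = 100, C = 2e-9, C_1 = 5e-12)
#' cp
#' @export
circuit_params <- function(R_s, R_ct, C_dl, R = NA_real_, R_1, C = NA_real_,
                           C_1, alpha_dl = 1, cell_branch = TRUE) {
  obj <- structure(
    list(R_s = as.numeric(R_s), R_ct = as.numeric(R_ct),
         C_dl = as.numeric(C_dl), R = as.numeric(R), R_1 = as.numeric(R_1),
         C = as.numeric(C), C_1 = as.numeric(C_1),
         alpha_dl = as.numeric(alpha_dl),
         cell_branch = isTRUE(cell_branch)),
    class = "circuit_params")
  validate_circuit_params(obj)
  obj
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>",
      if (!x$cell_branch) " (medium-only: cell branch absent)", "\n", sep = "")
  fmt <- function(v) formatC(v, digits = 6, format = "g")
  cat("  Randles: R_s = ", fmt(x$R_s), " ohm, R_ct = ", fmt(x$R_ct),
      " ohm, C_dl = ", fmt(x$C_dl), " F (alpha = ", fmt(x$alpha_dl), ")\n",
      sep = "")
  cat("  Debye:   R_1 = ", fmt(x$R_1), " ohm, C_1 = ", fmt(x$C_1), " F",
      sep = "")
  if (x$cell_branch)
    cat(", cell branch R = ", fmt(x$R), " ohm, C = ", fmt(x$C), " F",
        sep = "")
  cat("\n")
  invisible(x)
}

validate_circuit_params <- function(p) {
  stopifnot(inherits(p, "circuit_params"))
  check_pos <- function(value, field) {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
        value <= 0)
      stop("circuit parameter '", field,
           "' must be a single finite positive number", call. = FALSE)
  }
  for (f in c("R_s", "R_ct", "C_dl", "R_1", "C_1")) check_pos(p[[f]], f)
  if (p$cell_branch) {
    for (f in c("R", "C")) check_pos(p[[f]], f)
  }
  if (!is.finite(p$alpha_dl) || p$alpha_dl <= 0 || p$alpha_dl > 1)
    stop("circuit parameter 'alpha_dl' must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Drop the cell branch from a parameter set
#'
#' @param params A [circuit_params()] object.
#' @return The same circuit with `cell_branch = FALSE` (a medium-only
#'   circuit sharing the electrode and solution parameters).
#' @export
as_medium_params <- function(params) {
  validate_circuit_params(params)
  circuit_params(R_s = params$R_s, R_ct = params$R_ct, C_dl = params$C_dl,
                 R_1 = params$R_1, C_1 = params$C_1,
                 alpha_dl = params$alpha_dl, cell_branch = FALSE)
}

#' Logarithmic frequency grid
#'
#' @param f_min,f_max Band edges in Hz; defaults cover the 4 Hz - 20 GHz
#'   ultra-wide measurement band.
#' @param points_per_decade Grid density (default 10).
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @export
log_freq_grid <- function(f_min = 4, f_max = 2e10, points_per_decade = 10) {
  if (!is.finite(f_min) || !is.finite(f_max) || f_min <= 0 || f_max <= f_min)
    stop("need 0 < f_min < f_max", call. = FALSE)
  n <- max(2L, ceiling(log10(f_max / f_min) * points_per_decade) + 1L)
  10^seq(log10(f_min), log10(f_max), length.out = n)
}

validate_freq_grid <- function(f) {
  if (!is.numeric(f) || length(f) == 0L)
    stop("frequency grid must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequencies must be finite and strictly positive", call. = FALSE)
  if (is.unsorted(f, strictly = TRUE))
    stop("frequencies must be strictly increasing", call. = FALSE)
  invisible(f)
}

#' Impedance spectrum container
#'
#' A data frame with a frequency column (Hz) and a complex impedance column
#' (ohm), the common currency of every operation in the package.
#'
#' @param frequency Strictly increasing frequencies, Hz.
#' @param z Complex impedance values, ohm (same length as `frequency`).
#' @return A `data.frame` of class `impedance_spectrum` with columns
#'   `frequency` and `z`.
#' @export
impedance_spectrum <- function(frequency, z) {
  validate_freq_grid(frequency)
  if (length(z) != length(frequency))
    stop("frequency and z must have the same length", call. = FALSE)
  z <- as.complex(z)
  if (any(!is.finite(z)) || any(Mod(z) <= 0))
    stop("impedance values must be finite with positive magnitude",
         call. = FALSE)
  structure(data.frame(frequency = as.numeric(frequency), z = z),
            class = c("impedance_spectrum", "data.frame"))
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat("<impedance_spectrum> ", nrow(x), " points, ",
      formatC(min(x$frequency), format = "g"), " - ",
      formatC(max(x$frequency), format = "g"), " Hz\n", sep = "")
  utils::head(as.data.frame(x))
}

#' Magnitude and phase of a spectrum
#'
#' Phase uses the capacitive-negative sign convention: a purely capacitive
#' impedance has phase -90 degrees.
#'
#' @param spectrum An [impedance_spectrum()].
#' @return Numeric vector: magnitude in ohm, or phase in degrees.
#' @export
spectrum_magnitude <- function(spectrum) Mod(spectrum$z)

#' @rdname spectrum_magnitude
#' @export
spectrum_phase <- function(spectrum) Arg(spectrum$z) * 180 / pi

#' Exact complex impedance of the unified Randles-Debye circuit
#'
#' Evaluates the series combination of the Randles electrode block,
#' `R_s + (R_ct || Z_dl)` with `Z_dl = 1 / (C_dl (j*omega)^alpha_dl)`, and
#' the extended Debye suspension block, `R_1 || (R + 1/(j*omega*C)) ||
#' 1/(j*omega*C_1)`, at each grid frequency. The Warburg diffusion element
#' is omitted: its contribution only matters below the 4 Hz band edge.
#'
#' @param params A [circuit_params()] object.
#' @param frequency Frequencies in Hz (strictly increasing, positive).
#' @return An [impedance_spectrum()].
#' @examples
#' cp <- circuit_params(1, 2e4, 1e-6, 150, 100, 2e-9, 5e-12)
#' sp <- evaluate_impedance(cp, log_freq_grid())
#' range(spectrum_phase(sp))
#' @export
evaluate_impedance <- function(params, frequency) {
  validate_circuit_params(params)
  validate_freq_grid(frequency)
  w <- 2 * pi * frequency
  jw <- complex(real = 0, imaginary = 1) * w
  z_dl <- 1 / (params$C_dl * jw^params$alpha_dl)
  randles <- params$R_s + 1 / (1 / params$R_ct + 1 / z_dl)
  y_debye <- 1 / params$R_1 + params$C_1 * jw
  if (params$cell_branch)
    y_debye <- y_debye + 1 / (params$R + 1 / (params$C * jw))
  impedance_spectrum(frequency, randles + 1 / y_debye)
}

#' Impedance of the cell-free medium circuit
#'
#' The same circuit with the R-C cell branch removed, i.e. the Debye block
#' reduced to `R_1 || C_1`. This is the reference needed by the region-5
#' deviation metric d.
#'
#' @inheritParams evaluate_impedance
#' @return An [impedance_spectrum()].
#' @export
medium_impedance <- function(params, frequency) {
  evaluate_impedance(as_medium_params(params), frequency)
}
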