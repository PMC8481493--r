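# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# deterministic per-item seed stream derived from one user seed
split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

#' Scenario presets for the four emulated suspensions
#'
#' Returns a documented default scenario for one of the four suspensions:
#' tomato-like (`"MSK8-like"`) or tobacco-like (`"BY2-like"`) cells in a
#' nutrient-medium-like (`"MS-like"`) or phosphate-buffer-like
#' (`"PB-like"`) background. The numeric values are synthetic fixtures
#' chosen to satisfy the corner-separation the closed-form analysis
#' requires and to reproduce the qualitative behaviour of real
#' suspensions; they are not measurements of real cells.
#'
#' The concentration response (concentration `c` in relative units of a
#' stock, 0-1):
#' \itemize{
#'   \item `k(c) = g / (1/k0 + b c)` — cell loading adds conductance to
#'     the cell branch, so `k = R/R_1` falls monotonically from the dilute
#'     limit `k0`; the rate `b` is the cell-type signature, the factor `g`
#'     a small medium modulation.
#'   \item `R_1(c) = R_1 (1 + r1_slope c)` — cells displace conductive
#'     medium, raising the solution resistance; this is what deepens the
#'     region-6 peak with concentration.
#'   \item `C(c) = C_scale (C_offset + c)` — cell capacitance grows with
#'     loading.
#' }
#' The buffer background has three times the solution resistance of the
#' nutrient background at the same electrode (`R_s` fixed), hence a third
#' of its `p = R_s/R_1` — which is what makes the region-5 deviation
#' larger in the low-conductivity medium. Agglomeration is modelled as
#' mean-one lognormal jitter on `C` only (it perturbs the effective cell
#' capacitance, randomizing `f4` but not `phi4`).
#'
#' @param cell_type `"MSK8-like"` or `"BY2-like"` (the `-like` suffix may
#'   be omitted).
#' @param medium `"MS-like"` or `"PB-like"` (suffix optional).
#' @return A list of class `scenario_preset`: labels, `base` (a
#'   medium-only [circuit_params()]), response coefficients `k0`, `b`,
#'   `g`, `r1_slope`, `C_scale`, `C_offset`, and noise settings
#'   `agglomeration_cv`, `noise_mag_cv`, `noise_phase_sd_deg`.
#' @examples
#' preset("MSK8", "PB")$base$R_1
#' @export
preset <- function(cell_type, medium) {
  ct <- match.arg(sub("-like$", "", cell_type), c("MSK8", "BY2"))
  md <- match.arg(sub("-like$", "", medium), c("MS", "PB"))
  R_1 <- c(MS = 100, PB = 300)[[md]]
  structure(list(
    cell_type = paste0(ct, "-like"),
    medium = paste0(md, "-like"),
    base = circuit_params(R_s = 1, R_ct = 2e4, C_dl = 1e-6,
                          R_1 = R_1, C_1 = 5e-12, cell_branch = FALSE),
    k0 = 40,
    b = c(MSK8 = 0.9, BY2 = 1.6)[[ct]],
    g = c(MS = 1.0, PB = 1.06)[[md]],
    r1_slope = 2,
    C_scale = 4e-9,
    C_offset = 0.05,
    agglomeration_cv = 0.3,
    noise_mag_cv = 0.02,
    noise_phase_sd_deg = 0.3), class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("<scenario_preset> ", x$cell_type, " in ", x$medium, "\n", sep = "")
  cat(sprintf("  base R_1 = %g ohm (p0 = %g), k response: k0 = %g, b = %g, g = %g\n",
              x$base$R_1, x$base$R_s / x$base$R_1, x$k0, x$b, x$g))
  cat(sprintf("  agglomeration CV = %g, magnitude CV = %g, phase jitter = %g deg\n",
              x$agglomeration_cv, x$noise_mag_cv, x$noise_phase_sd_deg))
  invisible(x)
}

#' Deterministic circuit parameters at a concentration
#'
#' Applies the preset's concentration response; at zero concentration the
#' cell branch is absent and the cell-free base circuit is returned, so
#' the two cell types coincide in the same medium.
#'
#' @param preset A [preset()].
#' @param concentration Relative concentration, >= 0.
#' @return A [circuit_params()].
#' @export
params_at_concentration <- function(preset, concentration) {
  stopifnot(inherits(preset, "scenario_preset"))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0)
    stop("concentration must be a single non-negative number",
         call. = FALSE)
  b <- preset$base
  R_1 <- b$R_1 * (1 + preset$r1_slope * concentration)
  if (concentration == 0)
    return(circuit_params(R_s = b$R_s, R_ct = b$R_ct, C_dl = b$C_dl,
                          R_1 = R_1, C_1 = b$C_1, cell_branch = FALSE))
  k <- preset$g / (1 / preset$k0 + preset$b * concentration)
  circuit_params(R_s = b$R_s, R_ct = b$R_ct, C_dl = b$C_dl,
                 R = k * R_1, R_1 = R_1,
                 C = preset$C_scale * (preset$C_offset + concentration),
                 C_1 = b$C_1)
}

#' Generate one noisy synthetic spectrum
#'
#' Builds the deterministic parameters at the given concentration, applies
#' one seeded mean-one lognormal agglomeration draw to the cell
#' capacitance, evaluates the exact circuit, then applies seeded
#' multiplicative lognormal noise to the magnitude and additive Gaussian
#' jitter (degrees) to the phase. All randomness flows from `seed`;
#' identical seeds give identical spectra. Setting the preset's noise and
#' agglomeration coefficients to zero returns the exact deterministic
#' spectrum.
#'
#' @param preset A [preset()].
#' @param concentration Relative concentration, >= 0.
#' @param frequency Frequency grid, Hz; default 10 points/decade over
#'   4 Hz - 20 GHz.
#' @param seed Integer seed.
#' @return An [impedance_spectrum()] with attributes `truth` (the realized
#'   [circuit_params()], including the agglomeration-drawn C) and
#'   `nominal` (the deterministic parameters before the draw).
#' @export
generate_spectrum <- function(preset, concentration,
                              frequency = log_freq_grid(), seed = 1L) {
  stopifnot(inherits(preset, "scenario_preset"))
  nominal <- params_at_concentration(preset, concentration)
  validate_freq_grid(frequency)
  with_seed(seed, {
    truth <- nominal
    if (nominal$cell_branch && preset$agglomeration_cv > 0) {
      sdlog <- sqrt(log(1 + preset$agglomeration_cv^2))
      truth$C <- nominal$C * stats::rlnorm(1, meanlog = -sdlog^2 / 2,
                                           sdlog = sdlog)
    }
    sp <- evaluate_impedance(truth, frequency)
    mag <- spectrum_magnitude(sp)
    ph <- spectrum_phase(sp)
    n <- length(frequency)
    if (preset$noise_mag_cv > 0) {
      sdlog <- sqrt(log(1 + preset$noise_mag_cv^2))
      mag <- mag * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    if (preset$noise_phase_sd_deg > 0)
      ph <- ph + stats::rnorm(n, sd = preset$noise_phase_sd_deg)
    out <- impedance_spectrum(frequency,
                              complex(modulus = mag,
                                      argument = ph * pi / 180))
    attr(out, "truth") <- truth
    attr(out, "nominal") <- nominal
    out
  })
}

#' Generate a concentration series for one suspension
#'
#' One [generate_spectrum()] per concentration, with per-concentration
#' seeds derived deterministically from the single user seed (a fixed
#' prime-stride splitting rule; no hidden global state). Analytic
#' detection metrics are computed from the realized truth parameters, with
#' the cell-free base circuit as the medium reference for d.
#'
#' @param preset A [preset()].
#' @param concentrations Strictly increasing positive concentrations.
#' @param frequency Frequency grid, Hz.
#' @param seed Integer seed.
#' @return A [suspension_series()] whose `metrics` data frame has columns
#'   `k`, `p`, `phi4`, `f4`, `phi6`, `f6`, `z5`, `d`, with the spectra and
#'   realized truth parameters attached.
#' @export
generate_series <- function(preset, concentrations,
                            frequency = log_freq_grid(), seed = 1L) {
  stopifnot(inherits(preset, "scenario_preset"))
  if (is.unsorted(concentrations, strictly = TRUE) ||
      any(concentrations <= 0))
    stop("concentrations must be strictly increasing and positive",
         call. = FALSE)
  spectra <- vector("list", length(concentrations))
  truth <- vector("list", length(concentrations))
  rows <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    sp <- generate_spectrum(preset, concentrations[i], frequency,
                            seed = split_seed(seed, i))
    spectra[[i]] <- sp
    truth[[i]] <- attr(sp, "truth")
    m <- metrics_from_params(truth[[i]], medium_reference = preset$base)
    rows[[i]] <- as.data.frame(unclass(m))
  }
  suspension_series(cell_type = preset$cell_type, medium = preset$medium,
                    concentrations = concentrations,
                    metrics = do.call(rbind, rows),
                    truth = truth, spectra = spectra)
}
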