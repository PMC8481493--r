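#' Options for complex nonlinear least-squares fitting
#'
#' @param weighting Residual weighting: `"proportional"` (1/|Z|, the
#'   default, so the ohm-scale high-frequency plateaus are not drowned by
#'   the kilo-ohm region-1 plateau), `"unit"`, or `"modulus2"` (1/|Z|^2).
#' @param max_iterations Maximum optimizer iterations per start.
#' @param tolerance Relative convergence threshold on the step and on the
#'   residual sum of squares.
#' @param free_alpha Also fit the CPE exponent `alpha_dl` (bounded in
#'   `[0.3, 1]`); the default keeps the ideal capacitor `alpha_dl = 1`.
#' @param n_starts Number of optimizer starts: the supplied (or heuristic)
#'   initial point plus `n_starts - 1` log-space jittered restarts; the
#'   lowest weighted residual wins, ties broken by the earliest start.
#' @param jitter_sd Standard deviation of the multi-start jitter in
#'   decades (log10 units).
#' @param seed Integer seed for the multi-start jitter.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(weighting = c("proportional", "unit", "modulus2"),
                        max_iterations = 200, tolerance = 1e-12,
                        free_alpha = FALSE, n_starts = 5,
                        jitter_sd = 0.15, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(tolerance > 0, max_iterations >= 1, n_starts >= 1,
            jitter_sd >= 0)
  structure(list(weighting = weighting,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, free_alpha = isTRUE(free_alpha),
                 n_starts = as.integer(n_starts), jitter_sd = jitter_sd,
                 seed = as.integer(seed)), class = "fit_options")
}

#' Asymptote-driven initial parameter guess
#'
#' Inverts the seven-region Bode skeleton of a measured spectrum: the
#' plateau magnitudes give the resistances and the detected phase-peak
#' frequencies give the capacitances through the ladder formulas.
#' Specifically, `R_s` is read off the highest-frequency magnitude,
#' `R_s + R_1` and `R_s + R_1 || R` off the flattest (max-phase) points
#' between successive peaks, `R_ct` off the low-frequency plateau, and
#' `C_dl`, `C`, `C_1` by solving the geometric-mean peak relations at the
#' detected peak frequencies.
#'
#' When the low-frequency electrode dispersion is outside the recorded
#' band (e.g. a spectrum truncated below 1 kHz), `R_ct` falls back to
#' `R_1` and `C_dl` to the value placing its zero one decade below the
#' band edge; the returned object then carries a `"flags"` attribute
#' naming the fallbacks.
#'
#' @param spectrum An [impedance_spectrum()] spanning at least the two
#'   high-frequency dispersions (cell and water polarization).
#' @param cell_branch `FALSE` to initialize the medium-only model (one
#'   high-frequency dispersion).
#' @return A [circuit_params()] with optional attribute `flags`.
#' @export
initial_guess <- function(spectrum, cell_branch = TRUE) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequency
  mag <- spectrum_magnitude(spectrum)
  ph <- spectrum_phase(spectrum)
  # smooth the phase against measurement jitter before peak assignment,
  # then keep only one peak per half-decade neighbourhood (deepest wins)
  ph_s <- as.numeric(stats::filter(ph, rep(1 / 5, 5), sides = 2))
  ph_s[is.na(ph_s)] <- ph[is.na(ph_s)]
  smoothed <- impedance_spectrum(f, complex(modulus = mag,
                                            argument = ph_s * pi / 180))
  peaks <- find_phase_peaks(smoothed, min_depth_deg = 2)
  if (nrow(peaks) > 1L) {
    ord <- order(peaks$phi_min)
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(log10(peaks$f_peak[i] / peaks$f_peak[kept])) > 0.5))
        kept <- c(kept, i)
    }
    peaks <- peaks[sort(kept), , drop = FALSE]
  }
  need <- if (cell_branch) 2L else 1L
  if (nrow(peaks) < need)
    stop("initialization error: found ", nrow(peaks),
         " phase dispersion(s), need at least ", need,
         " (is this a pure-resistor spectrum?)", call. = FALSE)
  n_hf <- if (cell_branch) 2L else 1L
  hf <- utils::tail(peaks, n_hf)        # cell (region 4) and water (region 6)
  low <- utils::head(peaks, nrow(peaks) - n_hf)
  flags <- character(0)
  # Re(Z) -> R_s + 1/(omega^2 C_1^2 Rpar) above the last corner; remove
  # the residual tail by extrapolating in 1/omega^2 over the top decade
  n_pts <- length(f)
  i1 <- max(1L, findInterval(f[n_pts] / 10, f))
  re1 <- Re(spectrum$z[i1]); re2 <- Re(spectrum$z[n_pts])
  b <- (re1 - re2) / (1 / (2 * pi * f[i1])^2 - 1 / (2 * pi * f[n_pts])^2)
  R_s <- re2 - b / (2 * pi * f[n_pts])^2
  if (!is.finite(R_s) || R_s <= 0) R_s <- max(re2, 1e-12)
  # flattest point between two frequencies = plateau sample
  plateau_between <- function(f_lo, f_hi) {
    i <- which(f > f_lo & f < f_hi)
    if (length(i) == 0L) return(NA_real_)
    mag[i[which.max(ph[i])]]
  }
  f6 <- hf$f_peak[n_hf]
  if (cell_branch) {
    f4 <- hf$f_peak[1]
    f_below <- if (nrow(low) > 0) low$f_peak[nrow(low)] else min(f) / 2
    plateau_3 <- plateau_between(f_below, f4)
    plateau_5 <- plateau_between(f4, f6)
  } else {
    f4 <- NA_real_
    f_below <- if (nrow(low) > 0) low$f_peak[nrow(low)] else min(f) / 2
    plateau_3 <- plateau_between(f_below, f6)
    plateau_5 <- NA_real_
  }
  if (!is.finite(plateau_3) || plateau_3 <= R_s) plateau_3 <- 2 * R_s
  R_1 <- plateau_3 - R_s
  if (nrow(low) > 0) {
    # electrode dispersion visible: region-1 plateau at the low edge
    plateau_1 <- max(mag[1], plateau_3 * 1.01)
    R_ct <- plateau_1 - plateau_3
    if (ph[1] < -20) flags <- c(flags, "region1_plateau_clipped")
    C_dl <- 1 / (2 * pi * low$f_peak[1] * sqrt(plateau_1 * plateau_3))
  } else {
    flags <- c(flags, "R_ct_fallback", "C_dl_fallback")
    R_ct <- R_1
    C_dl <- 10 / (2 * pi * min(f) * (R_s + R_1))
  }
  if (cell_branch) {
    if (!is.finite(plateau_5) || plateau_5 <= R_s)
      plateau_5 <- R_s + R_1 / 2
    R_par <- min(plateau_5 - R_s, 0.999 * R_1)
    R <- 1 / (1 / R_par - 1 / R_1)
    k <- R / R_1
    C <- 1 / (2 * pi * f4 * R_1 * sqrt(k * (k + 1)))
    p <- R_s / R_1
    kf <- k / (k + 1)
    C_1 <- 1 / (2 * pi * f6 * R_1 * sqrt(p * (p + kf)))
    out <- circuit_params(R_s = R_s, R_ct = R_ct, C_dl = C_dl, R = R,
                          R_1 = R_1, C = C, C_1 = C_1)
  } else {
    # medium-only: peak at sqrt(omega_56 * omega_67)
    C_1 <- sqrt((R_s + R_1) / R_s) / (2 * pi * f6 * R_1)
    out <- circuit_params(R_s = R_s, R_ct = R_ct, C_dl = C_dl,
                          R_1 = R_1, C_1 = C_1, cell_branch = FALSE)
  }
  if (length(flags)) attr(out, "flags") <- flags
  out
}

fit_param_names <- function(cell_branch) {
  if (cell_branch) c("R_s", "R_ct", "C_dl", "R", "R_1", "C", "C_1")
  else c("R_s", "R_ct", "C_dl", "R_1", "C_1")
}

params_to_theta <- function(params, free_alpha) {
  th <- log(unlist(params[fit_param_names(params$cell_branch)]))
  if (free_alpha) th <- c(th, alpha_dl = params$alpha_dl)
  th
}

theta_to_params <- function(theta, cell_branch, free_alpha, alpha_fixed) {
  nm <- fit_param_names(cell_branch)
  v <- as.list(exp(theta[seq_along(nm)]))
  names(v) <- nm
  alpha <- if (free_alpha) theta[length(nm) + 1L] else alpha_fixed
  circuit_params(R_s = v$R_s, R_ct = v$R_ct, C_dl = v$C_dl,
                 R = if (cell_branch) v$R else NA_real_,
                 R_1 = v$R_1,
                 C = if (cell_branch) v$C else NA_real_,
                 C_1 = v$C_1, alpha_dl = alpha,
                 cell_branch = cell_branch)
}

#' Fit a spectrum to the unified Randles-Debye model
#'
#' Minimizes the weighted sum of squared real and imaginary residuals by
#' Levenberg-Marquardt, with the resistances and capacitances optimized in
#' log-space (which enforces positivity and tames the ten-plus decades
#' separating `C_dl` from `C_1`). The default start is [initial_guess()];
#' `options$n_starts` seeded log-jittered restarts guard against local
#' minima.
#'
#' @param spectrum An [impedance_spectrum()] with at least eight points
#'   per free parameter.
#' @param init Optional [circuit_params()] starting point.
#' @param options A [fit_options()] object.
#' @param cell_branch `FALSE` fits the five-parameter medium-only model.
#' @return A list of class `fit_result`: `estimate` ([circuit_params()]),
#'   `residual_norm` (weighted chi-square), `converged`, `n_iterations`
#'   (of the winning start), `start_point`, `se_log` (standard errors of
#'   the log-parameters, `NA` when unavailable; an exploding entry flags
#'   an unidentifiable parameter), `message`.
#' @examples
#' cp <- circuit_params(1, 2e4, 1e-6, 150, 100, 2e-9, 5e-12)
#' sp <- evaluate_impedance(cp, log_freq_grid())
#' fit <- fit_spectrum(sp)
#' fit$converged
#' @export
fit_spectrum <- function(spectrum, init = NULL, options = fit_options(),
                         cell_branch = TRUE) {
  stopifnot(inherits(spectrum, "impedance_spectrum"),
            inherits(options, "fit_options"))
  n_free <- length(fit_param_names(cell_branch)) + options$free_alpha
  if (nrow(spectrum) < 8 * n_free)
    stop("spectrum has ", nrow(spectrum), " points; need at least 8 per ",
         "free parameter (", 8 * n_free, ")", call. = FALSE)
  if (is.null(init)) init <- initial_guess(spectrum, cell_branch)
  validate_circuit_params(init)
  w <- switch(options$weighting,
              unit = rep(1, nrow(spectrum)),
              proportional = 1 / spectrum_magnitude(spectrum),
              modulus2 = 1 / spectrum_magnitude(spectrum)^2)
  z_data <- spectrum$z
  freq <- spectrum$frequency
  resid_fn <- function(theta) {
    p <- try(theta_to_params(theta, cell_branch, options$free_alpha,
                             init$alpha_dl), silent = TRUE)
    if (inherits(p, "try-error")) return(rep(1e6, 2 * length(freq)))
    zm <- evaluate_impedance(p, freq)$z
    c(Re(zm - z_data) * w, Im(zm - z_data) * w)
  }
  theta0 <- params_to_theta(init, options$free_alpha)
  starts <- list(theta0)
  if (options$n_starts > 1L) {
    jit <- with_seed(options$seed, {
      lapply(seq_len(options$n_starts - 1L), function(i) {
        th <- theta0
        nlog <- length(fit_param_names(cell_branch))
        th[seq_len(nlog)] <- th[seq_len(nlog)] +
          stats::rnorm(nlog, sd = options$jitter_sd * log(10))
        th
      })
    })
    starts <- c(starts, jit)
  }
  lower <- rep(-Inf, length(theta0))
  upper <- rep(Inf, length(theta0))
  if (options$free_alpha) {
    lower[length(theta0)] <- 0.3
    upper[length(theta0)] <- 1
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$max_iterations,
                                     ftol = options$tolerance,
                                     ptol = options$tolerance)
  best <- NULL
  for (s in seq_along(starts)) {
    fit <- try(minpack.lm::nls.lm(par = starts[[s]], fn = resid_fn,
                                  lower = lower, upper = upper,
                                  control = ctrl), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(estimate = init, residual_norm = Inf,
                          converged = FALSE, n_iterations = 0L,
                          start_point = init, se_log = NULL,
                          message = "all optimizer starts failed"),
                     class = "fit_result"))
  }
  est <- theta_to_params(best$par, cell_branch, options$free_alpha,
                         init$alpha_dl)
  se <- tryCatch({
    covm <- solve(best$hessian) * best$deviance /
      max(1L, length(best$fvec) - length(best$par))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(best$par)))
  names(se) <- names(theta0)
  structure(list(estimate = est, residual_norm = best$deviance,
                 converged = best$info %in% 1:3,
                 n_iterations = best$niter, start_point = init,
                 se_log = se, message = best$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$n_iterations, " iterations, weighted chi-square = ",
      formatC(x$residual_norm, digits = 4, format = "g"), "\n", sep = "")
  print(x$estimate)
  invisible(x)
}
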