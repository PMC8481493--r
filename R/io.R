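#' Read an impedance spectrum from CSV
#'
#' Two dialects are supported, identified by their header tokens:
#' \describe{
#'   \item{`freq_real_imag`}{columns `frequency_hz`, `z_real_ohm`,
#'     `z_imag_ohm`}
#'   \item{`freq_mag_phasedeg`}{columns `frequency_hz`, `z_mag_ohm`,
#'     `z_phase_deg` (capacitive phase negative)}
#' }
#' Rows are sorted by frequency on read; duplicate or non-positive
#' frequencies are rejected with the offending row number.
#'
#' @param path Path to a CSV file.
#' @param dialect `"auto"` (detect from the header), `"freq_real_imag"`,
#'   or `"freq_mag_phasedeg"`.
#' @return An [impedance_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("auto", "freq_real_imag",
                                            "freq_mag_phasedeg")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE)
  if (dialect == "auto") {
    dialect <- if (all(c("z_real_ohm", "z_imag_ohm") %in% names(df)))
      "freq_real_imag"
    else if (all(c("z_mag_ohm", "z_phase_deg") %in% names(df)))
      "freq_mag_phasedeg"
    else stop("cannot detect spectrum dialect from header: ",
              paste(names(df), collapse = ", "), call. = FALSE)
  }
  cols <- switch(dialect,
                 freq_real_imag = c("frequency_hz", "z_real_ohm",
                                    "z_imag_ohm"),
                 freq_mag_phasedeg = c("frequency_hz", "z_mag_ohm",
                                       "z_phase_deg"))
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("spectrum file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$frequency_hz) | df$frequency_hz <= 0)
  if (length(bad))
    stop("non-positive or unparseable frequency at data row ", bad[1],
         call. = FALSE)
  if (anyDuplicated(df$frequency_hz))
    stop("duplicate frequency at data row ",
         which(duplicated(df$frequency_hz))[1], call. = FALSE)
  df <- df[order(df$frequency_hz), , drop = FALSE]
  z <- if (dialect == "freq_real_imag")
    complex(real = df$z_real_ohm, imaginary = df$z_imag_ohm)
  else
    complex(modulus = df$z_mag_ohm, argument = df$z_phase_deg * pi / 180)
  impedance_spectrum(df$frequency_hz, z)
}

#' Write an impedance spectrum to CSV
#'
#' The inverse of [read_spectrum()]; values are written with 15
#' significant digits so a write/read round trip is lossless well beyond
#' 12 significant digits.
#'
#' @param spectrum An [impedance_spectrum()].
#' @param path Output path.
#' @param dialect Output dialect (see [read_spectrum()]).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path,
                           dialect = c("freq_real_imag",
                                       "freq_mag_phasedeg")) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  dialect <- match.arg(dialect)
  num <- function(x) formatC(x, digits = 15, format = "g")
  df <- if (dialect == "freq_real_imag")
    data.frame(frequency_hz = num(spectrum$frequency),
               z_real_ohm = num(Re(spectrum$z)),
               z_imag_ohm = num(Im(spectrum$z)))
  else
    data.frame(frequency_hz = num(spectrum$frequency),
               z_mag_ohm = num(spectrum_magnitude(spectrum)),
               z_phase_deg = num(spectrum_phase(spectrum)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Values holding comma-separated numbers are returned as numeric
#' vectors, single numbers as numerics, anything else as strings.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("unparseable config line: '", ln, "'", call. = FALSE)
    val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[m[2]]] <- if (length(parts) && !anyNA(nums)) nums else parts
  }
  out
}
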