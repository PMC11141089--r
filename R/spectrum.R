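#' Spectral power distribution
#'
#' The common currency of all photometric computation in melanophot: a
#' wavelength-gridded spectral flux. Irradiance spectra carry
#' W m^-2 nm^-1 (corneal measurements), radiance spectra
#' W m^-2 sr^-1 nm^-1 (surface measurements such as a display).
#'
#' @param wavelength_nm Strictly increasing numeric wavelength grid (nm),
#'   within 300--830 nm, length >= 2.
#' @param value Nonnegative finite spectral flux, same length as the grid.
#' @param quantity Either `"irradiance"` or `"radiance"`.
#' @param label Free-text label carried through reports.
#' @return An object of class `"spd"`: a list with elements
#'   `wavelength_nm`, `value`, `quantity`, `label`.
#' @seealso [read_spd()], [spd_resample()], [spd_integrate()]
#' @examples
#' s <- spd(400:700, rep(0.01, 301), label = "flat")
#' spd_integrate(s)  # 3.01 W/m2
#' @export
spd <- function(wavelength_nm, value,
                quantity = c("irradiance", "radiance"), label = "") {
  quantity <- match.arg(quantity)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2L || length(wavelength_nm) != length(value))
    stop_melanophot("wavelength and value must have equal length >= 2",
                    "melanophot_validation_error")
  if (anyNA(wavelength_nm) || anyNA(value) ||
      any(!is.finite(wavelength_nm)) || any(!is.finite(value)))
    stop_melanophot("spectrum contains non-finite entries",
                    "melanophot_validation_error")
  if (any(diff(wavelength_nm) <= 0))
    stop_melanophot("wavelength grid must be strictly increasing",
                    "melanophot_format_error")
  if (min(wavelength_nm) < 300 || max(wavelength_nm) > 830)
    stop_melanophot("wavelength grid must lie within [300, 830] nm",
                    "melanophot_validation_error")
  if (any(value < 0))
    stop_melanophot("spectral values must be nonnegative",
                    "melanophot_validation_error")
  structure(list(wavelength_nm = wavelength_nm, value = value,
                 quantity = quantity, label = as.character(label)[1L]),
            class = "spd")
}

is_spd <- function(x) inherits(x, "spd")

assert_spd <- function(x, quantity = NULL) {
  if (!is_spd(x))
    stop_melanophot("expected an `spd` object", "melanophot_validation_error")
  if (!is.null(quantity) && x$quantity != quantity)
    stop_melanophot(
      sprintf("expected a %s-tagged spectrum but got %s; convert explicitly (see alpha_opic_trolands for radiance handling)",
              quantity, x$quantity),
      "melanophot_unit_error")
  invisible(x)
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd> %s%s: %d points, %g-%g nm, total %g %s\n",
              x$quantity,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$value), min(x$wavelength_nm), max(x$wavelength_nm),
              sum(x$value) * mean(diff(x$wavelength_nm)),
              if (x$quantity == "irradiance") "W/m2 (approx)" else "W/m2/sr (approx)"))
  invisible(x)
}

#' @export
plot.spd <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$value, type = "l",
                 xlab = "wavelength (nm)",
                 ylab = sprintf("spectral %s (W m-2 %snm-1)", x$quantity,
                                if (x$quantity == "radiance") "sr-1 " else ""),
                 main = x$label, ...)
  invisible(x)
}

#' Read a spectral power distribution from delimited text
#'
#' Expects two numeric columns (wavelength nm, spectral flux); lines starting
#' with `#` are ignored. Comma- and whitespace-delimited files are both
#' accepted. Negative flux entries are rejected unless `clip_negative = TRUE`,
#' in which case they are clipped to zero with a warning (measurement noise
#' around zero in dark spectral regions).
#'
#' @param path Path to the file.
#' @param quantity,label Passed to [spd()].
#' @param clip_negative Clip negative values to 0 instead of erroring.
#' @return An [spd()] object with the file's grid kept verbatim.
#' @export
read_spd <- function(path, quantity = c("irradiance", "radiance"),
                     label = basename(path), clip_negative = FALSE) {
  quantity <- match.arg(quantity)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop_melanophot("no data rows in spectrum file", "melanophot_format_error")
  sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else ""
  dat <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           strip.white = TRUE)
  if (ncol(dat) < 2L || !is.numeric(dat[[1L]]) || !is.numeric(dat[[2L]]))
    stop_melanophot("spectrum file must have two numeric columns",
                    "melanophot_format_error")
  v <- dat[[2L]]
  if (clip_negative && any(v < 0)) {
    warning(sprintf("clipped %d negative spectral value(s) to 0", sum(v < 0)))
    v <- pmax(v, 0)
  }
  spd(dat[[1L]], v, quantity = quantity, label = label)
}

#' Write a spectrum as two-column delimited text
#'
#' Values are written with 12 significant digits so that
#' `read_spd(write_spd(s))` round-trips losslessly at 9+ significant digits.
#'
#' @param s An [spd()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spd <- function(s, path) {
  assert_spd(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s (%s)", s$label, s$quantity), con)
  writeLines(sprintf("%.12g %.12g", s$wavelength_nm, s$value), con)
  invisible(path)
}

#' Read a wide multi-spectrum CSV
#'
#' First column wavelength, remaining named columns one spectrum each.
#'
#' @inheritParams read_spd
#' @return A named list of [spd()] objects.
#' @export
read_spd_table <- function(path, quantity = c("irradiance", "radiance")) {
  quantity <- match.arg(quantity)
  dat <- utils::read.csv(path, comment.char = "#")
  if (ncol(dat) < 2L)
    stop_melanophot("wide spectrum file needs wavelength + >=1 value column",
                    "melanophot_format_error")
  wl <- dat[[1L]]
  out <- lapply(names(dat)[-1L], function(nm)
    spd(wl, dat[[nm]], quantity = quantity, label = nm))
  names(out) <- names(dat)[-1L]
  out
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation inside the measured support; exactly zero outside it
#' (a physical source emits nothing where it was not measured). Grid points
#' shared with the source map to their own values, so resampling onto the
#' source's own grid is the identity.
#'
#' @param s An [spd()] object.
#' @param grid_nm Strictly increasing target wavelengths (nm).
#' @return An [spd()] on `grid_nm`.
#' @export
spd_resample <- function(s, grid_nm) {
  assert_spd(s)
  if (!length(grid_nm))
    stop_melanophot("target grid is empty", "melanophot_validation_error")
  if (any(diff(grid_nm) <= 0))
    stop_melanophot("target grid must be strictly increasing",
                    "melanophot_validation_error")
  v <- stats::approx(s$wavelength_nm, s$value, xout = grid_nm,
                     method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  spd(grid_nm, v, quantity = s$quantity, label = s$label)
}

uniform_step <- function(wl) {
  d <- diff(wl)
  if (max(d) - min(d) > 1e-9 * mean(d)) return(NA_real_)
  mean(d)
}

#' Integrate a spectrum over wavelength
#'
#' Rectangular (delta-lambda weighted) summation on a uniform grid, matching
#' CIE tabulated-summation practice. Resample first if the grid is not
#' uniform.
#'
#' @param s An [spd()] object on a uniform grid.
#' @return Total flux: W m^-2 (irradiance) or W m^-2 sr^-1 (radiance).
#' @export
spd_integrate <- function(s) {
  assert_spd(s)
  step <- uniform_step(s$wavelength_nm)
  if (is.na(step))
    stop_melanophot("spectrum grid is not uniform; spd_resample() it first",
                    "melanophot_validation_error")
  step * sum(s$value)
}

#' Scale a spectrum by a nonnegative factor
#' @param s An [spd()] object.
#' @param c Nonnegative scalar.
#' @return The pointwise-scaled [spd()].
#' @export
spd_scale <- function(s, c) {
  assert_spd(s)
  check_number(c, "c", lower = 0)
  spd(s$wavelength_nm, c * s$value, quantity = s$quantity, label = s$label)
}

#' Add two spectra defined on the same grid
#' @param a,b [spd()] objects with identical grids and quantity tags.
#' @return Their pointwise sum.
#' @export
spd_add <- function(a, b) {
  assert_spd(a); assert_spd(b)
  if (length(a$wavelength_nm) != length(b$wavelength_nm) ||
      any(a$wavelength_nm != b$wavelength_nm))
    stop_melanophot("spectra are on different wavelength grids",
                    "melanophot_validation_error")
  if (a$quantity != b$quantity)
    stop_melanophot("cannot add irradiance and radiance spectra",
                    "melanophot_unit_error")
  spd(a$wavelength_nm, a$value + b$value, quantity = a$quantity,
      label = a$label)
}
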