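# CIE S 026 alpha-opic photometry: irradiances, illuminance, equivalent
# daylight illuminances (EDIs) and daylight efficacy ratios (DERs).

to_canonical <- function(s) {
  grid <- canonical_grid()
  if (length(s$wavelength_nm) == length(grid) &&
      all(s$wavelength_nm == grid)) return(s)
  spd_resample(s, grid)
}

#' Alpha-opic irradiance
#'
#' Corneal irradiance weighted by one (or several) photoreceptor spectral
#' sensitivity functions: `1000 * sum(E(lambda) * s_alpha(lambda)) * dlambda`
#' on the 1 nm canonical grid, in mW m^-2. Spectra not already on the
#' canonical grid are resampled to it.
#'
#' @param s An irradiance-tagged [spd()].
#' @param alpha Receptor tag(s), see [alpha_receptors()].
#' @return Named numeric vector of alpha-opic irradiances (mW m^-2).
#' @examples
#' line480 <- spd(c(479, 480, 481), c(0, 1, 0))
#' alpha_opic_irradiance(line480, "mel")
#' @export
alpha_opic_irradiance <- function(s, alpha = alpha_receptors()) {
  assert_spd(s, "irradiance")
  alpha <- match.arg(alpha, alpha_receptors(), several.ok = TRUE)
  s <- to_canonical(s)
  tab <- action_spectra()
  1000 * colSums(s$value * tab$sens[, alpha, drop = FALSE])
}

#' Alpha-opic radiance
#'
#' As [alpha_opic_irradiance()] but for radiance-tagged spectra; units
#' mW m^-2 sr^-1.
#'
#' @param s A radiance-tagged [spd()].
#' @inheritParams alpha_opic_irradiance
#' @return Named numeric vector (mW m^-2 sr^-1).
#' @export
alpha_opic_radiance <- function(s, alpha = alpha_receptors()) {
  assert_spd(s, "radiance")
  alpha <- match.arg(alpha, alpha_receptors(), several.ok = TRUE)
  s <- to_canonical(s)
  tab <- action_spectra()
  1000 * colSums(s$value * tab$sens[, alpha, drop = FALSE])
}

#' Photopic illuminance
#'
#' `683 * sum(E(lambda) * V(lambda)) * dlambda` in lux. One watt of
#' monochromatic 555 nm irradiance per square metre gives 683 lx by the
#' definition of the lumen.
#'
#' @param s An irradiance-tagged [spd()].
#' @return Illuminance (lx).
#' @export
photopic_illuminance <- function(s) {
  assert_spd(s, "irradiance")
  s <- to_canonical(s)
  683 * sum(s$value * action_spectra()$vlambda)
}

#' Photopic luminance
#'
#' The same V(lambda) kernel applied to a radiance spectrum, in cd m^-2.
#'
#' @param s A radiance-tagged [spd()].
#' @return Luminance (cd m^-2).
#' @export
photopic_luminance <- function(s) {
  assert_spd(s, "radiance")
  s <- to_canonical(s)
  683 * sum(s$value * action_spectra()$vlambda)
}

#' Daylight (D65) efficacy derived from the embedded tables
#'
#' The alpha-opic irradiance of D65 per lux of D65 (mW/lm), computed from
#' the embedded D65 spectrum and action spectra. Independent of the D65
#' normalisation. The EDI conversion [alpha_opic_edi()] divides by this
#' constant. Compare with the published values in
#' [s026_daylight_efficacy()].
#'
#' @inheritParams s026_daylight_efficacy
#' @return Named numeric vector, mW/lm.
#' @export
d65_efficacy <- function(alpha = alpha_receptors()) {
  alpha <- match.arg(alpha, alpha_receptors(), several.ok = TRUE)
  d65 <- d65_spd()
  alpha_opic_irradiance(d65, alpha) / photopic_illuminance(d65)
}

#' Alpha-opic equivalent daylight illuminance (EDI)
#'
#' The illuminance of a D65 spectrum producing the same alpha-opic
#' irradiance as the test light: `E_alpha / K_alpha`, in lux. For
#' `alpha = "mel"` this is the melanopic EDI (mEDI).
#'
#' @param e_alpha Alpha-opic irradiance(s), mW m^-2.
#' @param alpha A single receptor tag.
#' @param efficacy The daylight efficacy constant to divide by; defaults to
#'   the table-derived [d65_efficacy()].
#' @return EDI in lux, same length as `e_alpha`.
#' @examples
#' alpha_opic_edi(4.91, "mel")   # ~3.70 lx
#' @export
alpha_opic_edi <- function(e_alpha, alpha = "mel",
                           efficacy = d65_efficacy(alpha)) {
  alpha <- match.arg(alpha, alpha_receptors())
  if (!is.numeric(e_alpha) || any(!is.finite(e_alpha)) || any(e_alpha < 0))
    stop_melanophot("alpha-opic irradiance must be finite and nonnegative",
                    "melanophot_validation_error")
  unname(e_alpha / efficacy)
}

#' Full alpha-opic report for a spectrum
#'
#' All five alpha-opic irradiances, the photopic illuminance, the five
#' alpha-opic EDIs and the five daylight efficacy ratios
#' (DER = EDI / illuminance) for one irradiance spectrum -- the row set of a
#' light-characterisation table. DERs are `NA` (undefined) for a zero
#' spectrum rather than infinite.
#'
#' @param s An irradiance-tagged [spd()].
#' @return An object of class `"alpha_opic_report"`; a list with
#'   `irradiance_mw_m2`, `illuminance_lx`, `edi_lx`, `der` (each a named
#'   five-vector except the scalar illuminance) and `label`.
#' @export
full_report <- function(s) {
  assert_spd(s, "irradiance")
  e <- alpha_opic_irradiance(s)
  ill <- photopic_illuminance(s)
  edi <- e / d65_efficacy()
  der <- if (ill > 0) edi / ill else rep(NA_real_, 5L)
  names(der) <- alpha_receptors()
  structure(list(irradiance_mw_m2 = e, illuminance_lx = ill, edi_lx = edi,
                 der = der, label = s$label),
            class = "alpha_opic_report")
}

#' @export
print.alpha_opic_report <- function(x, digits = 2, ...) {
  cat(sprintf("Alpha-opic report%s\n",
              if (nzchar(x$label)) paste0(": ", x$label) else ""))
  cat(sprintf("  Photopic illuminance: %.*f lx\n", digits, x$illuminance_lx))
  m <- rbind(`irradiance (mW/m2)` = x$irradiance_mw_m2,
             `EDI (lx)` = x$edi_lx,
             `DER` = x$der)
  print(round(m, digits), ...)
  invisible(x)
}

#' @export
as.data.frame.alpha_opic_report <- function(x, ...) {
  data.frame(receptor = alpha_receptors(),
             irradiance_mw_m2 = unname(x$irradiance_mw_m2),
             edi_lx = unname(x$edi_lx),
             der = unname(x$der),
             illuminance_lx = x$illuminance_lx,
             label = x$label,
             row.names = NULL)
}
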