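# Retinal dose: conventional and alpha-opic trolands from corneal
# photometry plus pupil geometry. Retinal irradiance cannot be measured
# directly; the troland convention multiplies a photometric surface quantity
# by the pupil area admitting the light.

#' Conventional retinal illuminance (trolands)
#'
#' `luminance (cd m^-2) x pupil area (mm^2)`.
#'
#' @param luminance_cd_m2 Source luminance, >= 0.
#' @param pupil_area_mm2 Pupil area, >= 0 (see [diameter_to_area()]).
#' @return Retinal illuminance in trolands (Td); vectorised.
#' @examples
#' conventional_trolands(27.43, diameter_to_area(5))
#' @export
conventional_trolands <- function(luminance_cd_m2, pupil_area_mm2) {
  if (any(!is.finite(luminance_cd_m2)) || any(luminance_cd_m2 < 0) ||
      any(!is.finite(pupil_area_mm2)) || any(pupil_area_mm2 < 0))
    stop_melanophot("luminance and pupil area must be nonnegative",
                    "melanophot_validation_error")
  luminance_cd_m2 * pupil_area_mm2
}

#' Alpha-opic retinal irradiance ("alpha-opic trolands")
#'
#' Alpha-opic radiance times pupil area, generalising the conventional
#' troland to the five photoreceptor classes; units
#' mW m^-2 sr^-1 mm^2, used for *relative* comparisons (log-dose
#' regressions), where the unit convention cancels. Accepts a radiance
#' spectrum directly, or an irradiance spectrum from a uniform extended
#' source together with its solid angle (`L = E / omega`).
#'
#' @param s An [spd()]; radiance-tagged, or irradiance-tagged with
#'   `solid_angle_sr` supplied.
#' @param pupil_area_mm2 Pupil area (mm^2), >= 0.
#' @param alpha Receptor tag(s).
#' @param solid_angle_sr Solid angle of the source (sr); required for
#'   irradiance input (see [screen_solid_angle()]).
#' @return Named vector of alpha-opic retinal doses.
#' @export
alpha_opic_trolands <- function(s, pupil_area_mm2,
                                alpha = alpha_receptors(),
                                solid_angle_sr = NULL) {
  assert_spd(s)
  check_number(pupil_area_mm2, "pupil_area_mm2", lower = 0)
  if (s$quantity == "irradiance") {
    if (is.null(solid_angle_sr))
      stop_melanophot("irradiance input needs `solid_angle_sr` to derive radiance",
                      "melanophot_unit_error")
    check_number(solid_angle_sr, "solid_angle_sr", lower = 0, strict = TRUE)
    s <- spd(s$wavelength_nm, s$value / solid_angle_sr,
             quantity = "radiance", label = s$label)
  }
  alpha_opic_radiance(s, alpha) * pupil_area_mm2
}

#' Solid angle subtended by a flat screen
#'
#' Small-angle approximation `width x height / distance^2` for a viewer on
#' the screen axis; the default is a 27-inch 16:9 display at 60 cm.
#'
#' @param width_m,height_m Screen size (m).
#' @param distance_m Viewing distance (m).
#' @return Solid angle (sr).
#' @export
screen_solid_angle <- function(width_m = 0.598, height_m = 0.336,
                               distance_m = 0.60) {
  check_number(width_m, "width_m", lower = 0, strict = TRUE)
  check_number(height_m, "height_m", lower = 0, strict = TRUE)
  check_number(distance_m, "distance_m", lower = 0, strict = TRUE)
  width_m * height_m / distance_m^2
}

#' Base-10 logarithm of a positive dose
#'
#' Light doses are analysed on the log10 scale; nonpositive doses are a
#' hard domain error (flagged, never silently offset or dropped).
#'
#' @param x Positive dose value(s).
#' @return `log10(x)`.
#' @export
log10_dose <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop_melanophot("log10 dose undefined for nonpositive values",
                    "melanophot_domain_error")
  log10(x)
}
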