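#' Published light-condition table of the metameric screen study
#'
#' The eight calibrated screen conditions of the 4-intensity-group x
#' 2-condition (low/high melanopic, LM/HM) evening light exposure study this
#' package emulates: luminance, the five measured alpha-opic irradiances and
#' the melanopic EDI, as printed in the study's light-characterisation
#' table. These values are *inputs* (measured device calibration data); they
#' drive the synthetic-study defaults and the reproduction checks.
#'
#' @return A data.frame with one row per condition: `condition`, `group`
#'   (intensity group 1--4), `arm` (`"LM"`/`"HM"`), `luminance_cd_m2`,
#'   `sc`, `mc`, `lc`, `rh`, `mel` (alpha-opic irradiances, mW m^-2) and
#'   `medi_lx` (printed melanopic EDI).
#' @examples
#' cond <- study_conditions()
#' # melanopsin contrast per intensity group from the printed irradiances
#' with(cond, mel[arm == "HM"] / mel[arm == "LM"] - 1) * 100
#' @export
study_conditions <- function() {
  data.frame(
    condition = c("LM1", "HM1", "LM2", "HM2", "LM3", "HM3", "LM4", "HM4"),
    group = rep(1:4, each = 2),
    arm = rep(c("LM", "HM"), 4),
    luminance_cd_m2 = c(27.43, 27.41, 62.93, 61.39, 135.03, 133, 283.74, 284.5),
    sc = c(6.40, 6.22, 13.87, 13.72, 29.58, 29.71, 60.21, 62.00),
    mc = c(11.19, 11.74, 25.52, 25.43, 55.08, 54.79, 116.58, 115.12),
    lc = c(13.32, 13.50, 29.95, 30.09, 64.90, 64.78, 138.10, 138.86),
    rh = c(6.87, 18.70, 16.47, 40.39, 38.09, 86.81, 87.00, 180.89),
    mel = c(4.91, 20.11, 11.70, 43.51, 27.46, 93.27, 64.17, 193.62),
    medi_lx = c(3.70, 15.17, 8.82, 32.81, 20.70, 70.33, 48.39, 146.00)
  )
}
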