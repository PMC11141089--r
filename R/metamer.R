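# Silent-substitution metamer design for multiprimary devices: cone-matched
# (sc, mc, lc) spectral pairs differing maximally in melanopsin excitation.

#' Multiprimary light source
#'
#' A device made of several independently drivable primaries (e.g. LED
#' channels), each given as its spectrum at full drive; drive weights live in
#' `[0, 1]`. Primaries are resampled to the canonical grid on construction.
#'
#' @param primaries A list of irradiance-tagged [spd()] objects (the corneal
#'   spectrum of each primary at full drive).
#' @param labels Optional character labels (default: the spectra's labels).
#' @return An object of class `"multiprimary_device"`.
#' @seealso [gaussian_device()], [receptor_matrix()], [solve_weights()]
#' @export
multiprimary_device <- function(primaries, labels = NULL) {
  if (!is.list(primaries) || length(primaries) < 1L)
    stop_melanophot("`primaries` must be a non-empty list of spectra",
                    "melanophot_validation_error")
  primaries <- lapply(primaries, function(p) {
    assert_spd(p, "irradiance")
    to_canonical(p)
  })
  if (is.null(labels)) labels <- vapply(primaries, `[[`, "", "label")
  if (any(!nzchar(labels))) labels <- paste0("P", seq_along(primaries))
  structure(list(primaries = primaries, labels = as.character(labels)),
            class = "multiprimary_device")
}

#' @export
print.multiprimary_device <- function(x, ...) {
  cat(sprintf("<multiprimary_device> %d primaries: %s\n",
              length(x$primaries), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Gaussian model primary
#'
#' A Gaussian-shaped LED spectral model, the standard stand-in when a
#' device's measured primary spectra are unavailable.
#'
#' @param peak_nm Peak wavelength (nm).
#' @param fwhm_nm Full width at half maximum (nm).
#' @param peak_w_m2_nm Spectral irradiance at the peak (W m^-2 nm^-1).
#' @return An irradiance-tagged [spd()] on the canonical grid.
#' @export
gaussian_primary <- function(peak_nm, fwhm_nm = 30, peak_w_m2_nm = 1) {
  check_number(peak_nm, "peak_nm", lower = 0, strict = TRUE)
  check_number(fwhm_nm, "fwhm_nm", lower = 0, strict = TRUE)
  check_number(peak_w_m2_nm, "peak_w_m2_nm", lower = 0)
  grid <- canonical_grid()
  v <- peak_w_m2_nm * exp(-4 * log(2) * ((grid - peak_nm) / fwhm_nm)^2)
  spd(grid, v, quantity = "irradiance", label = sprintf("%g nm", peak_nm))
}

#' Five-channel Gaussian model device
#'
#' A Gaussian-primary model of a five-LED display with the dominant
#' wavelengths used in the metameric screen study (430, 480, 500, 550,
#' 630 nm). The 30 nm default width makes the model device's achievable
#' melanopsin contrast match the 200--300% range the physical screen
#' realised (see the methods vignette).
#'
#' @param peaks_nm Peak wavelengths of the channels.
#' @param fwhm_nm FWHM, recycled over channels.
#' @param peak_w_m2_nm Peak spectral irradiance, recycled.
#' @return A [multiprimary_device()].
#' @export
gaussian_device <- function(peaks_nm = c(430, 480, 500, 550, 630),
                            fwhm_nm = 30, peak_w_m2_nm = 1) {
  fwhm_nm <- rep_len(fwhm_nm, length(peaks_nm))
  peak_w_m2_nm <- rep_len(peak_w_m2_nm, length(peaks_nm))
  multiprimary_device(Map(gaussian_primary, peaks_nm, fwhm_nm, peak_w_m2_nm))
}

#' Receptor response matrix of a device
#'
#' Entry `[r, p]` is the alpha-opic irradiance of primary `p` at full drive
#' for receptor `r`; by linearity, the receptor response of any mixture is
#' `receptor_matrix %*% weights`.
#'
#' @param device A [multiprimary_device()].
#' @param receptors Ordered receptor tags (rows).
#' @return A `length(receptors)` x n-primaries matrix (mW m^-2 at full
#'   drive), with dimnames.
#' @export
receptor_matrix <- function(device, receptors = c("sc", "mc", "lc")) {
  if (!inherits(device, "multiprimary_device"))
    stop_melanophot("`device` must be a multiprimary_device",
                    "melanophot_validation_error")
  receptors <- match.arg(receptors, alpha_receptors(), several.ok = TRUE)
  m <- vapply(device$primaries,
              function(p) alpha_opic_irradiance(p, receptors),
              numeric(length(receptors)))
  m <- matrix(m, nrow = length(receptors),
              dimnames = list(receptors, device$labels))
  m
}

resolve_subset <- function(device, subset) {
  if (is.character(subset)) subset <- match(subset, device$labels)
  subset <- as.integer(subset)
  if (anyNA(subset) || any(subset < 1L | subset > length(device$primaries)))
    stop_melanophot("primary subset refers to unknown primaries",
                    "melanophot_validation_error")
  subset
}

#' Solve drive weights reproducing a cone-opic target
#'
#' Direct 3x3 linear solve: find weights on a three-primary subset (zero on
#' all other primaries) whose mixture reproduces the target S-, M- and
#' L-cone-opic irradiances exactly. Errors if the subset's cone matrix is
#' numerically singular or if any solved weight leaves the `[0, 1]` drive
#' range (naming the violating primary).
#'
#' @param device A [multiprimary_device()].
#' @param subset Three primary indices or labels.
#' @param target Numeric length-3 target `(sc, mc, lc)` irradiances,
#'   mW m^-2, componentwise nonnegative.
#' @return Full-length weight vector (named by primary label).
#' @export
solve_weights <- function(device, subset, target) {
  subset <- resolve_subset(device, subset)
  if (length(subset) != 3L)
    stop_melanophot("`subset` must name exactly 3 primaries",
                    "melanophot_validation_error")
  target <- as.numeric(target)
  if (length(target) != 3L || any(!is.finite(target)) || any(target < 0))
    stop_melanophot("`target` must be 3 nonnegative cone-opic irradiances",
                    "melanophot_validation_error")
  m <- receptor_matrix(device)[, subset, drop = FALSE]
  if (rcond(m) < 1e-12)
    stop_melanophot("cone response matrix of the subset is singular (degenerate primaries)",
                    "melanophot_degeneracy_error")
  w3 <- solve(m, target)
  w3[abs(w3) < 1e-12] <- 0
  slack <- 1e-12
  if (any(w3 < -slack | w3 > 1 + slack)) {
    bad <- which(w3 < -slack | w3 > 1 + slack)[1L]
    stop_melanophot(
      sprintf("target outside device gamut: primary '%s' needs drive %.4g",
              device$labels[subset[bad]], w3[bad]),
      "melanophot_gamut_error")
  }
  w <- numeric(length(device$primaries))
  names(w) <- device$labels
  w[subset] <- pmin(pmax(w3, 0), 1)
  w
}

#' Mixture spectrum of a device at given weights
#'
#' @param device A [multiprimary_device()].
#' @param weights Drive fractions in `[0, 1]`, one per primary.
#' @return The summed irradiance [spd()].
#' @export
mix_spectrum <- function(device, weights) {
  if (length(weights) != length(device$primaries))
    stop_melanophot("one weight per primary required",
                    "melanophot_validation_error")
  grid <- canonical_grid()
  v <- numeric(length(grid))
  for (i in seq_along(weights))
    v <- v + weights[[i]] * device$primaries[[i]]$value
  spd(grid, v, quantity = "irradiance", label = "mixture")
}

#' Melanopsin (Michelson-free) contrast between two conditions
#'
#' `(E_HM - E_LM) / E_LM * 100`, in percent. Unit-invariant: identical
#' whether computed on melanopic irradiances or melanopic EDIs.
#'
#' @param e_hm,e_lm Melanopic quantities of the high- and low-melanopic
#'   member in the same unit; `e_lm` must be positive.
#' @return Contrast in percent (vectorised).
#' @examples
#' melanopsin_contrast(20.11, 4.91)  # ~310 %
#' @export
melanopsin_contrast <- function(e_hm, e_lm) {
  if (any(!is.finite(e_lm)) || any(e_lm <= 0))
    stop_melanophot("contrast undefined: low-melanopic reference must be > 0",
                    "melanophot_validation_error")
  unname((e_hm - e_lm) / e_lm * 100)
}

#' Design a cone-matched metamer pair
#'
#' Solves the silent-substitution problem for two fixed three-primary
#' subsets: both mixtures reproduce the same S/M/L cone-opic target, while
#' the melanopic irradiances differ. Rod (rhodopic) excitation is reported
#' but deliberately unconstrained.
#'
#' @param device A [multiprimary_device()].
#' @param subset_lm,subset_hm Three primary indices/labels for the low- and
#'   high-melanopic member.
#' @param target_cones Length-3 `(sc, mc, lc)` cone-opic target, mW m^-2.
#' @return An object of class `"metamer_pair"`: weights, mixture spectra,
#'   full alpha-opic reports for both members, `contrast_mel` (%), and
#'   `cone_residual` (max relative S/M/L mismatch between the members).
#' @examples
#' dev <- gaussian_device()
#' pair <- design_metamer_pair(dev, c("430 nm", "550 nm", "630 nm"),
#'                             c("480 nm", "500 nm", "630 nm"),
#'                             target_cones = c(6.40, 11.19, 13.32))
#' pair$contrast_mel
#' @export
design_metamer_pair <- function(device, subset_lm, subset_hm, target_cones) {
  w_lm <- solve_weights(device, subset_lm, target_cones)
  w_hm <- solve_weights(device, subset_hm, target_cones)
  s_lm <- mix_spectrum(device, w_lm)
  s_hm <- mix_spectrum(device, w_hm)
  s_lm$label <- "LM"; s_hm$label <- "HM"
  rep_lm <- full_report(s_lm)
  rep_hm <- full_report(s_hm)
  cones <- c("sc", "mc", "lc")
  a <- rep_lm$irradiance_mw_m2[cones]
  b <- rep_hm$irradiance_mw_m2[cones]
  denom <- pmax(abs(a), abs(b), .Machine$double.eps)
  residual <- max(abs(a - b) / denom)
  structure(list(
    weights_lm = w_lm, weights_hm = w_hm,
    spd_lm = s_lm, spd_hm = s_hm,
    achieved_lm = rep_lm, achieved_hm = rep_hm,
    contrast_mel = melanopsin_contrast(rep_hm$irradiance_mw_m2[["mel"]],
                                       rep_lm$irradiance_mw_m2[["mel"]]),
    cone_residual = residual,
    target_cones = stats::setNames(as.numeric(target_cones), cones)),
    class = "metamer_pair")
}

#' @export
print.metamer_pair <- function(x, ...) {
  cat("<metamer_pair>\n")
  cat(sprintf("  melanopsin contrast: %.1f %%   cone residual: %.2e\n",
              x$contrast_mel, x$cone_residual))
  w <- rbind(LM = x$weights_lm, HM = x$weights_hm)
  cat("  drive weights:\n")
  print(round(w, 4))
  m <- rbind(LM = x$achieved_lm$irradiance_mw_m2,
             HM = x$achieved_hm$irradiance_mw_m2)
  cat("  alpha-opic irradiances (mW/m2):\n")
  print(round(m, 2))
  invisible(x)
}

#' Maximise melanopsin contrast of a metamer pair
#'
#' Melanopsin contrast of a cone-matched pair is invariant to rescaling the
#' cone target, so the maximisation runs over the *direction* of the cone
#' target: every LM-feasible target is `M_LM %*% w` for LM-subset drives
#' `w` on the unit simplex, and the contrast of the induced pair is
#' maximised over that simplex (coarse grid then Nelder-Mead refinement),
#' subject to the HM solution staying inside the drive gamut. The returned
#' pair is then scaled along the gamut: to the largest feasible intensity,
#' or to `illuminance_lx` if given (gamut error if infeasible). The weight
#' that reaches full drive first (the binding constraint) is reported.
#'
#' @param device A [multiprimary_device()].
#' @param subset_lm,subset_hm Three-primary subsets as in
#'   [design_metamer_pair()].
#' @param illuminance_lx Optional photopic illuminance (lx) both members
#'   should reach; `NULL` scales to the gamut boundary.
#' @param grid_n Resolution of the simplex grid scan.
#' @return A `"metamer_pair"` with extra fields `binding_primary` (label of
#'   the weight at the gamut boundary) and `scale` (the applied intensity
#'   scale).
#' @export
maximize_melanopsin_contrast <- function(device, subset_lm = NULL,
                                         subset_hm = NULL,
                                         illuminance_lx = NULL,
                                         grid_n = 40) {
  if (is.null(subset_lm) || is.null(subset_hm))
    stop_melanophot("both primary subsets must be given",
                    "melanophot_validation_error")
  i_lm <- resolve_subset(device, subset_lm)
  i_hm <- resolve_subset(device, subset_hm)
  rm_all <- receptor_matrix(device, c("sc", "mc", "lc", "mel"))
  m_lm <- rm_all[1:3, i_lm, drop = FALSE]
  m_hm <- rm_all[1:3, i_hm, drop = FALSE]
  if (rcond(m_hm) < 1e-12 || rcond(m_lm) < 1e-12)
    stop_melanophot("singular cone matrix in a subset",
                    "melanophot_degeneracy_error")
  mel_lm <- rm_all["mel", i_lm]
  mel_hm <- rm_all["mel", i_hm]
  m_hm_inv <- solve(m_hm)
  contrast_of <- function(w) {
    # w: LM-subset drives (>= 0, not all 0); returns % contrast or -Inf
    if (any(w < 0) || sum(w) <= 0) return(-Inf)
    wh <- m_hm_inv %*% (m_lm %*% w)
    if (any(wh < -1e-12)) return(-Inf)
    100 * (sum(mel_hm * wh) / sum(mel_lm * w) - 1)
  }
  # coarse barycentric scan of the simplex
  best <- -Inf; w_best <- NULL
  fr <- seq(0, 1, length.out = grid_n + 1L)
  for (a in fr) for (b in fr[fr <= 1 - a + 1e-12]) {
    w <- c(a, b, 1 - a - b)
    v <- contrast_of(w)
    if (v > best) { best <- v; w_best <- w }
  }
  if (!is.finite(best))
    stop_melanophot("no cone direction is jointly feasible for the subsets",
                    "melanophot_gamut_error")
  # refine (penalised Nelder-Mead on the first two coordinates)
  obj <- function(p) {
    w <- c(p, 1 - sum(p))
    v <- contrast_of(w)
    if (!is.finite(v)) return(1e6)
    -v
  }
  opt <- stats::optim(w_best[1:2], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  if (-opt$value > best) w_best <- c(opt$par, 1 - sum(opt$par))
  w_best <- pmax(w_best, 0)

  target <- as.numeric(m_lm %*% w_best)
  # scale the target into the gamut (contrast is scale-invariant)
  w_lm3 <- as.numeric(solve(m_lm, target))
  w_hm3 <- as.numeric(m_hm_inv %*% target)
  peak <- max(c(w_lm3, w_hm3))
  scale <- 1 / peak
  if (!is.null(illuminance_lx)) {
    check_number(illuminance_lx, "illuminance_lx", lower = 0, strict = TRUE)
    w_full <- numeric(length(device$primaries)); w_full[i_lm] <- w_lm3
    ill1 <- photopic_illuminance(mix_spectrum(device, w_full))
    need <- illuminance_lx / ill1
    if (need > scale * (1 + 1e-12))
      stop_melanophot(sprintf(
        "illuminance %.4g lx outside gamut (max feasible %.4g lx)",
        illuminance_lx, ill1 * scale), "melanophot_gamut_error")
    scale <- need
  }
  pair <- design_metamer_pair(device, i_lm, i_hm, target * scale)
  binding <- c(pair$weights_lm, pair$weights_hm)
  pair$binding_primary <- names(binding)[which.max(binding)]
  pair$scale <- scale
  pair
}
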