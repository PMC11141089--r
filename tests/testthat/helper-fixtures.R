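# Shared fixtures: analytic spectra and toy devices built in code.

# spectrum that is `value` at a single canonical-grid wavelength, 0 elsewhere
delta_spd <- function(at_nm, value = 1, quantity = "irradiance") {
  grid <- canonical_grid()
  v <- numeric(length(grid))
  v[grid == at_nm] <- value
  spd(grid, v, quantity = quantity, label = sprintf("delta %d nm", at_nm))
}

flat_spd <- function(value = 1, quantity = "irradiance") {
  grid <- canonical_grid()
  spd(grid, rep(value, length(grid)), quantity = quantity, label = "flat")
}

# random full-rank three-primary device (Gaussian-shaped, random peaks/widths)
random_device <- function() {
  repeat {
    peaks <- sort(stats::runif(3, 420, 650))
    if (min(diff(peaks)) > 25) break
  }
  gaussian_device(peaks_nm = peaks,
                  fwhm_nm = stats::runif(3, 15, 40),
                  peak_w_m2_nm = stats::runif(3, 0.5, 2))
}

# independent 3x3 solve via the explicit adjugate inverse (no solve())
inverse_3x3 <- function(m) {
  cof <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    cof[i, j] <- (-1)^(i + j) * det(m[-i, -j, drop = FALSE])
  t(cof) / det(m)
}

# direct-summation alpha-opic oracle (bypasses alpha_opic_irradiance)
oracle_alpha <- function(s, alpha) {
  tab <- action_spectra()
  v <- spd_resample(s, tab$grid)$value
  1000 * sum(v * tab$sens[, alpha])
}
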