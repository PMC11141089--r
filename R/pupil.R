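# Pupillometry preprocessing: artifact filtering, per-part median binning,
# and data-quality exclusion, following the eye-tracker analysis conventions
# of steady-state pupil studies (3D-model diameters, 200 Hz nominal rate).

#' Pupillometry recording
#'
#' Time-ordered pupil samples of one test part: timestamps (s from part
#' start), 3D-model pupil diameter (mm) and detection confidence (0--1).
#'
#' @param t Nondecreasing sample timestamps (s).
#' @param diameter_mm Pupil diameters (mm); may contain implausible values
#'   (blinks) which [filter_samples()] removes.
#' @param confidence Detection confidence in `[0, 1]`.
#' @param subject,session,part Labels (session is typically `"LM"`/`"HM"`).
#' @param expected_rate_hz Nominal sampling rate of the instrument.
#' @param duration_s Nominal duration of the part; defaults to the last
#'   timestamp. Used as the denominator basis for data-quality fractions,
#'   so storage dropouts count against quality.
#' @return An object of class `"pupil_recording"`.
#' @export
pupil_recording <- function(t, diameter_mm, confidence,
                            subject = "S01", session = "LM", part = "P1",
                            expected_rate_hz = 200,
                            duration_s = if (length(t)) max(t) else 0) {
  n <- length(t)
  if (length(diameter_mm) != n || length(confidence) != n)
    stop_melanophot("t, diameter_mm and confidence must have equal length",
                    "melanophot_validation_error")
  if (n && (anyNA(t) || any(!is.finite(t))))
    stop_melanophot("timestamps must be finite", "melanophot_validation_error")
  if (n && any(diff(t) < 0))
    stop_melanophot("timestamps must be nondecreasing",
                    "melanophot_validation_error")
  if (n && (any(confidence < 0 | confidence > 1, na.rm = TRUE)))
    stop_melanophot("confidence must lie in [0, 1]",
                    "melanophot_validation_error")
  check_number(expected_rate_hz, "expected_rate_hz", lower = 0, strict = TRUE)
  structure(list(
    samples = data.frame(t = as.numeric(t),
                         diameter_mm = as.numeric(diameter_mm),
                         confidence = as.numeric(confidence)),
    subject = subject, session = session, part = part,
    expected_rate_hz = expected_rate_hz,
    duration_s = as.numeric(duration_s)),
    class = "pupil_recording")
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf("<pupil_recording> %s/%s/%s: %d samples over %.1f s (nominal %g Hz)\n",
              x$subject, x$session, x$part, nrow(x$samples), x$duration_s,
              x$expected_rate_hz))
  invisible(x)
}

#' Remove blink and artifact samples
#'
#' Retains exactly the samples with confidence >= 0.6 and diameter within
#' `[2, 10]` mm; samples with confidence < 0.6, diameter < 2 mm or
#' diameter > 10 mm are excluded (strict inequalities: the boundary values
#' 0.6, 2 mm and 10 mm are kept). Idempotent.
#'
#' @param rec A [pupil_recording()].
#' @param min_confidence,min_mm,max_mm Exclusion thresholds.
#' @return The filtered [pupil_recording()] (possibly with zero samples).
#' @export
filter_samples <- function(rec, min_confidence = 0.6, min_mm = 2,
                           max_mm = 10) {
  if (!inherits(rec, "pupil_recording"))
    stop_melanophot("`rec` must be a pupil_recording",
                    "melanophot_validation_error")
  s <- rec$samples
  keep <- s$confidence >= min_confidence &
    s$diameter_mm >= min_mm & s$diameter_mm <= max_mm
  keep[is.na(keep)] <- FALSE
  rec$samples <- s[keep, , drop = FALSE]
  rownames(rec$samples) <- NULL
  rec
}

#' Median pupil diameter per time bin
#'
#' Reduces a (filtered) recording to the median diameter of consecutive
#' bins (default one 20-min bin, the analysis unit of steady-state pupil
#' protocols). Even-count medians are the mean of the two central values
#' ([stats::median()]). `fraction_valid` is the number of surviving samples
#' over the *expected* count (`bin duration x expected_rate_hz`), so both
#' artifact losses and storage dropouts lower it. A bin with zero valid
#' samples is returned excluded with an `NA` median.
#'
#' @param rec A [pupil_recording()], already passed through
#'   [filter_samples()].
#' @param bin_minutes Bin length in minutes.
#' @return A data.frame of class `"binned_pupil"`: `subject`, `session`,
#'   `part`, `bin`, `median_diameter_mm`, `n_valid`, `fraction_valid`,
#'   `excluded`, `reason`.
#' @export
bin_median <- function(rec, bin_minutes = 20) {
  if (!inherits(rec, "pupil_recording"))
    stop_melanophot("`rec` must be a pupil_recording",
                    "melanophot_validation_error")
  check_number(bin_minutes, "bin_minutes", lower = 0, strict = TRUE)
  bin_s <- bin_minutes * 60
  dur <- max(rec$duration_s, if (nrow(rec$samples)) max(rec$samples$t) else 0)
  n_bins <- max(1L, ceiling((dur - 1e-9) / bin_s))
  idx <- pmin(floor(rec$samples$t / bin_s), n_bins - 1L)
  out <- lapply(seq_len(n_bins) - 1L, function(b) {
    d <- rec$samples$diameter_mm[idx == b]
    expected <- min(bin_s, max(dur - b * bin_s, 0)) * rec$expected_rate_hz
    n <- length(d)
    data.frame(subject = rec$subject, session = rec$session,
               part = rec$part, bin = b + 1L,
               median_diameter_mm = if (n) stats::median(d) else NA_real_,
               n_valid = n,
               fraction_valid = if (expected > 0) n / expected else 0,
               excluded = n == 0L,
               reason = if (n == 0L) "no_valid_samples" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("binned_pupil", "data.frame")
  out
}

#' Exclude bins with poor data quality
#'
#' Flags bins whose valid-sample fraction is below the threshold (strict
#' inequality: a bin at exactly the threshold is retained). All other rows
#' are untouched. The exclusion log is attached as the
#' `"exclusion_log"` attribute.
#'
#' @param bins A `"binned_pupil"` data.frame (rows may come from many
#'   recordings; `rbind` them).
#' @param min_fraction Quality threshold on `fraction_valid` (default 2%).
#' @return `bins` with `excluded`/`reason` updated.
#' @export
exclude_low_quality <- function(bins, min_fraction = 0.02) {
  if (!is.data.frame(bins) || is.null(bins$fraction_valid))
    stop_melanophot("`bins` must be a binned_pupil data.frame",
                    "melanophot_validation_error")
  low <- !bins$excluded & bins$fraction_valid < min_fraction
  bins$excluded[low] <- TRUE
  bins$reason[low] <- "low_quality"
  log <- bins[bins$excluded, c("subject", "session", "part", "bin",
                               "fraction_valid", "reason")]
  attr(bins, "exclusion_log") <- log
  bins
}

#' Pupil area from diameter
#'
#' @param diameter_mm Pupil diameter(s), mm, strictly positive.
#' @return Area(s) `pi * (d/2)^2` in mm^2.
#' @examples
#' diameter_to_area(5)  # 19.63 mm2
#' @export
diameter_to_area <- function(diameter_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0))
    stop_melanophot("pupil diameter must be positive",
                    "melanophot_validation_error")
  pi * (diameter_mm / 2)^2
}

#' Relative pupil-size increase between metameric conditions
#'
#' The percent increase of the low-melanopic pupil over the high-melanopic
#' pupil: `(d_LM - d_HM) / d_HM * 100`.
#'
#' @param d_lm,d_hm Pupil diameters (mm) under the low- and high-melanopic
#'   condition; `d_hm` must be positive.
#' @return Percent increase (vectorised).
#' @export
relative_increase <- function(d_lm, d_hm) {
  if (any(!is.finite(d_hm)) || any(d_hm <= 0))
    stop_melanophot("reference diameter must be > 0",
                    "melanophot_validation_error")
  (d_lm - d_hm) / d_hm * 100
}

#' Read an eye-tracker export into pupil recordings
#'
#' Delimited table with columns for timestamp, 3D diameter and confidence
#' (plus optional subject/session/part labels). Column names are mappable
#' to match different exports; one [pupil_recording()] is returned per
#' distinct subject/session/part combination.
#'
#' @param path CSV path.
#' @param columns Named character vector mapping the roles `t`, `diameter`,
#'   `confidence` (and optionally `subject`, `session`, `part`) to column
#'   names in the file.
#' @param expected_rate_hz Nominal instrument rate.
#' @return A list of [pupil_recording()] objects.
#' @export
read_pupil_csv <- function(path,
                           columns = c(t = "timestamp_s",
                                       diameter = "diameter_3d_mm",
                                       confidence = "confidence",
                                       subject = "subject",
                                       session = "session", part = "part"),
                           expected_rate_hz = 200) {
  dat <- utils::read.csv(path)
  need <- c("t", "diameter", "confidence")
  if (!all(need %in% names(columns)) ||
      !all(columns[need] %in% names(dat)))
    stop_melanophot("required pupil columns missing from file",
                    "melanophot_format_error")
  get <- function(role, default) {
    if (role %in% names(columns) && columns[[role]] %in% names(dat))
      dat[[columns[[role]]]] else rep(default, nrow(dat))
  }
  key <- paste(get("subject", "S01"), get("session", "LM"),
               get("part", "P1"), sep = "\r")
  idx <- split(seq_len(nrow(dat)), key)
  lapply(unname(idx), function(i) {
    pupil_recording(dat[[columns[["t"]]]][i],
                    dat[[columns[["diameter"]]]][i],
                    dat[[columns[["confidence"]]]][i],
                    subject = get("subject", "S01")[i][1L],
                    session = get("session", "LM")[i][1L],
                    part = get("part", "P1")[i][1L],
                    expected_rate_hz = expected_rate_hz)
  })
}
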