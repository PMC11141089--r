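# Synthetic-study generator: the full 4-intensity-group x 2-metameric-
# condition x 18-subject evening light exposure design, with known
# ground-truth dose-response structure, so every pipeline stage can be
# exercised end to end without any recorded data.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Steady-state pupil diameter model
#'
#' Log-logistic shrinkage of the sustained pupil diameter with melanopic
#' EDI: `d = d_min + (d_max - d_min) / (1 + (mEDI / e50)^hill)`. Over the
#' study's 3.7--146 lx range this is close to log-linear while saturating
#' sensibly outside it.
#'
#' @param medi_lx Melanopic EDI (lx), > 0.
#' @param d_max_mm,d_min_mm Diameter asymptotes in darkness / bright light.
#' @param e50_lx mEDI of half-maximal constriction.
#' @param hill Hill slope on the dose-ratio scale.
#' @return Steady-state diameter(s), mm.
#' @export
pupil_steady_state <- function(medi_lx, d_max_mm = 7, d_min_mm = 2,
                               e50_lx = 20, hill = 0.5) {
  if (any(medi_lx <= 0))
    stop_melanophot("mEDI must be positive", "melanophot_validation_error")
  if (d_min_mm >= d_max_mm)
    stop_melanophot("d_min must be below d_max", "melanophot_validation_error")
  d_min_mm + (d_max_mm - d_min_mm) / (1 + (medi_lx / e50_lx)^hill)
}

#' Dose-dependent melatonin suppression factor
#'
#' `s(dose) = 1 / (1 + (dose / s50)^hill)`: 1 at zero dose, exactly 0.5 at
#' `dose = s50`.
#'
#' @param dose Light dose (mEDI lx or melanopic Td), >= 0.
#' @param s50 Half-maximal suppression dose (same unit as `dose`).
#' @param hill Hill coefficient.
#' @return Suppression factor(s) in (0, 1].
#' @export
suppression_factor <- function(dose, s50, hill = 1) {
  if (any(dose < 0) || s50 <= 0)
    stop_melanophot("doses must be nonnegative and s50 positive",
                    "melanophot_validation_error")
  1 / (1 + (dose / s50)^hill)
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic study. Defaults
#' encode the emulated design: the eight published screen conditions
#' ([study_conditions()]), 18 subjects per intensity group, a steady-state
#' pupil model whose LM/HM diameter gaps fall in the observed 16--23% band,
#' blink/low-confidence artifact injection, and evening melatonin profiles
#' attenuated by a dose-dependent suppression factor. See the methods
#' vignette for the rationale behind each default.
#'
#' @param n_per_group Subjects per intensity group.
#' @param conditions Condition table in the [study_conditions()] layout.
#' @param pupil Named list overriding pupil-model defaults: `d_max_mm`,
#'   `d_min_mm`, `e50_lx`, `hill`, `subject_sd_mm` (between-subject diameter
#'   SD), `condition_offset_mm` (residual LM-HM offset beyond the melanopic
#'   effect), `ar_sd_mm`/`ar_coef` (AR(1) measurement noise, marginal SD and
#'   autocorrelation), `blink_rate_hz`, `blink_duration_s`, `low_conf_frac`,
#'   `rate_hz` (sampling rate used for generated traces; the 200 Hz
#'   instrument rate is decimatable), `part_minutes`, `n_parts`.
#' @param melatonin Named list overriding melatonin-model defaults:
#'   `peak_pg_ml`, `rise_midpoint_h`, `rise_rate`, `s50_corneal` (lx),
#'   `s50_retinal` (melanopic Td), `hill`, `noise_sd_log`,
#'   `subject_sd_log`, `sample_minutes`, `t_start_h`, `t_end_h`,
#'   `exposure_h` (light-exposure window, h relative to bedtime),
#'   `suppression_driver` (`"corneal"` or `"retinal"`).
#' @param solid_angle_sr Solid angle of the screen (for retinal doses).
#' @param seed Integer seed fixing the full dataset.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_per_group = 18, conditions = study_conditions(),
                       pupil = list(), melatonin = list(),
                       solid_angle_sr = screen_solid_angle(), seed = 1L) {
  p <- utils::modifyList(list(
    d_max_mm = 7, d_min_mm = 2, e50_lx = 20, hill = 0.5,
    subject_sd_mm = 0.4, condition_offset_mm = 0,
    ar_sd_mm = 0.15, ar_coef = 0.95,
    blink_rate_hz = 0.2, blink_duration_s = 0.3, low_conf_frac = 0.02,
    rate_hz = 10, part_minutes = 20, n_parts = 5), pupil)
  m <- utils::modifyList(list(
    peak_pg_ml = 20, rise_midpoint_h = -2, rise_rate = 2,
    s50_corneal = 30, s50_retinal = 600, hill = 1,
    noise_sd_log = 0.2, subject_sd_log = 0.3,
    sample_minutes = 30, t_start_h = -5, t_end_h = 0,
    exposure_h = c(-4, -0.5), suppression_driver = "corneal"), melatonin)
  if (p$d_min_mm >= p$d_max_mm)
    stop_melanophot("pupil d_min must be below d_max",
                    "melanophot_validation_error")
  for (nm in c("e50_lx", "hill", "rate_hz", "part_minutes"))
    check_number(p[[nm]], paste0("pupil$", nm), lower = 0, strict = TRUE)
  for (nm in c("subject_sd_mm", "ar_sd_mm", "blink_rate_hz",
               "blink_duration_s", "low_conf_frac"))
    check_number(p[[nm]], paste0("pupil$", nm), lower = 0)
  if (p$ar_coef < 0 || p$ar_coef >= 1)
    stop_melanophot("pupil ar_coef must lie in [0, 1)",
                    "melanophot_validation_error")
  for (nm in c("peak_pg_ml", "rise_rate", "s50_corneal", "s50_retinal",
               "hill"))
    check_number(m[[nm]], paste0("melatonin$", nm), lower = 0, strict = TRUE)
  for (nm in c("noise_sd_log", "subject_sd_log"))
    check_number(m[[nm]], paste0("melatonin$", nm), lower = 0)
  m$suppression_driver <- match.arg(m$suppression_driver,
                                    c("corneal", "retinal"))
  structure(list(n_per_group = as.integer(n_per_group),
                 conditions = conditions, pupil = p, melatonin = m,
                 solid_angle_sr = solid_angle_sr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one steady-state pupil trace
#'
#' A constant-adaptation pupil recording: the steady-state diameter for the
#' given melanopic EDI plus AR(1) measurement noise, contaminated with
#' Poisson blink events (runs of low-confidence samples with sub-2 mm
#' diameter excursions, flanked by out-of-range samples that keep high
#' confidence) and isolated low-confidence samples -- exercising every
#' clause of [filter_samples()]. Deterministic under `seed`.
#'
#' @param medi_lx Melanopic EDI of the adapting light (lx), > 0.
#' @param duration_s Trace duration (s).
#' @param rate_hz Sampling rate (Hz); the 200 Hz instrument rate is the
#'   natural choice for single traces, lower rates decimate.
#' @param pupil Pupil-parameter list as in [sim_config()] (defaults used
#'   for omitted entries).
#' @param diameter_offset_mm Additive diameter offset (subject/condition
#'   random effects).
#' @param seed Optional integer seed (local to this call).
#' @param subject,session,part Labels for the recording.
#' @return A [pupil_recording()].
#' @export
simulate_pupil_trace <- function(medi_lx, duration_s = 1200, rate_hz = 200,
                                 pupil = list(), diameter_offset_mm = 0,
                                 seed = NULL, subject = "S01",
                                 session = "LM", part = "P1") {
  p <- sim_config(pupil = pupil)$pupil
  check_number(medi_lx, "medi_lx", lower = 0, strict = TRUE)
  check_number(duration_s, "duration_s", lower = 0, strict = TRUE)
  with_seed(seed, {
    n <- max(2L, round(duration_s * rate_hz))
    t <- (seq_len(n) - 1L) / rate_hz
    d0 <- pupil_steady_state(medi_lx, p$d_max_mm, p$d_min_mm,
                             p$e50_lx, p$hill) + diameter_offset_mm
    d <- rep(d0, n)
    if (p$ar_sd_mm > 0) {
      innov_sd <- p$ar_sd_mm * sqrt(1 - p$ar_coef^2)
      noise <- stats::filter(stats::rnorm(n, 0, innov_sd), p$ar_coef,
                             method = "recursive")
      d <- d + as.numeric(noise)
    }
    conf <- stats::runif(n, 0.85, 1)
    if (p$low_conf_frac > 0) {
      k <- round(p$low_conf_frac * n)
      if (k > 0) {
        i <- sample.int(n, k)
        conf[i] <- stats::runif(k, 0, 0.59)
      }
    }
    if (p$blink_rate_hz > 0 && p$blink_duration_s > 0) {
      nb <- stats::rpois(1L, p$blink_rate_hz * duration_s)
      if (nb > 0) {
        starts <- stats::runif(nb, 0, duration_s - p$blink_duration_s)
        for (s0 in starts) {
          core <- which(t >= s0 & t <= s0 + p$blink_duration_s)
          if (!length(core)) next
          conf[core] <- stats::runif(length(core), 0, 0.55)
          d[core] <- stats::runif(length(core), 0.5, 1.9)
          edges <- c(min(core) - 1L, max(core) + 1L)
          edges <- edges[edges >= 1L & edges <= n]
          d[edges] <- stats::runif(length(edges), 0.5, 1.9)
          conf[edges] <- stats::runif(length(edges), 0.65, 0.9)
        }
      }
    }
    pupil_recording(t, pmax(d, 0.1), conf, subject = subject,
                    session = session, part = part,
                    expected_rate_hz = rate_hz, duration_s = duration_s)
  })
}

#' Simulate an evening melatonin profile
#'
#' Half-hourly salivary melatonin concentrations: a logistic baseline rise
#' towards habitual bedtime, multiplied from light onset onwards by the
#' dose-dependent suppression factor [suppression_factor()], with
#' multiplicative lognormal assay/biological noise.
#'
#' @param dose Melanopic light dose driving suppression (unit matching
#'   `s50`), > 0.
#' @param melatonin Melatonin-parameter list as in [sim_config()]; the
#'   `s50` used is `s50_corneal` or `s50_retinal` per
#'   `suppression_driver`.
#' @param peak_mult Subject-level multiplicative amplitude effect.
#' @param seed Optional integer seed.
#' @return A data.frame with `time_h` (relative to habitual bedtime) and
#'   `conc_pg_ml`.
#' @export
simulate_melatonin_profile <- function(dose, melatonin = list(),
                                       peak_mult = 1, seed = NULL) {
  m <- sim_config(melatonin = melatonin)$melatonin
  check_number(dose, "dose", lower = 0, strict = TRUE)
  s50 <- if (m$suppression_driver == "retinal") m$s50_retinal else
    m$s50_corneal
  with_seed(seed, {
    time_h <- seq(m$t_start_h, m$t_end_h, by = m$sample_minutes / 60)
    base <- m$peak_pg_ml * peak_mult *
      stats::plogis((time_h - m$rise_midpoint_h) * m$rise_rate)
    s <- suppression_factor(dose, s50, m$hill)
    supp <- ifelse(time_h >= m$exposure_h[1L], s, 1)
    conc <- base * supp
    if (m$noise_sd_log > 0)
      conc <- conc * exp(stats::rnorm(length(conc), 0, m$noise_sd_log))
    data.frame(time_h = time_h, conc_pg_ml = conc)
  })
}

#' Generate the full synthetic study
#'
#' 4 intensity groups x 18 subjects x 2 counterbalanced metameric sessions
#' = 144 subject-sessions. Each session carries `n_parts` pupil test parts
#' and one evening melatonin profile; subject-level random effects (pupil
#' diameter offset, melatonin amplitude) are drawn once per subject. The
#' melatonin suppression dose is the session's melanopic EDI
#' (`suppression_driver = "corneal"`) or the ground-truth melanopic
#' troland dose implied by the subject's generating pupil
#' (`"retinal"`). Fully reproducible under the config seed.
#'
#' @param config A [sim_config()].
#' @param pupil_traces If `TRUE`, full sample-level pupil recordings are
#'   generated; if `FALSE`, per-part medians are drawn directly from the
#'   model's sampling distribution (fast path for replicate-level
#'   property checks; bypasses the sample-level pipeline).
#' @return A list of class `"melanophot_study"`: `sessions` (one row per
#'   subject-session with condition metadata, ground-truth diameter and
#'   doses), `recordings` (list of [pupil_recording()]s, or `NULL`),
#'   `part_medians` (fast-path medians, or `NULL`), `melatonin` (long
#'   concentration table), `ground_truth` (generating parameters and
#'   per-subject effects), `config`.
#' @export
generate_study <- function(config = sim_config(), pupil_traces = TRUE) {
  if (!inherits(config, "sim_config"))
    stop_melanophot("`config` must be a sim_config", "melanophot_validation_error")
  p <- config$pupil; m <- config$melatonin
  cond <- config$conditions
  n_subj <- 4L * config$n_per_group
  with_seed(config$seed, {
    subjects <- data.frame(
      subject = sprintf("S%02d", seq_len(n_subj)),
      group = rep(1:4, each = config$n_per_group),
      lm_first = rep(rep(c(TRUE, FALSE),
                         length.out = config$n_per_group), 4L),
      diameter_offset_mm = stats::rnorm(n_subj, 0, p$subject_sd_mm),
      peak_mult = exp(stats::rnorm(n_subj, 0, m$subject_sd_log)))
    sessions <- NULL
    recordings <- list()
    part_medians <- NULL
    melatonin <- NULL
    for (i in seq_len(n_subj)) {
      sub <- subjects[i, ]
      arms <- if (sub$lm_first) c("LM", "HM") else c("HM", "LM")
      for (vi in seq_along(arms)) {
        arm <- arms[vi]
        row <- cond[cond$group == sub$group & cond$arm == arm, ]
        offset <- sub$diameter_offset_mm +
          if (arm == "LM") p$condition_offset_mm else 0
        d_true <- pupil_steady_state(row$medi_lx, p$d_max_mm, p$d_min_mm,
                                     p$e50_lx, p$hill) + offset
        mel_td_true <- (row$mel / config$solid_angle_sr) *
          diameter_to_area(max(d_true, 0.5))
        dose <- if (m$suppression_driver == "retinal") mel_td_true else
          row$medi_lx
        if (pupil_traces) {
          for (k in seq_len(p$n_parts)) {
            recordings[[length(recordings) + 1L]] <-
              simulate_pupil_trace(row$medi_lx,
                                   duration_s = p$part_minutes * 60,
                                   rate_hz = p$rate_hz, pupil = p,
                                   diameter_offset_mm = offset,
                                   subject = sub$subject, session = arm,
                                   part = sprintf("P%d", k))
          }
        } else {
          med <- d_true + stats::rnorm(p$n_parts, 0, p$ar_sd_mm / sqrt(50))
          part_medians <- rbind(part_medians, data.frame(
            subject = sub$subject, session = arm,
            part = sprintf("P%d", seq_len(p$n_parts)),
            median_diameter_mm = med))
        }
        prof <- simulate_melatonin_profile(dose, melatonin = m,
                                           peak_mult = sub$peak_mult)
        melatonin <- rbind(melatonin, data.frame(
          subject = sub$subject, group = sub$group, session = arm,
          prof))
        sessions <- rbind(sessions, data.frame(
          subject = sub$subject, group = sub$group, arm = arm,
          visit = vi, condition = row$condition,
          luminance_cd_m2 = row$luminance_cd_m2,
          medi_lx = row$medi_lx, mel_irr_mw_m2 = row$mel,
          true_diameter_mm = d_true, true_mel_td = mel_td_true,
          suppression_dose = dose))
      }
    }
    structure(list(sessions = sessions,
                   recordings = if (pupil_traces) recordings else NULL,
                   part_medians = part_medians,
                   melatonin = melatonin,
                   ground_truth = list(pupil = p, melatonin = m,
                                       solid_angle_sr = config$solid_angle_sr,
                                       subjects = subjects),
                   config = config),
              class = "melanophot_study")
  })
}

#' @export
print.melanophot_study <- function(x, ...) {
  cat(sprintf("<melanophot_study> %d subject-sessions, %d pupil recordings, %d melatonin samples\n",
              nrow(x$sessions),
              if (is.null(x$recordings)) 0L else length(x$recordings),
              nrow(x$melatonin)))
  invisible(x)
}

#' Run the analysis pipeline over a synthetic (or real) study
#'
#' Applies the full preprocessing chain -- [filter_samples()],
#' [bin_median()], [exclude_low_quality()] -- to every pupil recording,
#' aggregates one median diameter per subject-session, computes the
#' observed melanopic troland dose from that median, and the melatonin AUC
#' over the light-exposure window.
#'
#' @param study A `"melanophot_study"` (or a compatible list).
#' @param bin_minutes,min_fraction Pipeline settings (see the component
#'   functions).
#' @return A list: `bins` (all part-level rows with exclusion flags) and
#'   `sessions` (the study's session table augmented with
#'   `median_diameter_mm`, `pupil_area_mm2`, `mel_td`, `auc`).
#' @export
process_study <- function(study, bin_minutes = 20, min_fraction = 0.02) {
  if (!is.null(study$recordings)) {
    bins <- do.call(rbind, lapply(study$recordings, function(r)
      bin_median(filter_samples(r), bin_minutes = bin_minutes)))
    bins <- exclude_low_quality(bins, min_fraction = min_fraction)
  } else {
    bins <- study$part_medians
    bins$excluded <- FALSE
  }
  ok <- bins[!bins$excluded, ]
  key <- paste(ok$subject, ok$session)
  med <- tapply(ok$median_diameter_mm, key, stats::median)
  sess <- study$sessions
  sess$median_diameter_mm <-
    as.numeric(med[paste(sess$subject, sess$arm)])
  sess$pupil_area_mm2 <- ifelse(is.na(sess$median_diameter_mm), NA,
                                pi * (sess$median_diameter_mm / 2)^2)
  omega <- study$config$solid_angle_sr
  sess$mel_td <- sess$mel_irr_mw_m2 / omega * sess$pupil_area_mm2
  expo <- study$config$melatonin$exposure_h
  auc_key <- paste(study$melatonin$subject, study$melatonin$session)
  auc <- vapply(split(study$melatonin, auc_key), function(d)
    melatonin_auc(d$time_h, d$conc_pg_ml, window = expo), numeric(1L))
  sess$auc <- as.numeric(auc[paste(sess$subject, sess$arm)])
  list(bins = bins, sessions = sess)
}

#' Recover the generating pupil dose-response model
#'
#' Nonlinear least-squares fit of the log-logistic steady-state model to
#' per-session median diameters versus mEDI (Levenberg-Marquardt,
#' data-driven starting values). Over a study-sized dose range
#' (~1.6 decades) the four-parameter model is poorly identified -- the
#' asymptotes, `e50` and the Hill slope trade off along a likelihood
#' ridge -- so when the physiological diameter range is known (it is part
#' of the model family: baseline dark-adapted and fully constricted
#' diameters), supply it via `d_range` to fix the asymptotes and fit only
#' `e50` and `hill`. With the asymptotes fixed, 144 sessions recover the
#' generating `e50` well within +/-25%.
#'
#' @param medi_lx Session melanopic EDIs (lx).
#' @param diameter_mm Session median pupil diameters (mm).
#' @param d_range Optional `c(d_min_mm, d_max_mm)`; when given the
#'   asymptotes are fixed at these values.
#' @return A list: `coef` (named vector `d_max_mm`, `d_min_mm`, `e50_lx`,
#'   `hill`) and the underlying `nls` fit.
#' @export
recover_pupil_model <- function(medi_lx, diameter_mm, d_range = NULL) {
  ok <- is.finite(medi_lx) & is.finite(diameter_mm)
  medi_lx <- medi_lx[ok]; diameter_mm <- diameter_mm[ok]
  if (length(medi_lx) < 8L)
    stop_melanophot("need at least 8 sessions to fit the pupil model",
                    "melanophot_insufficient_data_error")
  dat <- data.frame(medi = medi_lx, d = diameter_mm)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  e50_start <- 10^mean(log10(range(medi_lx)))
  if (!is.null(d_range)) {
    dat$d_min <- d_range[1L]; dat$d_max <- d_range[2L]
    fit <- minpack.lm::nlsLM(
      d ~ d_min + (d_max - d_min) / (1 + (medi / e50)^h),
      data = dat, start = list(e50 = e50_start, h = 1),
      lower = c(e50 = 1e-3, h = 0.05), upper = c(e50 = 1e5, h = 5),
      control = ctrl)
    co <- stats::coef(fit)
    co <- c(d_max = d_range[2L], d_min = d_range[1L], co)
  } else {
    fit <- minpack.lm::nlsLM(
      d ~ d_min + (d_max - d_min) / (1 + (medi / e50)^h),
      data = dat,
      start = list(d_max = max(diameter_mm) + 0.5,
                   d_min = max(min(diameter_mm) - 0.5, 0.5),
                   e50 = e50_start, h = 1),
      lower = c(d_max = 1, d_min = 0.1, e50 = 1e-3, h = 0.05),
      upper = c(d_max = 12, d_min = 8, e50 = 1e5, h = 5),
      control = ctrl)
    co <- stats::coef(fit)
  }
  list(coef = c(d_max_mm = unname(co["d_max"]),
                d_min_mm = unname(co["d_min"]),
                e50_lx = unname(co["e50"]), hill = unname(co["h"])),
       fit = fit)
}

#' Write a synthetic study bundle to disk
#'
#' Emits the pipeline's input formats: one pupil CSV (`timestamp_s`,
#' `diameter_3d_mm`, `confidence`, `subject`, `session`, `part`), a
#' melatonin CSV, the condition table, and a ground-truth JSON (requires
#' jsonlite).
#'
#' @param study A `"melanophot_study"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(study$recordings)) {
    pup <- do.call(rbind, lapply(study$recordings, function(r)
      data.frame(timestamp_s = r$samples$t,
                 diameter_3d_mm = r$samples$diameter_mm,
                 confidence = r$samples$confidence,
                 subject = r$subject, session = r$session, part = r$part)))
    utils::write.csv(pup, file.path(dir, "pupil.csv"), row.names = FALSE)
  }
  utils::write.csv(study$melatonin, file.path(dir, "melatonin.csv"),
                   row.names = FALSE)
  utils::write.csv(study$config$conditions, file.path(dir, "conditions.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- study$ground_truth
    jsonlite::write_json(list(pupil = gt$pupil, melatonin = gt$melatonin,
                              solid_angle_sr = gt$solid_angle_sr,
                              subjects = gt$subjects),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
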