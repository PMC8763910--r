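#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable parameter of the synthetic mPower-style cohort:
#' cohort composition, per-group record-count distributions, task timing,
#' and the severity-coupled effect sizes that differentiate PD signals from
#' control signals.  Defaults reproduce the summary statistics of the real
#' tapping study population: 20-s tapping records sampled at 100 Hz with
#' roughly 153 taps per healthy record, and right-skewed record counts with
#' means 40.2 (PD) and 6.06 (control).
#'
#' Disease severity is a latent non-negative scalar, 0 for controls and
#' Gamma-distributed for PD individuals.  Every disease effect (slower and
#' more variable inter-tap intervals, wider tap scatter, a 4-6 Hz tremor
#' band in the accelerometer, stride irregularity, vocal jitter/shimmer,
#' self-report scores) is linear in severity, so one knob controls task
#' difficulty.
#'
#' @param n_individuals Number of individuals in the cohort.
#' @param prevalence Marginal probability of a PD label, in (0, 1).
#' @param modalities Character subset of `c("tapping", "gait", "voice")`
#'   for which record payloads are generated.  `character(0)` generates the
#'   individual table only (useful for demographic studies at large n).
#' @param records_pd_mean,records_ctrl_mean Target mean number of records
#'   per individual and modality, by PD group.  Counts are drawn as
#'   1 + a negative binomial (right-skewed) and capped at `records_cap`;
#'   the negative-binomial mean is calibrated so the post-cap mean equals
#'   the target.
#' @param records_dispersion Negative-binomial size parameter; smaller
#'   values give heavier right skew.
#' @param records_cap Upper bound on records per individual per modality.
#' @param severity_shape,severity_rate Gamma parameters of latent severity
#'   for PD individuals (default mean 2, sd 1).
#' @param tap_duration_mean,tap_duration_sd,tap_duration_range Tapping
#'   record duration model (seconds): Gaussian, truncated to the range.
#' @param accel_rate Accelerometer sampling rate in Hz.
#' @param healthy_tap_interval Mean inter-tap interval (s) at severity 0.
#' @param tap_interval_cv Coefficient of variation of inter-tap intervals
#'   at severity 0.
#' @param iti_slope,iti_cv_slope Per-severity-unit multiplicative increase
#'   of the inter-tap-interval mean and CV (bradykinesia).
#' @param scatter_base,scatter_slope Tap positional scatter (px sd) at
#'   severity 0 and its per-severity-unit multiplicative increase.
#' @param tremor_amp_slope Tremor amplitude (m/s^2 per severity unit) of
#'   the 4-6 Hz band added to PD accelerometer signals.
#' @param tremor_band Tremor frequency band in Hz.
#' @param accel_noise_sd Accelerometer white-noise sd (m/s^2).
#' @param tap_impulse_amp Peak amplitude of the per-tap impulse (m/s^2).
#' @param gravity Gravity offset on the accelerometer z channel (m/s^2).
#' @param screen Screen size in px, `c(width, height)`.
#' @param buttons List of two target-button rectangles, each
#'   `c(x0, y0, x1, y1)` in px.
#' @param gait_duration_range Walking record duration range (s); drawn
#'   uniformly on the integers of this range times 10 s grid (20 or 30 s
#'   by default).
#' @param stride_freq Healthy stride frequency in Hz.
#' @param stride_amp Vertical stride acceleration amplitude (m/s^2).
#' @param gait_phase_noise,gait_irregularity_slope Random-walk phase noise
#'   (rad per sample) of the stride oscillator at severity 0 and its
#'   per-severity-unit multiplicative increase.
#' @param voice_rate Phonation sampling rate in Hz.  The real recordings
#'   are 44.1 kHz; the default keeps desk-scale data volumes while
#'   preserving the fundamental and first harmonics.
#' @param voice_duration Phonation duration (s).
#' @param f0_range Fundamental-frequency range (Hz) sampled per record.
#' @param jitter_base,jitter_slope Cycle-to-cycle period perturbation
#'   (proportional sd) at severity 0 and per severity unit.
#' @param shimmer_base,shimmer_slope Cycle-to-cycle amplitude perturbation
#'   at severity 0 and per severity unit.
#' @param voice_noise_sd Additive waveform noise sd.
#' @param updrs_part2_slope,updrs_part2_sd,updrs_extra_slope,updrs_extra_sd
#'   Self-report model: part 2 = max(0, slope * severity + noise), total =
#'   part 2 + max(0, slope * severity + noise).  With all noise at 0 a
#'   control reports (0, 0); with the defaults controls get small noisy
#'   scores so self-report separates the classes well but imperfectly.
#' @param age_pd_mean,age_pd_sd Age model for PD individuals (Gaussian,
#'   clamped to 18-95).
#' @param age_ctrl_shape,age_ctrl_scale Age model for controls: 18 +
#'   Gamma(shape, scale), clamped to 95; right-skewed towards younger ages
#'   so PD prevalence rises steeply with age.
#' @param gender_probs,smoke_probs Sampling probabilities for
#'   `c("male", "female", "unspecified")` and `c("no", "yes", "unknown")`.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_individuals = 20, modalities = "tapping")
#' coh <- simulate_cohort(cfg, seed = 1)
#' @export
cohort_config <- function(n_individuals = 100,
                          prevalence = 0.25,
                          modalities = c("tapping", "gait", "voice"),
                          records_pd_mean = 40.2,
                          records_ctrl_mean = 6.06,
                          records_dispersion = 0.6,
                          records_cap = 100,
                          severity_shape = 4,
                          severity_rate = 2,
                          tap_duration_mean = 19.92,
                          tap_duration_sd = 0.2,
                          tap_duration_range = c(19.4, 20.2),
                          accel_rate = 100,
                          healthy_tap_interval = 0.13,
                          tap_interval_cv = 0.12,
                          iti_slope = 0.3,
                          iti_cv_slope = 0.3,
                          scatter_base = 10,
                          scatter_slope = 0.6,
                          tremor_amp_slope = 0.25,
                          tremor_band = c(4, 6),
                          accel_noise_sd = 0.15,
                          tap_impulse_amp = 1.5,
                          gravity = 9.81,
                          screen = c(width = 320, height = 480),
                          buttons = list(c(40, 290, 130, 380),
                                         c(190, 290, 280, 380)),
                          gait_duration_range = c(20, 30),
                          stride_freq = 1.9,
                          stride_amp = 2,
                          gait_phase_noise = 0.02,
                          gait_irregularity_slope = 0.8,
                          voice_rate = 4000,
                          voice_duration = 10,
                          f0_range = c(110, 220),
                          jitter_base = 0.004,
                          jitter_slope = 0.012,
                          shimmer_base = 0.03,
                          shimmer_slope = 0.1,
                          voice_noise_sd = 0.02,
                          updrs_part2_slope = 8,
                          updrs_part2_sd = 3,
                          updrs_extra_slope = 14,
                          updrs_extra_sd = 5,
                          age_pd_mean = 62,
                          age_pd_sd = 10,
                          age_ctrl_shape = 2.2,
                          age_ctrl_scale = 10,
                          gender_probs = c(male = 0.78, female = 0.21,
                                           unspecified = 0.01),
                          smoke_probs = c(no = 0.62, yes = 0.33,
                                          unknown = 0.05)) {
  cfg <- as.list(environment())
  stop_if_not(is.numeric(n_individuals) && length(n_individuals) == 1 &&
                n_individuals >= 1 && n_individuals == floor(n_individuals),
              "n_individuals must be a positive integer")
  stop_if_not(prevalence > 0 && prevalence < 1,
              "prevalence must lie strictly inside (0, 1)")
  stop_if_not(all(modalities %in% c("tapping", "gait", "voice")),
              "unknown modality in config (use tapping/gait/voice)")
  stop_if_not(records_pd_mean >= 1 && records_ctrl_mean >= 1,
              "record-count means must be >= 1")
  stop_if_not(records_dispersion > 0, "records_dispersion must be positive")
  stop_if_not(records_cap >= 2, "records_cap must be >= 2")
  stop_if_not(severity_shape > 0 && severity_rate > 0,
              "severity distribution parameters must be positive")
  stop_if_not(tap_duration_range[1] < tap_duration_range[2] &&
                tap_duration_range[1] > 0,
              "tap_duration_range must be an increasing positive interval")
  stop_if_not(healthy_tap_interval > 0 && tap_interval_cv > 0,
              "tap interval parameters must be positive")
  stop_if_not(all(c(iti_slope, iti_cv_slope, scatter_slope, tremor_amp_slope,
                    gait_irregularity_slope, jitter_slope, shimmer_slope) >= 0),
              "effect-size slopes must be non-negative")
  stop_if_not(length(buttons) == 2 && all(lengths(buttons) == 4),
              "buttons must be two c(x0, y0, x1, y1) rectangles")
  stop_if_not(tremor_band[1] < tremor_band[2] && tremor_band[1] > 0,
              "tremor_band must be an increasing positive interval")
  stop_if_not(voice_rate > 2 * f0_range[2],
              "voice_rate must exceed twice the maximum fundamental")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  individuals: %d, prevalence: %.2f\n",
              x$n_individuals, x$prevalence))
  cat(sprintf("  modalities: %s\n",
              if (length(x$modalities)) paste(x$modalities, collapse = ", ")
              else "(none)"))
  cat(sprintf("  record-count means (PD / control): %.2f / %.2f, cap %d\n",
              x$records_pd_mean, x$records_ctrl_mean, as.integer(x$records_cap)))
  invisible(x)
}

#' Multi-channel uniformly sampled sensor waveform
#'
#' @param values Numeric matrix, channels x n_samples.  Accelerometer
#'   modalities carry 3 channels (x, y, z); voice carries 1.
#' @param sample_rate Sampling rate in Hz.
#' @param modality One of `"tap_accel"`, `"gait"`, `"rest"`, `"voice"`.
#' @return A `sensor_series` object.
#' @export
sensor_series <- function(values, sample_rate,
                          modality = c("tap_accel", "gait", "rest", "voice")) {
  modality <- match.arg(modality)
  stop_if_not(is.matrix(values) && is.numeric(values),
              "values must be a numeric channels x n_samples matrix")
  stop_if_not(all(is.finite(values)), "sensor values must all be finite")
  stop_if_not(sample_rate > 0, "sample_rate must be positive")
  want <- if (modality == "voice") 1L else 3L
  stop_if_not(nrow(values) == want,
              "%s series must have %d channel(s), got %d",
              modality, want, nrow(values))
  structure(list(values = values, sample_rate = sample_rate,
                 modality = modality,
                 duration = ncol(values) / sample_rate),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> %s: %d ch x %d samples @ %g Hz (%.2f s)\n",
              x$modality, nrow(x$values), ncol(x$values), x$sample_rate,
              x$duration))
  invisible(x)
}

#' Ordered tap-event sequence with target-button geometry
#'
#' @param events Data frame with columns `t` (seconds, strictly
#'   increasing), `x`, `y` (px).  At least 2 events.
#' @param buttons List of two `c(x0, y0, x1, y1)` rectangles in px.
#' @param screen `c(width, height)` in px.
#' @param duration Record duration in seconds; all timestamps must lie in
#'   `[0, duration]`.
#' @return A `tap_events` object.
#' @export
tap_events <- function(events, buttons, screen, duration) {
  stop_if_not(is.data.frame(events) && all(c("t", "x", "y") %in% names(events)),
              "events must be a data frame with columns t, x, y")
  stop_if_not(nrow(events) >= 2, "a tapping record needs at least 2 events")
  stop_if_not(all(diff(events$t) > 0), "tap timestamps must be strictly increasing")
  stop_if_not(all(events$t >= 0) && all(events$t <= duration),
              "tap timestamps must lie in [0, duration]")
  stop_if_not(length(buttons) == 2 && all(lengths(buttons) == 4),
              "buttons must be two c(x0, y0, x1, y1) rectangles")
  structure(list(events = events[, c("t", "x", "y")], buttons = buttons,
                 screen = screen, duration = duration),
            class = "tap_events")
}

#' @export
print.tap_events <- function(x, ...) {
  cat(sprintf("<tap_events> %d taps over %.2f s on a %g x %g px screen\n",
              nrow(x$events), x$duration, x$screen[1], x$screen[2]))
  invisible(x)
}

# Union bounding box of the two target buttons: c(x0, y0, x1, y1).
button_bounds <- function(buttons) {
  b <- do.call(rbind, buttons)
  c(min(b[, 1]), min(b[, 2]), max(b[, 3]), max(b[, 4]))
}
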