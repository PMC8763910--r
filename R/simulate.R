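# Synthetic cohort and record generation.
#
# All record-level simulators draw from the current RNG stream; callers are
# responsible for seeding.  simulate_cohort() derives one sub-seed per
# (individual, modality, record) so cohorts are reproducible bit-for-bit and
# insensitive to generation order.

# Mean of min(X, cap) for X ~ NB(mu, size): sum_{k=0}^{cap-1} P(X > k).
nbinom_capped_mean <- function(mu, size, cap) {
  k <- 0:(cap - 1)
  sum(1 - pnbinom(k, mu = mu, size = size))
}

# Calibrate the negative-binomial mean so that E[1 + min(X, cap - 1)]
# equals the configured target mean after capping.
calibrate_record_mu <- function(target_mean, size, cap) {
  target <- target_mean - 1
  if (target <= 0) return(1e-9)
  upper <- target
  # capping only lowers the mean, so search upward for the matching mu
  while (nbinom_capped_mean(upper, size, cap - 1) < target) {
    upper <- upper * 2
    if (upper > 1e6) stop("record-count mean unreachable under the cap")
  }
  uniroot(function(mu) nbinom_capped_mean(mu, size, cap - 1) - target,
          lower = target / 2, upper = upper, tol = 1e-8)$root
}

draw_record_counts <- function(n, target_mean, size, cap) {
  mu <- calibrate_record_mu(target_mean, size, cap)
  1L + pmin(rnbinom(n, mu = mu, size = size), cap - 1L)
}

#' Simulate an mPower-style cohort
#'
#' Draws individuals (PD label, demographics, latent severity, self-report
#' scores, per-modality record counts) and, for each configured modality,
#' per-record sensor payloads with severity-coupled disease effects.
#' Identical `(config, seed)` pairs reproduce the cohort bit-for-bit.
#'
#' PD labels are Bernoulli with the configured prevalence; ages are drawn
#' conditional on the label (older for PD), which induces the steep rise of
#' PD prevalence with age seen in the real study population.  Record counts
#' per individual and modality are 1 + a capped negative binomial whose mean
#' is calibrated to the configured group target, reproducing the heavy
#' right skew of records-per-individual.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the only source of randomness.
#' @return A `pd_cohort` object: list with `individuals` (data frame),
#'   `records` (list of record objects with `individual_id`, `record_id`,
#'   `modality`, and payloads), `config`, `seed`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_individuals = 12,
#'                                      modalities = "tapping"), seed = 42)
#' table(coh$individuals$pd_label)
#' @export
simulate_cohort <- function(config, seed) {
  stop_if_not(inherits(config, "cohort_config"),
              "config must be built with cohort_config()")
  stop_if_not(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single integer")
  n <- as.integer(config$n_individuals)

  individuals <- with_seed(mix_seed(seed, 1), {
    pd <- rbinom(n, 1L, config$prevalence)
    severity <- ifelse(pd == 1L,
                       rgamma(n, shape = config$severity_shape,
                              rate = config$severity_rate),
                       0)
    age <- ifelse(pd == 1L,
                  pmin(pmax(rnorm(n, config$age_pd_mean, config$age_pd_sd),
                            18), 95),
                  pmin(18 + rgamma(n, shape = config$age_ctrl_shape,
                                   scale = config$age_ctrl_scale), 95))
    gender <- sample(names(config$gender_probs), n, replace = TRUE,
                     prob = config$gender_probs)
    smoke <- sample(names(config$smoke_probs), n, replace = TRUE,
                    prob = config$smoke_probs)
    df <- data.frame(
      id = sprintf("ind%05d", seq_len(n)),
      pd_label = pd, age = round(age, 1), gender = gender, smoke = smoke,
      severity = severity, stringsAsFactors = FALSE)
    sr <- t(vapply(seq_len(n), function(i)
      simulate_self_report(list(severity = severity[i]), config),
      numeric(2)))
    df$updrs_total <- sr[, 1]
    df$updrs_part2 <- sr[, 2]
    for (m in c("tapping", "gait", "voice")) {
      cnt <- integer(n)
      for (grp in c(0L, 1L)) {
        idx <- which(pd == grp)
        if (length(idx))
          cnt[idx] <- draw_record_counts(
            length(idx),
            if (grp == 1L) config$records_pd_mean else config$records_ctrl_mean,
            config$records_dispersion, config$records_cap)
      }
      df[[paste0("n_records_", m)]] <- cnt
    }
    df
  })

  records <- list()
  mod_code <- c(tapping = 2, gait = 3, voice = 4)
  for (m in config$modalities) {
    for (i in seq_len(n)) {
      ind <- as.list(individuals[i, ])
      for (r in seq_len(individuals[[paste0("n_records_", m)]][i])) {
        rec_seed <- mix_seed(seed, mod_code[[m]], i, r)
        rec <- with_seed(rec_seed, {
          if (m == "tapping") {
            dur <- trunc_norm(config$tap_duration_mean, config$tap_duration_sd,
                              config$tap_duration_range)
            pair <- simulate_tapping_record(ind, dur, config)
            list(series = pair$series, events = pair$events, duration = dur)
          } else if (m == "gait") {
            dur <- sample(seq(config$gait_duration_range[1],
                              config$gait_duration_range[2], by = 10), 1)
            list(series = simulate_gait_record(ind, dur, config),
                 duration = dur)
          } else {
            list(series = simulate_voice_record(ind, config$voice_duration,
                                                config$voice_rate, config),
                 duration = config$voice_duration)
          }
        })
        rec$individual_id <- ind$id
        rec$record_id <- sprintf("%s_%s_%03d", ind$id, m, r)
        rec$modality <- m
        records[[rec$record_id]] <- rec
      }
    }
  }

  structure(list(individuals = individuals, records = records,
                 config = config, seed = as.integer(seed)),
            class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf("<pd_cohort> %d individuals (%d PD), %d records, seed %d\n",
              nrow(x$individuals), sum(x$individuals$pd_label),
              length(x$records), x$seed))
  invisible(x)
}

trunc_norm <- function(mean, sd, range) {
  min(max(rnorm(1, mean, sd), range[1]), range[2])
}

#' Simulate one finger-tapping record
#'
#' Generates the coupled pair recorded by a tapping task: the sequence of
#' screen taps alternating between the two target buttons, and the phone's
#' 3-axis accelerometer stream.  Bradykinesia is modeled as lognormal
#' inter-tap intervals whose mean and coefficient of variation grow
#' linearly with severity; tap positions scatter around the button centers
#' with severity-scaled Gaussian spread.  The accelerometer carries the
#' gravity offset, white noise, a decaying impulse at each tap, and an
#' additive sinusoidal tremor in the 4-6 Hz band whose amplitude is
#' proportional to severity.
#'
#' Draws from the current RNG stream; seed before calling for
#' reproducibility.
#'
#' @param ind A list with at least a `severity` field (>= 0).
#' @param duration Record duration in seconds (> 0).
#' @param config A [cohort_config()].
#' @return List with `series` (a 3-channel [sensor_series()] at
#'   `config$accel_rate`) and `events` (a [tap_events()]).
#' @export
simulate_tapping_record <- function(ind, duration, config) {
  sev <- ind$severity
  stop_if_not(is.numeric(sev) && sev >= 0, "severity must be non-negative")
  stop_if_not(duration > 0, "duration must be positive")

  mean_iti <- config$healthy_tap_interval * (1 + config$iti_slope * sev)
  cv <- config$tap_interval_cv * (1 + config$iti_cv_slope * sev)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_iti) - sdlog^2 / 2
  n_draw <- ceiling(duration / mean_iti * 1.5) + 20
  t0 <- runif(1, 0.05, 0.3)
  times <- t0 + cumsum(rlnorm(n_draw, meanlog, sdlog))
  times <- c(t0, times[times <= duration])
  if (length(times) < 2) times <- c(t0, min(t0 + mean_iti, duration))

  scatter <- config$scatter_base * (1 + config$scatter_slope * sev)
  centers <- lapply(config$buttons,
                    function(b) c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2))
  side <- (seq_along(times) + sample(0:1, 1)) %% 2 + 1
  px <- vapply(side, function(s) centers[[s]][1], numeric(1)) +
    rnorm(length(times), 0, scatter)
  py <- vapply(side, function(s) centers[[s]][2], numeric(1)) +
    rnorm(length(times), 0, scatter)
  px <- pmin(pmax(px, 0), config$screen[[1]])
  py <- pmin(pmax(py, 0), config$screen[[2]])
  events <- tap_events(data.frame(t = times, x = round(px, 1),
                                  y = round(py, 1)),
                       config$buttons, config$screen, duration)

  rate <- config$accel_rate
  ns <- round(duration * rate)
  tt <- (seq_len(ns) - 1) / rate
  acc <- matrix(rnorm(3 * ns, 0, config$accel_noise_sd), nrow = 3)
  acc[3, ] <- acc[3, ] + config$gravity
  # tap impulses: exponential decay over ~50 ms, mostly vertical
  amp_xy <- 0.25 * config$tap_impulse_amp
  for (tp in times) {
    i0 <- floor(tp * rate) + 1
    idx <- i0:min(i0 + ceiling(0.05 * rate), ns)
    if (idx[1] > ns) next
    decay <- exp(-(tt[idx] - tp) / 0.015)
    decay[tt[idx] < tp] <- 0
    acc[3, idx] <- acc[3, idx] + config$tap_impulse_amp * decay
    acc[1, idx] <- acc[1, idx] + amp_xy * rnorm(1) * decay
    acc[2, idx] <- acc[2, idx] + amp_xy * rnorm(1) * decay
  }
  if (sev > 0) {
    f <- runif(1, config$tremor_band[1], config$tremor_band[2])
    phase <- runif(1, 0, 2 * pi)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    tremor <- config$tremor_amp_slope * sev * sin(2 * pi * f * tt + phase)
    acc <- acc + outer(dir, tremor)
  }
  list(series = sensor_series(acc, rate, "tap_accel"), events = events)
}

#' Simulate one gait/rest accelerometer record
#'
#' A 3-channel walking signal: a stride oscillator (fundamental plus one
#' harmonic, largest on the vertical axis) whose phase performs a random
#' walk -- the walk's step size grows with severity, degrading stride
#' regularity -- plus a severity-scaled 4-6 Hz tremor band, gravity and
#' white noise.  Draws from the current RNG stream.
#'
#' @inheritParams simulate_tapping_record
#' @return A 3-channel [sensor_series()] with modality `"gait"`.
#' @export
simulate_gait_record <- function(ind, duration, config) {
  sev <- ind$severity
  stop_if_not(is.numeric(sev) && sev >= 0, "severity must be non-negative")
  stop_if_not(duration > 0, "duration must be positive")
  rate <- config$accel_rate
  ns <- round(duration * rate)
  tt <- (seq_len(ns) - 1) / rate

  f <- config$stride_freq * (1 + rnorm(1, 0, 0.03))
  noise_sd <- config$gait_phase_noise * (1 + config$gait_irregularity_slope * sev)
  phase <- 2 * pi * f * tt + cumsum(rnorm(ns, 0, noise_sd)) +
    runif(1, 0, 2 * pi)
  a <- config$stride_amp
  acc <- rbind(0.35 * a * sin(phase + runif(1, 0, 2 * pi)),
               0.25 * a * sin(phase / 2 + runif(1, 0, 2 * pi)),
               config$gravity + a * sin(phase) + 0.3 * a * sin(2 * phase))
  acc <- acc + matrix(rnorm(3 * ns, 0, config$accel_noise_sd), nrow = 3)
  if (sev > 0) {
    ftr <- runif(1, config$tremor_band[1], config$tremor_band[2])
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    acc <- acc + outer(dir, config$tremor_amp_slope * sev *
                         sin(2 * pi * ftr * tt + runif(1, 0, 2 * pi)))
  }
  sensor_series(acc, rate, "gait")
}

#' Simulate one sustained-phonation record
#'
#' A mono "Ahh" waveform built cycle by cycle: a harmonic stack at a
#' per-record fundamental, with cycle-to-cycle period perturbation
#' (jitter) and amplitude perturbation (shimmer) whose magnitudes grow
#' linearly with severity -- the vocal instability characteristic of PD.
#' Draws from the current RNG stream.
#'
#' @inheritParams simulate_tapping_record
#' @param sample_rate Sampling rate in Hz.
#' @return A 1-channel [sensor_series()] with modality `"voice"`.
#' @export
simulate_voice_record <- function(ind, duration, sample_rate, config) {
  sev <- ind$severity
  stop_if_not(is.numeric(sev) && sev >= 0, "severity must be non-negative")
  stop_if_not(duration > 0, "duration must be positive")
  stop_if_not(sample_rate > 0, "sample_rate must be positive")

  f0 <- runif(1, config$f0_range[1], config$f0_range[2])
  jitter <- config$jitter_base + config$jitter_slope * sev
  shimmer <- config$shimmer_base + config$shimmer_slope * sev
  n_cycles <- ceiling(duration * f0 * 1.3) + 8
  periods <- (1 / f0) * pmax(1 + rnorm(n_cycles, 0, jitter), 0.5)
  amps <- pmax(1 + rnorm(n_cycles, 0, shimmer), 0.1)
  starts <- c(0, cumsum(periods))

  ns <- round(duration * sample_rate)
  tt <- (seq_len(ns) - 1) / sample_rate
  cyc <- findInterval(tt, starts)
  frac <- (tt - starts[cyc]) / periods[cyc]
  phase <- 2 * pi * (cyc - 1 + frac)
  harm <- c(0.55, 0.28, 0.12)
  wav <- amps[cyc] * (harm[1] * sin(phase) + harm[2] * sin(2 * phase) +
                        harm[3] * sin(3 * phase)) +
    rnorm(ns, 0, config$voice_noise_sd)
  wav <- pmin(pmax(wav, -0.999), 0.999)
  sensor_series(matrix(wav, nrow = 1), sample_rate, "voice")
}

#' Simulate self-reported symptom scores
#'
#' Maps latent severity to a (total, part 2) pair of self-reported symptom
#' scores.  Both components are `max(0, slope * severity + noise)`; the
#' total is the part-2 score plus a non-negative remainder, so
#' `part2 <= total` always holds and a noiseless control reports (0, 0).
#' Reporting noise makes self-report a strong but imperfect separator of
#' the PD label.  Draws from the current RNG stream.
#'
#' @inheritParams simulate_tapping_record
#' @return Numeric `c(updrs_total, updrs_part2)`.
#' @export
simulate_self_report <- function(ind, config) {
  sev <- ind$severity
  stop_if_not(is.numeric(sev) && sev >= 0, "severity must be non-negative")
  part2 <- max(0, config$updrs_part2_slope * sev +
                 rnorm(1, 0, config$updrs_part2_sd))
  extra <- max(0, config$updrs_extra_slope * sev +
                 rnorm(1, 0, config$updrs_extra_sd))
  c(updrs_total = round(part2 + extra, 1), updrs_part2 = round(part2, 1))
}

#' Extract records of one model modality from a cohort
#'
#' Model modalities map onto cohort record types: `tap_accel` and
#' `tap_coord` both come from tapping records (accelerometer stream and
#' tap-event sequence respectively); `gait` and `voice` map directly.
#'
#' @param cohort A `pd_cohort`.
#' @param modality One of `"tap_accel"`, `"tap_coord"`, `"gait"`, `"voice"`.
#' @return Named list of records (payload plus ids).
#' @export
cohort_records <- function(cohort,
                           modality = c("tap_accel", "tap_coord",
                                        "gait", "voice")) {
  modality <- match.arg(modality)
  src <- switch(modality, tap_accel = "tapping", tap_coord = "tapping",
                gait = "gait", voice = "voice")
  Filter(function(r) r$modality == src, cohort$records)
}
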