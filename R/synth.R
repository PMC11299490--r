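# Seeded synthetic-fixture generator: pink-noise LFP shaped by the device
# filter cascade, stimulation pulse trains that alias exactly as sampling
# would fold them, soft-start banding bursts, a cardiac line, and multi-week
# trend logs with injected biorhythms. Every analysis path in the package can
# be exercised against the generator's known ground truth.

# run code with a fixed RNG state without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' One stimulation segment of a synthetic recording
#'
#' @param start_s,end_s segment bounds in seconds from recording start.
#' @param stim a [stim_setting()].
#' @param amplitude artifact amplitude in signal units (the post-blanking
#'   residual; the amplifier itself is not simulated).
#' @return A list describing the segment.
#' @export
stim_segment <- function(start_s, end_s, stim, amplitude = 1000) {
  stopifnot(inherits(stim, "stim_setting"), end_s > start_s, amplitude >= 0)
  list(start_s = start_s, end_s = end_s, stim = stim, amplitude = amplitude)
}

#' Synthetic-fixture configuration
#'
#' @param seed integer RNG seed; all generators are deterministic given it.
#' @param duration_s in-clinic recording duration in seconds.
#' @param fs_hz sampling rate (250).
#' @param noise a [noise_model()] for the pink-noise background.
#' @param cascade the [filter_cascade()] shaping the background.
#' @param stim_segments list of [stim_segment()]s (non-overlapping).
#' @param stim_mode `"pulse"` (rectangular pulse train represented by its
#'   analog-filtered harmonics, so harmonics and aliasing arise naturally) or
#'   `"tone"` (a single sinusoid at the stimulation frequency, for exact
#'   single-line tests).
#' @param n_harmonics harmonics per pulse train in `"pulse"` mode.
#' @param cardiac_hz optional cardiac line frequency (e.g. 1.2 Hz = 72 bpm).
#' @param cardiac_amplitude cardiac line amplitude in signal units.
#' @param soft_start optional list with a [soft_start_plan()] under `plan`,
#'   plus `start_s` and `amplitude`: injects a broadband burst at every
#'   amplitude step of the ramp (the "banding" artifact).
#' @param trend optional list configuring [generate_trend()]: `days`,
#'   `hemispheres`, `baseline`, `components` (data.frame with
#'   `cycles_per_day`, `amplitude`, `phase`), `noise_sd`, `start`
#'   (POSIXct), `gap_slots` (integer slots to drop, per hemisphere).
#' @param channel_label,start_time recording metadata.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, duration_s = 60, fs_hz = 250,
                         noise = noise_model(amplitude = 1, exponent = 1),
                         cascade = percept_cascade(sampling_rate_hz = fs_hz),
                         stim_segments = list(), stim_mode = c("pulse", "tone"),
                         n_harmonics = 4L, cardiac_hz = NULL,
                         cardiac_amplitude = 0, soft_start = NULL, trend = NULL,
                         channel_label = "LEFT_0-3",
                         start_time = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  stim_mode <- match.arg(stim_mode)
  if (length(stim_segments) > 1) {
    iv <- t(vapply(stim_segments, function(s) c(s$start_s, s$end_s), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("stimulation segments must not overlap")
  }
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 fs_hz = fs_hz, noise = noise, cascade = cascade,
                 stim_segments = stim_segments, stim_mode = stim_mode,
                 n_harmonics = as.integer(n_harmonics),
                 cardiac_hz = cardiac_hz, cardiac_amplitude = cardiac_amplitude,
                 soft_start = soft_start, trend = trend,
                 channel_label = channel_label,
                 start_time = parse_datetime(start_time)),
            class = "synth_config")
}

# continuous-time (analog) power gain: only the analog stages, evaluated at
# the true frequency, which may exceed Nyquist (that is the point: the analog
# anti-aliasing stages attenuate harmonics before sampling folds them)
analog_power_gain <- function(cascade, f) {
  g <- rep(1, length(f))
  for (s in cascade$stages)
    if (s$family == "first_order_cascade")
      g <- g * stage_power_gain(s, f, cascade$sampling_rate_hz)
  g
}

digital_power_gain <- function(cascade, f) {
  g <- rep(1, length(f))
  for (s in cascade$stages)
    if (s$family != "first_order_cascade")
      g <- g * stage_power_gain(s, pmax(f, 1e-6), cascade$sampling_rate_hz)
  g
}

# pink noise shaped by the full cascade, synthesised in the frequency domain
# so its one-sided PSD is exactly noise$amplitude * f^-exp * filter_gain(f)
shaped_noise <- function(n, fs, noise, cascade) {
  nfreq <- n %/% 2 + 1L
  f <- (seq_len(nfreq) - 1L) * fs / n
  S <- numeric(nfreq)
  pos <- f > 0 & f <= fs / 2
  S[pos] <- noise$amplitude * f[pos]^(-noise$exponent) * filter_gain(cascade, f[pos])
  X <- complex(real = stats::rnorm(nfreq), imaginary = stats::rnorm(nfreq)) / sqrt(2)
  X <- X * sqrt(S * fs * n / 2)
  X[1] <- 0
  if (n %% 2 == 0) X[nfreq] <- sqrt(S[nfreq] * fs * n / 2) * stats::rnorm(1) # real at Nyquist
  full <- c(X, Conj(rev(X[2:(nfreq - 1L + n %% 2)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Generate a synthetic in-clinic recording
#'
#' Pink noise with the configured exponent, shaped by the filter cascade, plus
#' per-segment stimulation artifacts sampled at `fs` (so above-Nyquist lines
#' alias exactly as the device's digitiser would fold them), an optional
#' cardiac sinusoid, and optional soft-start broadband bursts at the ramp
#' cadence. Deterministic given the seed.
#'
#' In `"pulse"` mode each stimulation segment contributes the Fourier-series
#' harmonics of a rectangular pulse train (amplitude, width and rate from the
#' segment's [stim_setting()]), each harmonic attenuated by the analog stages
#' at its true frequency and by the digital stage at its aliased frequency.
#'
#' @param cfg a [synth_config()].
#' @return A [time_domain_recording()]; when stimulation segments are present
#'   the first segment's setting is attached as recording metadata.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$fs_hz
  n <- round(cfg$duration_s * fs)
  with_local_seed(cfg$seed, {
    x <- shaped_noise(n, fs, cfg$noise, cfg$cascade)
    t <- (seq_len(n) - 1L) / fs
    for (seg in cfg$stim_segments) {
      idx <- t >= seg$start_s & t < seg$end_s
      f0 <- seg$stim$frequency_hz
      if (cfg$stim_mode == "tone") {
        # cos, phase-locked to the sample clock: the device times stimulation
        # relative to sampling, and a Nyquist-rate line in sin phase would
        # vanish at the sample instants
        x[idx] <- x[idx] + seg$amplitude * cos(2 * pi * f0 * t[idx])
      } else {
        pw <- seg$stim$pulse_width_us * 1e-6
        for (k in seq_len(cfg$n_harmonics)) {
          fk <- k * f0
          ck <- 2 * seg$amplitude * pw * f0 *
            abs(sinc(k * pw * f0)) *
            sqrt(analog_power_gain(cfg$cascade, fk) *
                   digital_power_gain(cfg$cascade, alias_frequency(fk, fs)))
          x[idx] <- x[idx] + ck * cos(2 * pi * fk * t[idx])
        }
      }
    }
    if (!is.null(cfg$cardiac_hz) && cfg$cardiac_amplitude > 0)
      x <- x + cfg$cardiac_amplitude * sin(2 * pi * cfg$cardiac_hz * t)
    if (!is.null(cfg$soft_start)) {
      ss <- cfg$soft_start
      burst_len <- max(1L, round(0.04 * fs))
      for (j in seq_len(ss$plan$n_steps) - 1L) {
        i0 <- round((ss$start_s + j * ss$plan$step_interval_s) * fs) + 1L
        ii <- i0:min(n, i0 + burst_len - 1L)
        if (ii[1] > n) break
        x[ii] <- x[ii] + ss$amplitude * stats::rnorm(length(ii))
      }
    }
    stim <- if (length(cfg$stim_segments) > 0) cfg$stim_segments[[1]]$stim else NULL
    time_domain_recording(x, sampling_rate_hz = fs, start_time = cfg$start_time,
                          channel_label = cfg$channel_label, stim = stim)
  })
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Generate a synthetic at-home trend log
#'
#' 144 entries per day at 10-minute spacing; each value is a baseline plus a
#' sum of biorhythm sinusoids (in cycles/day) plus Gaussian noise, floored at
#' zero. Deterministic given the seed.
#'
#' @param cfg a [synth_config()] with a `trend` entry.
#' @return A [trend_log_series()].
#' @export
generate_trend <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  tr <- cfg$trend
  if (is.null(tr)) stop("config has no `trend` entry")
  days <- tr$days %||% 28
  hemis <- tr$hemispheres %||% "Left"
  baseline <- tr$baseline %||% 20
  comps <- tr$components %||% data.frame(cycles_per_day = numeric(),
                                         amplitude = numeric(), phase = numeric())
  if (is.null(comps$phase)) comps$phase <- rep(0, nrow(comps))
  sd <- tr$noise_sd %||% 1
  start <- parse_datetime(tr$start %||% as.POSIXct("2026-01-01 00:00:00", tz = "UTC"))
  n <- as.integer(round(days * 144))
  td <- (seq_len(n) - 1L) / 144 # time in days
  with_local_seed(cfg$seed, {
    per_h <- lapply(seq_along(hemis), function(hi) {
      v <- rep(baseline, n)
      for (i in seq_len(nrow(comps)))
        v <- v + comps$amplitude[i] *
          sin(2 * pi * comps$cycles_per_day[i] * td + comps$phase[i])
      v <- pmax(0, v + stats::rnorm(n, sd = sd))
      df <- data.frame(timestamp = start + (seq_len(n) - 1L) * 600,
                       lfp_power = v, stim_amplitude_ma = NA_real_)
      drop <- tr$gap_slots %||% integer()
      if (length(drop) > 0) df <- df[-drop, , drop = FALSE]
      df
    })
    names(per_h) <- hemis
    trend_log_series(per_h, allow_overfull = days > 60)
  })
}

#' Bundle synthetic fixtures into a session report
#'
#' @param cfgs a [synth_config()] or list of them; recordings are taken from
#'   every config (ordered by start time) and trend logs from the first
#'   config that carries a `trend` entry.
#' @return A [percept_report()] that round-trips through [write_report()] /
#'   [parse_report()].
#' @export
generate_report <- function(cfgs) {
  if (inherits(cfgs, "synth_config")) cfgs <- list(cfgs)
  if (length(cfgs) == 0) stop("need at least one config")
  recs <- lapply(cfgs, generate_recording)
  recs <- recs[order(vapply(recs, function(r) as.numeric(r$start_time), numeric(1)))]
  trends <- NULL
  for (cfg in cfgs) {
    if (!is.null(cfg$trend)) { trends <- generate_trend(cfg); break }
  }
  percept_report(
    session_metadata = list(Source = "perceptkit synthetic fixture",
                            Seed = cfgs[[1]]$seed, Deidentified = TRUE),
    time_domain = recs, trend_logs = trends
  )
}

#' Named synthetic-scenario presets
#'
#' * `"fig2_baseline"`: 3 min of shaped pink noise with a cardiac line —
#'   baseline spectrum and model-fitting scenarios.
#' * `"fig3_stim_sweep"`: alternating 1-min baseline / 1-min stimulation at
#'   120, 145 and 160 Hz — spectrogram line-tracking (lines at 120, 105,
#'   90 Hz after folding).
#' * `"fig5_alias"`: 3 min baseline then 1-min segments at 125, 145, 165 Hz —
#'   folded lines at 125, 105 and 85 Hz.
#' * `"fig6_trend"`: a 28-day trend log with half-day, daily, two-day and
#'   weekly components.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return A [synth_config()].
#' @export
synth_preset <- function(name = c("fig2_baseline", "fig3_stim_sweep",
                                  "fig5_alias", "fig6_trend"), seed = 1L) {
  name <- match.arg(name)
  st <- function(f) stim_setting(amplitude_ma = 2, frequency_hz = f,
                                 pulse_width_us = 90, impedance_ohm = 1000)
  switch(name,
    fig2_baseline = synth_config(
      seed = seed, duration_s = 180,
      noise = noise_model(amplitude = 10, exponent = 1),
      cardiac_hz = 1.2, cardiac_amplitude = 2
    ),
    fig3_stim_sweep = synth_config(
      seed = seed, duration_s = 360,
      noise = noise_model(amplitude = 1, exponent = 1),
      stim_segments = list(
        stim_segment(60, 120, st(120), amplitude = 5000),
        stim_segment(180, 240, st(145), amplitude = 5000),
        stim_segment(300, 360, st(160), amplitude = 5000)
      )
    ),
    fig5_alias = synth_config(
      seed = seed, duration_s = 360,
      noise = noise_model(amplitude = 1, exponent = 1),
      stim_segments = list(
        stim_segment(180, 240, st(125), amplitude = 5000),
        stim_segment(240, 300, st(145), amplitude = 5000),
        stim_segment(300, 360, st(165), amplitude = 5000)
      )
    ),
    fig6_trend = synth_config(
      seed = seed, duration_s = 1, # trend-only scenario; minimal recording
      trend = list(
        days = 28, hemispheres = c("Left", "Right"), baseline = 20,
        components = data.frame(
          cycles_per_day = c(12, 1, 0.5, 1 / 7),
          amplitude = c(1.5, 3, 2, 2),
          phase = c(0, 0.4, 1.1, 2.0)
        ),
        noise_sd = 1
      )
    )
  )
}
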