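#' Predict aliased stimulation-artifact line positions
#'
#' For each harmonic `k = 1..n_harmonics` of the stimulation frequency, the
#' observed line after sampling is `alias_frequency(k * stim_freq, fs)`. A
#' line is flagged as contaminating the clean band when it falls below the
#' conventional 80 Hz neural-analysis ceiling.
#'
#' @param stim_freq_hz stimulation frequency in Hz (> 0).
#' @param fs_hz sampling rate in Hz (default 250).
#' @param n_harmonics number of harmonics to predict (default 1).
#' @param clean_band_ceiling_hz contamination threshold (default 80).
#' @return A data.frame with columns `harmonic_index`, `source_hz`,
#'   `observed_hz`, `in_clean_band`.
#' @examples
#' predict_artifact_lines(145, 250)      # observed at 105 Hz
#' predict_artifact_lines(90, 250, 2)    # 90 Hz and 70 Hz (180 folds)
#' @export
predict_artifact_lines <- function(stim_freq_hz, fs_hz = 250, n_harmonics = 1L,
                                   clean_band_ceiling_hz = 80) {
  if (stim_freq_hz <= 0) stop("`stim_freq_hz` must be > 0")
  k <- seq_len(n_harmonics)
  src <- k * stim_freq_hz
  obs <- alias_frequency(src, fs_hz)
  data.frame(harmonic_index = k, source_hz = src, observed_hz = obs,
             in_clean_band = obs < clean_band_ceiling_hz)
}

#' Soft-start ramp plan
#'
#' The device ramps stimulation in 0.1 mA steps at one of four programmable
#' cadences (1, 2, 4 or 8 s per step) for patient comfort.
#'
#' @param target_ma ramp target amplitude in mA.
#' @param step_ma step size in mA (device default 0.1).
#' @param step_interval_s seconds per step; one of 1, 2, 4, 8 unless
#'   `allow_any_interval`.
#' @param allow_any_interval permit non-device cadences.
#' @return An object of class `soft_start_plan` with `total_time_s`.
#' @export
soft_start_plan <- function(target_ma, step_ma = 0.1, step_interval_s = 1,
                            allow_any_interval = FALSE) {
  t <- soft_start_added_time(target_ma, step_ma, step_interval_s,
                             allow_any_interval)
  structure(list(target_ma = target_ma, step_ma = step_ma,
                 step_interval_s = step_interval_s, total_time_s = t,
                 n_steps = as.integer(round(t / step_interval_s))),
            class = "soft_start_plan")
}

#' Recording time added by the soft-start ramp
#'
#' `ceiling(target / step) * step_interval`, per ramp direction. A 2 mA
#' target at 0.1 mA steps takes 20 steps, hence 20 s at the fastest cadence
#' and 160 s at the slowest; sessions with both ramp-up and ramp-down incur
#' twice this.
#'
#' @inheritParams soft_start_plan
#' @return Added time in seconds.
#' @export
soft_start_added_time <- function(target_ma, step_ma = 0.1, step_interval_s = 1,
                                  allow_any_interval = FALSE) {
  if (target_ma < 0) stop("`target_ma` must be >= 0")
  if (step_ma <= 0) stop("`step_ma` must be > 0")
  if (!allow_any_interval && !step_interval_s %in% c(1, 2, 4, 8))
    stop("`step_interval_s` must be one of 1, 2, 4, 8 (set allow_any_interval = TRUE to override)")
  # guard against binary round-up: 2/0.1 evaluates just above 20
  ceiling(target_ma / step_ma - 1e-9) * step_interval_s
}

#' Detect soft-start "banding" artifacts in a scalogram
#'
#' The amplitude steps of the soft-start ramp inject broadband transients at
#' the step cadence, visible as vertical bands. Detection: the broadband
#' power trace (column mean over the full frequency axis) is compared to
#' `threshold` times its rolling median; runs of exceedances recurring at
#' approximately `cadence_s` spacing are merged into intervals. The heuristic
#' is validated against this package's own synthetic ground truth only.
#'
#' @param scal a [scalogram()] covering at least 10 s.
#' @param cadence_s expected step cadence in seconds (default 1).
#' @param threshold multiple of the rolling median that counts as an
#'   exceedance (default 3).
#' @param median_window_s rolling-median window (default 11 s).
#' @param min_hits minimum number of cadence-spaced exceedances per interval.
#' @return A data.frame with columns `start_s`, `end_s` (possibly 0 rows).
#' @export
detect_banding <- function(scal, cadence_s = 1, threshold = 3,
                           median_window_s = 11, min_hits = 3L) {
  stopifnot(inherits(scal, "scalogram"))
  tt <- scal$times_s
  if (diff(range(tt)) < 10) stop("scalogram must cover at least 10 s")
  b <- colMeans(scal$magnitude)
  dt <- stats::median(diff(tt))
  half <- max(1L, floor((median_window_s / dt) / 2))
  roll_med <- vapply(seq_along(b), function(i) {
    stats::median(b[max(1, i - half):min(length(b), i + half)])
  }, numeric(1))
  hit <- which(b > threshold * roll_med)
  if (length(hit) < min_hits) return(data.frame(start_s = numeric(), end_s = numeric()))
  # collapse adjacent hit samples into events, then group events by cadence
  ev_t <- tt[hit]
  ev <- split(ev_t, cumsum(c(1, diff(ev_t) > cadence_s / 2)))
  ev_mid <- vapply(ev, stats::median, numeric(1))
  if (length(ev_mid) < min_hits) return(data.frame(start_s = numeric(), end_s = numeric()))
  # chain events spaced ~1 cadence apart; isolated noise exceedances fall
  # into weak groups that are dropped before the merge step
  gap_ok <- c(TRUE, abs(diff(ev_mid) - cadence_s) < 0.5 * cadence_s)
  grp <- cumsum(!gap_ok)
  out <- do.call(rbind, lapply(split(ev_mid, grp), function(g) {
    if (length(g) < min_hits) return(NULL)
    data.frame(start_s = min(g) - cadence_s / 2, end_s = max(g) + cadence_s / 2)
  }))
  if (is.null(out)) return(data.frame(start_s = numeric(), end_s = numeric()))
  rownames(out) <- NULL
  # a single missed burst splits one ramp into two strong chains; rejoin
  # chains separated by no more than a couple of cadences
  if (nrow(out) > 1) {
    keep <- out[1, , drop = FALSE]
    for (i in 2:nrow(out)) {
      if (out$start_s[i] - keep$end_s[nrow(keep)] <= 3 * cadence_s) {
        keep$end_s[nrow(keep)] <- out$end_s[i]
      } else {
        keep <- rbind(keep, out[i, ])
      }
    }
    out <- keep
    rownames(out) <- NULL
  }
  out
}

#' Amplifier-blanking timing feasibility
#'
#' During each stimulation pulse the amplifier input is shorted ("blanked").
#' The artifact is invisible to the digitiser when pulse width + passive
#' recharge + the blanking offset after the sample instant all fit inside one
#' intersample period (4 ms at 250 Hz).
#'
#' @param pulse_width_s stimulation pulse width in seconds.
#' @param recharge_s passive recharge duration in seconds.
#' @param fs_hz sampling rate in Hz.
#' @param blank_offset_after_sample_s delay between the sample instant and
#'   the pulse (default 0: pulse arrives immediately after sampling).
#' @return An object of class `blanking_timeline` with `sample_period_s`,
#'   `margin_s`, and `feasible`.
#' @export
blanking_feasibility <- function(pulse_width_s, recharge_s, fs_hz = 250,
                                 blank_offset_after_sample_s = 0) {
  if (pulse_width_s <= 0 || recharge_s <= 0 || fs_hz <= 0)
    stop("all timing arguments must be > 0")
  period <- 1 / fs_hz
  occupied <- pulse_width_s + recharge_s + blank_offset_after_sample_s
  structure(list(sample_period_s = period,
                 pulse_width_s = pulse_width_s,
                 recharge_s = recharge_s,
                 blank_offset_after_sample_s = blank_offset_after_sample_s,
                 margin_s = period - occupied,
                 feasible = occupied < period),
            class = "blanking_timeline")
}

#' @export
print.blanking_timeline <- function(x, ...) {
  cat(sprintf("<blanking_timeline> period %g ms, occupied %g ms, margin %g ms: %s\n",
              1e3 * x$sample_period_s,
              1e3 * (x$pulse_width_s + x$recharge_s + x$blank_offset_after_sample_s),
              1e3 * x$margin_s,
              if (x$feasible) "feasible" else "NOT feasible"))
  invisible(x)
}
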