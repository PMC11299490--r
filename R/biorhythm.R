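# At-home trend-log analysis: the device records a 10-minute average of band
# power (144 samples/day) into a 60-day FIFO buffer; rhythms with hourly to
# weekly periods appear as peaks on a cycles/day spectral axis.

biorhythm_targets <- data.frame(
  label = c("hourly", "circadian_90min", "half_day", "daily", "two_day", "weekly"),
  cycles_per_day = c(24, 16, 12, 1, 0.5, 1 / 7),
  stringsAsFactors = FALSE
)

#' Named biorhythm frequencies
#'
#' The label-to-frequency table used by [detect_biorhythms()]: hourly
#' (24 cycles/day), circadian/90 min (16), half-day (12), daily (1),
#' two-day (0.5), weekly (1/7). The label/value pairing is kept verbatim
#' from the device-analysis convention.
#'
#' @return A data.frame with columns `label` and `cycles_per_day`.
#' @export
biorhythm_frequencies <- function() biorhythm_targets

#' Regularise a trend log onto the 144 samples/day grid
#'
#' Snaps entries to the nearest 10-minute slot, averages duplicates landing
#' in the same slot, and linearly interpolates gaps, marking imputed points
#' in `gap_mask`. A masked fraction above 20% triggers a data-quality
#' warning.
#'
#' @param series a [trend_log_series()].
#' @param hemisphere which hemisphere's entries to use.
#' @return An object of class `regularized_trend`: `values`, `gap_mask`,
#'   `start` (POSIXct of the first slot), `grid_per_day` (144),
#'   `interval_s` (600).
#' @export
regularize <- function(series, hemisphere) {
  stopifnot(inherits(series, "trend_log_series"))
  df <- series$entries_per_hemisphere[[hemisphere]]
  if (is.null(df)) stop("no entries for hemisphere '", hemisphere, "'")
  step <- series$nominal_interval_s
  tnum <- as.numeric(df$timestamp)
  if (diff(range(tnum)) < 2 * 86400)
    stop("need at least 2 days of data to regularise")
  t0 <- round(min(tnum) / step) * step
  slot <- as.integer(round((tnum - t0) / step))
  n <- max(slot) + 1L
  vals <- rep(NA_real_, n)
  agg <- tapply(df$lfp_power, slot, mean)
  vals[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  gap <- is.na(vals)
  if (any(gap)) {
    idx <- seq_len(n)
    vals <- stats::approx(idx[!gap], vals[!gap], xout = idx, rule = 2)$y
  }
  if (mean(gap) > 0.2)
    warning(sprintf("%.0f%% of grid slots were imputed; treat results with caution",
                    100 * mean(gap)))
  structure(list(values = vals, gap_mask = gap,
                 start = as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"),
                 grid_per_day = as.integer(round(86400 / step)),
                 interval_s = step),
            class = "regularized_trend")
}

#' @export
print.regularized_trend <- function(x, ...) {
  cat(sprintf("<regularized_trend> %d points (%.1f days), %d imputed, from %s\n",
              length(x$values), length(x$values) / x$grid_per_day,
              sum(x$gap_mask), format_iso_utc(x$start)))
  invisible(x)
}

#' Cycles-per-day spectrum of a regularised trend
#'
#' The time-averaged Morlet scalogram magnitude of the (mean-removed) trend,
#' on a cycles/day axis; biorhythms appear as peaks at their cycle
#' frequencies. A Welch estimator is available behind the `method` flag.
#'
#' @param trend a [regularize()]d trend of at least 7 days for weekly-peak
#'   resolution (shorter spans drop the unresolvable low frequencies with a
#'   warning).
#' @param method `"scalogram_mean"` (default) or `"welch"`.
#' @param max_cpd upper frequency limit in cycles/day (default 72, the
#'   Nyquist limit of the 144/day grid).
#' @param voices_per_octave frequency resolution of the scalogram estimator.
#' @return A [spectral_estimate()] whose `freqs_hz` field holds cycles/day.
#' @export
cycles_per_day_spectrum <- function(trend, method = c("scalogram_mean", "welch"),
                                    max_cpd = 72, voices_per_octave = 12) {
  stopifnot(inherits(trend, "regularized_trend"))
  method <- match.arg(method)
  span_days <- length(trend$values) / trend$grid_per_day
  min_cpd <- 1 / 14
  if (span_days < 7) {
    warning("span under 7 days: frequencies below ", sprintf("%.3f", 2 / span_days),
            " cycles/day omitted (unresolvable)")
    min_cpd <- max(min_cpd, 2 / span_days)
  }
  x <- trend$values - mean(trend$values)
  fs_cpd <- trend$grid_per_day # samples per day
  if (method == "scalogram_mean") {
    freqs <- 2^seq(log2(min_cpd), log2(min(max_cpd, fs_cpd / 2)),
                   by = 1 / voices_per_octave)
    mag <- morlet_cwt(x, fs_cpd, freqs)
    spectral_estimate(freqs, rowMeans(mag), method = "scalogram_mean",
                      window_params = list(axis = "cycles_per_day",
                                           span_days = span_days))
  } else {
    rec <- time_domain_recording(x, sampling_rate_hz = fs_cpd,
                                 channel_label = "TREND")
    # window of ~2 weeks (in days) for sub-daily resolution, capped by span
    win <- min(span_days, 14)
    psd <- welch_psd(rec, window_s = win, overlap_frac = 0.5)
    keep <- psd$freqs_hz >= min_cpd & psd$freqs_hz <= max_cpd & psd$freqs_hz > 0
    spectral_estimate(psd$freqs_hz[keep], psd$power[keep], method = "welch",
                      window_params = list(axis = "cycles_per_day",
                                           span_days = span_days))
  }
}

#' Detect named biorhythm peaks
#'
#' Searches for a local maximum within +/-15% of each named biorhythm
#' frequency (see [biorhythm_frequencies()]) and reports its prominence as
#' the ratio of the peak magnitude to the spectrum's median magnitude. Peaks
#' below `min_prominence` are dropped. The default threshold of 4 is
#' calibrated so that pure measurement noise on a 28-day trend essentially
#' never clears it while sinusoidal components at amplitude-to-noise 3 always
#' do (their prominences exceed 7).
#'
#' @param spectrum a cycles/day [spectral_estimate()] from
#'   [cycles_per_day_spectrum()].
#' @param min_prominence minimum peak/median ratio (default 4).
#' @return A data.frame with columns `label`, `cycles_per_day` (the named
#'   target), `observed_cpd` (the peak bin), `magnitude`, `prominence`;
#'   0 rows when nothing is found.
#' @export
detect_biorhythms <- function(spectrum, min_prominence = 4) {
  stopifnot(inherits(spectrum, "spectral_estimate"))
  f <- spectrum$freqs_hz
  p <- spectrum$power
  base <- stats::median(p)
  rows <- lapply(seq_len(nrow(biorhythm_targets)), function(i) {
    f0 <- biorhythm_targets$cycles_per_day[i]
    sel <- which(f >= 0.85 * f0 & f <= 1.15 * f0)
    if (length(sel) == 0) return(NULL)
    j <- sel[which.max(p[sel])]
    # require a genuine local maximum (not a band edge riding a slope)
    if (j > 1 && p[j] < p[j - 1]) return(NULL)
    if (j < length(p) && p[j] < p[j + 1]) return(NULL)
    prom <- if (base > 0) p[j] / base else Inf
    if (!is.finite(prom) || prom < min_prominence) return(NULL)
    data.frame(label = biorhythm_targets$label[i], cycles_per_day = f0,
               observed_cpd = f[j], magnitude = p[j], prominence = prom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = character(), cycles_per_day = numeric(),
                      observed_cpd = numeric(), magnitude = numeric(),
                      prominence = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the device's 60-day FIFO buffer
#'
#' Models the implant's running memory: only entries within `buffer_days` of
#' the newest entry (per hemisphere) are retained.
#'
#' @param series a [trend_log_series()].
#' @return A [trend_log_series()] spanning at most `buffer_days`.
#' @export
enforce_fifo_buffer <- function(series) {
  stopifnot(inherits(series, "trend_log_series"))
  kept <- lapply(series$entries_per_hemisphere, function(df) {
    if (nrow(df) == 0) return(df)
    cutoff <- max(as.numeric(df$timestamp)) - series$buffer_days * 86400
    df[as.numeric(df$timestamp) >= cutoff, , drop = FALSE]
  })
  trend_log_series(kept, nominal_interval_s = series$nominal_interval_s,
                   buffer_days = series$buffer_days)
}
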