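#' Spectral estimate container
#'
#' A one-sided power spectrum with its frequency axis and provenance.
#'
#' @param freqs_hz strictly increasing frequency grid.
#' @param power nonnegative power per bin, same length as `freqs_hz`.
#' @param method estimator name, e.g. `"welch"`, `"periodogram"`,
#'   `"scalogram_mean"`, `"model"`.
#' @param window_params list of estimator parameters for provenance.
#' @return An object of class `spectral_estimate`.
#' @export
spectral_estimate <- function(freqs_hz, power, method = "periodogram",
                              window_params = list()) {
  if (length(freqs_hz) != length(power))
    stop("`freqs_hz` and `power` must have equal length")
  if (is.unsorted(freqs_hz, strictly = TRUE))
    stop("`freqs_hz` must be strictly increasing")
  if (any(power < 0)) stop("`power` must be nonnegative")
  structure(list(freqs_hz = as.numeric(freqs_hz), power = as.numeric(power),
                 method = method, window_params = window_params),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %s, %d bins, %.4g-%.4g Hz\n",
              x$method, length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz)))
  invisible(x)
}

#' Time-frequency magnitude container
#'
#' @param times_s time axis (seconds, or days for trend-log analyses).
#' @param freqs_hz frequency axis.
#' @param magnitude matrix, `length(freqs_hz)` rows by `length(times_s)`
#'   columns, nonnegative.
#' @param wavelet_params list of parameters (e.g. Morlet centre frequency).
#' @return An object of class `scalogram`.
#' @export
scalogram <- function(times_s, freqs_hz, magnitude, wavelet_params = list()) {
  magnitude <- as.matrix(magnitude)
  if (nrow(magnitude) != length(freqs_hz) || ncol(magnitude) != length(times_s))
    stop("`magnitude` must be freqs x times")
  if (any(magnitude < 0)) stop("`magnitude` must be nonnegative")
  structure(list(times_s = as.numeric(times_s), freqs_hz = as.numeric(freqs_hz),
                 magnitude = magnitude, wavelet_params = wavelet_params),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d freqs x %d times, %.4g-%.4g Hz\n",
              length(x$freqs_hz), length(x$times_s),
              min(x$freqs_hz), max(x$freqs_hz)))
  invisible(x)
}

# Hann-windowed segment FFTs shared by welch_psd and spectrogram.
# Returns one-sided power density per segment (freq x segment) scaled so that
# sum(power) * df approximates mean squared signal (Parseval).
segment_psd_matrix <- function(x, fs, window_s, overlap_frac) {
  nwin <- round(window_s * fs)
  if (nwin < 2) stop("window too short")
  if (length(x) < nwin)
    stop("recording shorter than one analysis window")
  step <- max(1L, nwin - floor(nwin * overlap_frac))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1)) # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nwin %/% 2 + 1L
  segs <- vapply(starts, function(s) {
    X <- stats::fft(x[s:(s + nwin - 1L)] * w)[seq_len(nfreq)]
    p <- Mod(X)^2 * scale
    # one-sided: double everything except DC (and Nyquist when nwin even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nwin %% 2 == 0) dbl[nfreq] <- 1
    p * dbl
  }, numeric(nfreq))
  list(freqs = (seq_len(nfreq) - 1L) * fs / nwin,
       power = matrix(segs, nrow = nfreq),
       times = (starts - 1L + nwin / 2) / fs)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram (Hann window) of a time-domain recording.
#' Power is a one-sided density in squared signal units per Hz; integrating
#' it over frequency recovers the mean squared signal (Parseval, up to
#' windowing tolerance).
#'
#' @param rec a [time_domain_recording()].
#' @param window_s analysis window length in seconds (default 1).
#' @param overlap_frac fractional overlap between windows (default 0.5).
#' @return A [spectral_estimate()] with method `"welch"`.
#' @export
welch_psd <- function(rec, window_s = 1, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "time_domain_recording"))
  m <- segment_psd_matrix(rec$samples, rec$sampling_rate_hz, window_s, overlap_frac)
  spectral_estimate(m$freqs, rowMeans(m$power), method = "welch",
                    window_params = list(window_s = window_s,
                                         overlap_frac = overlap_frac,
                                         window = "hann",
                                         n_segments = ncol(m$power)))
}

#' Short-time Fourier spectrogram
#'
#' Uniform-resolution time-frequency power, the estimator of choice for
#' narrowband high-frequency content such as stimulation artifact lines.
#' Columns average to the Welch PSD at matching parameters.
#'
#' @inheritParams welch_psd
#' @return A [scalogram()] whose magnitude holds one-sided power density.
#' @export
spectrogram <- function(rec, window_s = 1, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "time_domain_recording"))
  m <- segment_psd_matrix(rec$samples, rec$sampling_rate_hz, window_s, overlap_frac)
  scalogram(m$times, m$freqs, m$power,
            wavelet_params = list(kind = "stft", window_s = window_s,
                                  overlap_frac = overlap_frac))
}

# Morlet CWT magnitude via FFT convolution with the analytic Morlet wavelet.
# Normalised so a unit-amplitude sinusoid yields ridge magnitude ~1 at its
# own frequency, independent of frequency (constant-Q response).
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(max(n, 2)))
  xp <- c(x, rep(0, npad - n))
  X <- stats::fft(xp)
  k <- 0:(npad - 1)
  wk <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) * fs / npad
  fourier_factor <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    s <- fourier_factor / freqs[i]
    psi <- ifelse(wk > 0, exp(-(s * wk - omega0)^2 / 2), 0)
    wt <- stats::fft(X * psi, inverse = TRUE) / npad
    mag[i, ] <- 2 * Mod(wt[seq_len(n)]) # analytic: restore negative-freq half
  }
  mag
}

#' Morlet wavelet magnitude scalogram
#'
#' Continuous wavelet transform with an analytic Morlet wavelet on a
#' log-spaced frequency axis: frequency resolution is finer at low
#' frequencies and temporal resolution finer at high frequencies, the
#' complementary trade-off to the spectrogram. The magnitude is normalised so
#' that a unit-amplitude sinusoid produces a ridge of magnitude ~1 at its own
#' frequency at any frequency.
#'
#' @param rec a [time_domain_recording()].
#' @param freq_range_hz two-element range within `(0, fs/2]`.
#' @param voices_per_octave frequency bins per octave (default 12).
#' @param omega0 Morlet centre-frequency parameter (default 6).
#' @return A [scalogram()].
#' @export
morlet_scalogram <- function(rec, freq_range_hz = c(1, 100),
                             voices_per_octave = 12, omega0 = 6) {
  stopifnot(inherits(rec, "time_domain_recording"))
  fs <- rec$sampling_rate_hz
  lo <- freq_range_hz[1]; hi <- freq_range_hz[2]
  if (lo <= 0 || hi > fs / 2 || lo >= hi)
    stop("`freq_range_hz` must satisfy 0 < low < high <= fs/2")
  freqs <- 2^seq(log2(lo), log2(hi), by = 1 / voices_per_octave)
  mag <- morlet_cwt(rec$samples, fs, freqs, omega0)
  scalogram(seq_along(rec$samples) / fs - 1 / fs, freqs, mag,
            wavelet_params = list(kind = "morlet", omega0 = omega0,
                                  voices_per_octave = voices_per_octave))
}

#' Fit the filtered-1/f baseline model to a PSD
#'
#' Least-squares fit, in log-log space, of the acquisition-chain model
#' `power(f) = amplitude * f^(-exponent) * filter_gain(f)` to an observed
#' PSD. The cascade's gain is divided out, so the fit is a straight line in
#' `log(f)` with slope `-exponent` and intercept `log(amplitude)`. Bins
#' within `exclude_halfwidth_hz` of any frequency in `exclude_lines_hz`
#' (known artifact lines) are dropped.
#'
#' @param psd a [spectral_estimate()].
#' @param cascade the [filter_cascade()] that shaped the data.
#' @param fit_band_hz two-element band to fit over (default 3-95 Hz, below
#'   the hardware-switching line region).
#' @param exclude_lines_hz frequencies of known artifact lines to mask out.
#' @param exclude_halfwidth_hz half-width of the mask around each line (Hz).
#' @return A list with `noise` (the fitted [noise_model()]), `r_squared`,
#'   `residual_sd` (log-power residual SD), and `n_bins`.
#' @export
fit_baseline_model <- function(psd, cascade, fit_band_hz = c(3, 95),
                               exclude_lines_hz = numeric(),
                               exclude_halfwidth_hz = 2) {
  stopifnot(inherits(psd, "spectral_estimate"))
  f <- psd$freqs_hz; p <- psd$power
  keep <- f >= fit_band_hz[1] & f <= fit_band_hz[2] & p > 0
  for (fl in exclude_lines_hz)
    keep <- keep & abs(f - fl) > exclude_halfwidth_hz
  if (sum(keep) < 5)
    stop("fewer than 5 usable bins in the fit band")
  f <- f[keep]; p <- p[keep]
  y <- log(p) - log(filter_gain(cascade, f))
  fit <- stats::lm(y ~ log(f))
  co <- stats::coef(fit)
  list(noise = noise_model(amplitude = exp(unname(co[1])),
                           exponent = -unname(co[2])),
       r_squared = summary(fit)$r.squared,
       residual_sd = stats::sd(stats::residuals(fit)),
       n_bins = length(f))
}

#' Mean power in a frequency band
#'
#' Mean of the PSD bins whose centres lie inside the band; the default
#' 40-80 Hz band sits above alpha/beta neural activity and below the aliased
#' stimulation and hardware-switching lines, where the spectrum is dominated
#' by the pink-noise floor.
#'
#' @param psd a [spectral_estimate()].
#' @param band_hz two-element `(low, high)` band in Hz.
#' @return Scalar mean power.
#' @export
band_mean_power <- function(psd, band_hz = c(40, 80)) {
  stopifnot(inherits(psd, "spectral_estimate"))
  if (band_hz[1] >= band_hz[2]) stop("band must satisfy low < high")
  sel <- psd$freqs_hz >= band_hz[1] & psd$freqs_hz <= band_hz[2]
  if (!any(sel)) stop("band contains no PSD bins")
  mean(psd$power[sel])
}

#' Locate narrowband spectral lines
#'
#' Finds local maxima that stand above the smooth local background (a running
#' median of the PSD) by at least `prominence`, the signature of stimulation
#' artifact lines riding on the pink-noise floor. Results are sorted by
#' absolute power, so the first row is the dominant line.
#'
#' @param psd a [spectral_estimate()].
#' @param min_freq_hz ignore bins below this frequency (default 30, above
#'   the steep 1/f region).
#' @param prominence minimum peak/background ratio (default 5).
#' @param background_width_hz width of the running-median background window
#'   (default 11 Hz, wide enough that a windowing-leakage skirt of a few
#'   bins cannot dominate the median).
#' @return A data.frame with columns `freq_hz`, `power`, `prominence`,
#'   sorted by decreasing power (0 rows when no line is found).
#' @export
find_spectral_lines <- function(psd, min_freq_hz = 30, prominence = 5,
                                background_width_hz = 11) {
  stopifnot(inherits(psd, "spectral_estimate"))
  f <- psd$freqs_hz; p <- psd$power
  df <- stats::median(diff(f))
  k <- max(7L, as.integer(round(background_width_hz / df)))
  if (k %% 2 == 0) k <- k + 1L
  bg <- stats::runmed(p, k, endrule = "keep")
  n <- length(p)
  # extend the interior background to the edges: the endpoint rules would let
  # a line sitting at a grid edge (e.g. exactly at Nyquist) mask itself
  half <- k %/% 2
  if (n > k) {
    bg[seq_len(half)] <- bg[half + 1L]
    bg[(n - half + 1L):n] <- bg[n - half]
  }
  is_peak <- c(FALSE, p[2:(n - 1)] >= p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n], FALSE)
  # a line sitting in the last bin (e.g. exactly at Nyquist) is still a peak
  is_peak[n] <- p[n] >= p[n - 1]
  sel <- which(is_peak & f >= min_freq_hz & bg > 0 & p > prominence * bg)
  out <- data.frame(freq_hz = f[sel], power = p[sel], prominence = p[sel] / bg[sel])
  out[order(-out$power), , drop = FALSE]
}

#' Band-power result for one lead
#'
#' @param mean_power mean band power (nonnegative).
#' @param band_hz the band it was computed over.
#' @param channel_label channel identifier.
#' @param impedance_ohm bipolar impedance of the recording pair, if measured.
#' @return An object of class `band_power_result`.
#' @export
band_power_result <- function(mean_power, band_hz = c(40, 80),
                              channel_label = "", impedance_ohm = NA_real_) {
  if (mean_power < 0) stop("`mean_power` must be >= 0")
  if (band_hz[1] >= band_hz[2]) stop("band must satisfy low < high")
  structure(list(mean_power = mean_power, band_hz = band_hz,
                 channel_label = channel_label, impedance_ohm = impedance_ohm),
            class = "band_power_result")
}

#' Pearson correlation between impedance and band power
#'
#' Tests whether the broadband noise floor of a lead scales with its bipolar
#' impedance. One `(impedance, mean_power)` pair per entry; the p-value is
#' two-sided from the t distribution with `n - 2` degrees of freedom, with no
#' multiple-testing correction.
#'
#' @param results a list of [band_power_result()] objects (or a data.frame
#'   with `impedance_ohm` and `mean_power` columns).
#' @return A list with `r`, `p`, and `n`.
#' @export
impedance_power_correlation <- function(results) {
  if (is.data.frame(results)) {
    imp <- results$impedance_ohm; pow <- results$mean_power
  } else {
    imp <- vapply(results, function(r) r$impedance_ohm, numeric(1))
    pow <- vapply(results, function(r) r$mean_power, numeric(1))
  }
  if (length(imp) < 3) stop("need at least 3 pairs")
  if (anyNA(imp) || anyNA(pow)) stop("impedance must be present for all entries")
  if (stats::sd(imp) == 0 || stats::sd(pow) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(imp, pow, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(imp))
}
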