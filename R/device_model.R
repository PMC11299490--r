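#' ADC specification of the sensing front end
#'
#' Describes the analog-to-digital conversion chain of a sensing-enabled DBS
#' implant: the amplifier gain applied before digitisation, the digitiser's
#' symmetric voltage range, and the converter's bit depth. Defaults match the
#' Percept-PC-class front end: a gain of 250 into a 16-bit converter spanning
#' +/-1.2 V, which corresponds to +/-4.8 mV at the electrode and an ideal
#' resolution of about 146 nV per least-significant bit.
#'
#' @param bits integer bit depth of the converter (>= 1).
#' @param amplifier_gain dimensionless voltage gain before the digitiser (> 0).
#' @param digitizer_range_v symmetric half-range of the digitiser in volts
#'   (the converter spans `+/- digitizer_range_v`).
#' @return An object of class `adc_spec`.
#' @examples
#' spec <- adc_spec()
#' adc_input_range(spec)      # 0.0048 V referred to the electrode
#' adc_ideal_resolution(spec) # ~1.46e-7 V per LSB
#' @export
adc_spec <- function(bits = 16L, amplifier_gain = 250, digitizer_range_v = 1.2) {
  bits <- as.integer(bits)
  if (is.na(bits) || bits < 1L) stop("`bits` must be an integer >= 1")
  if (!is.numeric(amplifier_gain) || amplifier_gain <= 0)
    stop("`amplifier_gain` must be > 0")
  if (!is.numeric(digitizer_range_v) || digitizer_range_v <= 0)
    stop("`digitizer_range_v` must be > 0")
  structure(
    list(bits = bits, amplifier_gain = amplifier_gain,
         digitizer_range_v = digitizer_range_v),
    class = "adc_spec"
  )
}

#' @export
print.adc_spec <- function(x, ...) {
  cat(sprintf("<adc_spec> %d bits, gain %g, digitizer +/-%g V\n",
              x$bits, x$amplifier_gain, x$digitizer_range_v))
  cat(sprintf("  input range at electrode: +/-%g mV, ideal resolution %.3g nV/LSB\n",
              1e3 * adc_input_range(x), 1e9 * adc_ideal_resolution(x)))
  invisible(x)
}

#' Analog input range referred to the electrode
#'
#' The digitiser half-range divided by the amplifier gain: the largest signal
#' (half-range, in volts) at the electrode that the converter can represent.
#'
#' @param spec an [adc_spec()].
#' @return Half-range in volts at the electrode.
#' @export
adc_input_range <- function(spec) {
  stopifnot(inherits(spec, "adc_spec"))
  spec$digitizer_range_v / spec$amplifier_gain
}

#' Ideal ADC resolution referred to the electrode
#'
#' The full input span at the electrode (twice the half-range) divided by the
#' number of quantisation levels `2^bits`: volts per least-significant bit.
#'
#' @param spec an [adc_spec()].
#' @return Volts per LSB at the electrode.
#' @export
adc_ideal_resolution <- function(spec) {
  stopifnot(inherits(spec, "adc_spec"))
  2 * adc_input_range(spec) / 2^spec$bits
}

#' A single filter stage of the acquisition chain
#'
#' @param kind `"high_pass"` or `"low_pass"`.
#' @param corner_hz corner frequency in Hz (> 0).
#' @param order filter order (integer >= 1).
#' @param family `"first_order_cascade"` for an idealised analog stage with
#'   magnitude-squared response `1/(1 + (f/fc)^(2n))` (low-pass) or
#'   `(f/fc)^(2n)/(1 + (f/fc)^(2n))` (high-pass), or `"elliptic"` for a
#'   digital elliptic design (see `ripple_db`, `stopband_db`).
#' @param ripple_db passband ripple in dB (elliptic only).
#' @param stopband_db stopband attenuation in dB (elliptic only).
#' @return An object of class `filter_stage`.
#' @export
filter_stage <- function(kind = c("low_pass", "high_pass"), corner_hz, order = 1L,
                         family = c("first_order_cascade", "elliptic"),
                         ripple_db = 0.5, stopband_db = 40) {
  kind <- match.arg(kind)
  family <- match.arg(family)
  order <- as.integer(order)
  if (!is.numeric(corner_hz) || corner_hz <= 0) stop("`corner_hz` must be > 0")
  if (is.na(order) || order < 1L) stop("`order` must be an integer >= 1")
  structure(
    list(kind = kind, corner_hz = corner_hz, order = order, family = family,
         ripple_db = ripple_db, stopband_db = stopband_db),
    class = "filter_stage"
  )
}

#' Ordered filter cascade of the acquisition chain
#'
#' @param stages a list of [filter_stage()] objects, applied in order.
#' @param sampling_rate_hz sampling rate in Hz (the digital stages are designed
#'   against this rate; the Nyquist frequency is half of it).
#' @return An object of class `filter_cascade`.
#' @seealso [percept_cascade()] for the default device cascade.
#' @export
filter_cascade <- function(stages, sampling_rate_hz = 250) {
  if (!is.list(stages) || length(stages) == 0)
    stop("`stages` must be a nonempty list of filter_stage objects")
  ok <- vapply(stages, inherits, logical(1), what = "filter_stage")
  if (!all(ok)) stop("all elements of `stages` must be filter_stage objects")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be > 0")
  structure(list(stages = stages, sampling_rate_hz = sampling_rate_hz),
            class = "filter_cascade")
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat(sprintf("<filter_cascade> fs = %g Hz, %d stage(s)\n",
              x$sampling_rate_hz, length(x$stages)))
  for (s in x$stages) {
    cat(sprintf("  %s %s, corner %g Hz, order %d\n",
                s$family, s$kind, s$corner_hz, s$order))
  }
  invisible(x)
}

#' Default acquisition-chain filter cascade
#'
#' The device's documented chain: a 1st-order analog high-pass at 0.5 Hz, 1st-
#' and 3rd-order analog low-pass stages at 100 Hz (anti-aliasing), and a
#' 4th-order digital elliptic low-pass. The elliptic stage's passband ripple
#' (0.5 dB), stopband attenuation (40 dB) and corner (100 Hz) are package
#' defaults exposed as parameters, since only the order is documented.
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param elliptic_ripple_db,elliptic_stopband_db,elliptic_corner_hz elliptic
#'   stage parameters.
#' @return A [filter_cascade()].
#' @export
percept_cascade <- function(sampling_rate_hz = 250, elliptic_ripple_db = 0.5,
                            elliptic_stopband_db = 40, elliptic_corner_hz = 100) {
  filter_cascade(
    stages = list(
      filter_stage("high_pass", 0.5, 1L, "first_order_cascade"),
      filter_stage("low_pass", 100, 1L, "first_order_cascade"),
      filter_stage("low_pass", 100, 3L, "first_order_cascade"),
      filter_stage("low_pass", elliptic_corner_hz, 4L, "elliptic",
                   ripple_db = elliptic_ripple_db,
                   stopband_db = elliptic_stopband_db)
    ),
    sampling_rate_hz = sampling_rate_hz
  )
}

#' 1/f noise model
#'
#' Power-law ("pink") noise: `power(f) = amplitude * f^(-exponent)`, the
#' idealised broadband neural/electronic background against which the filter
#' response is fitted.
#'
#' @param amplitude power at 1 Hz (> 0), in squared signal units per Hz.
#' @param exponent spectral slope (>= 0); 1 is classic pink noise, 0 is white.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(amplitude = 1, exponent = 1) {
  if (!is.numeric(amplitude) || amplitude <= 0) stop("`amplitude` must be > 0")
  if (!is.numeric(exponent) || exponent < 0) stop("`exponent` must be >= 0")
  structure(list(amplitude = amplitude, exponent = exponent),
            class = "noise_model")
}

# magnitude-squared response of one stage at frequencies f (Hz)
stage_power_gain <- function(stage, f, fs) {
  if (stage$family == "first_order_cascade") {
    r <- (f / stage$corner_hz)^(2 * stage$order)
    if (stage$kind == "low_pass") 1 / (1 + r) else r / (1 + r)
  } else {
    # digital elliptic design against the cascade's sampling rate
    w <- stage$corner_hz / (fs / 2)
    type <- if (stage$kind == "low_pass") "low" else "high"
    flt <- signal::ellip(stage$order, stage$ripple_db, stage$stopband_db,
                         W = w, type = type)
    z <- exp(-1i * 2 * pi * f / fs)
    num <- outer(z, seq_along(flt$b) - 1, `^`) %*% flt$b
    den <- outer(z, seq_along(flt$a) - 1, `^`) %*% flt$a
    as.numeric(Mod(num / den)^2)
  }
}

#' Power gain of the filter cascade
#'
#' Product of the magnitude-squared responses of all stages, evaluated at the
#' given frequencies. The result is a dimensionless power (not amplitude)
#' gain in (0, 1] for the default cascade.
#'
#' @param cascade a [filter_cascade()].
#' @param freq_hz numeric vector of frequencies in `(0, fs/2]`.
#' @return Numeric vector of power gains.
#' @export
filter_gain <- function(cascade, freq_hz) {
  stopifnot(inherits(cascade, "filter_cascade"))
  fs <- cascade$sampling_rate_hz
  if (any(freq_hz <= 0) || any(freq_hz > fs / 2))
    stop(sprintf("frequencies must lie in (0, %g] Hz", fs / 2))
  g <- rep(1, length(freq_hz))
  for (s in cascade$stages) g <- g * stage_power_gain(s, freq_hz, fs)
  g
}

#' Theoretical spectrum of filtered 1/f noise
#'
#' The idealised total response overlay: power-law source noise shaped by the
#' cascade, `power(f) = amplitude * f^(-exponent) * filter_gain(f)`.
#'
#' @param cascade a [filter_cascade()].
#' @param noise a [noise_model()].
#' @param freqs_hz frequency grid in `(0, fs/2]`.
#' @return A [spectral_estimate()] with method `"model"`.
#' @export
ideal_spectrum <- function(cascade, noise, freqs_hz) {
  stopifnot(inherits(noise, "noise_model"))
  p <- noise$amplitude * freqs_hz^(-noise$exponent) * filter_gain(cascade, freqs_hz)
  spectral_estimate(freqs_hz, p, method = "model",
                    window_params = list(amplitude = noise$amplitude,
                                         exponent = noise$exponent))
}

#' Aliased (folded) frequency under sampling
#'
#' The apparent frequency at which a component of true frequency `f_hz`
#' appears after sampling at `fs_hz`: reduce modulo `fs`, then reflect about
#' the Nyquist frequency `fs/2`. A 145 Hz stimulation line sampled at 250 Hz
#' appears at 105 Hz; 160 Hz appears at 90 Hz; 165 Hz at 85 Hz.
#'
#' @param f_hz numeric vector of nonnegative frequencies in Hz.
#' @param fs_hz sampling rate in Hz (> 0).
#' @return Frequencies in `[0, fs/2]`.
#' @examples
#' alias_frequency(145, 250) # 105
#' alias_frequency(165, 250) # 85
#' @export
alias_frequency <- function(f_hz, fs_hz) {
  if (any(f_hz < 0)) stop("`f_hz` must be >= 0")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("`fs_hz` must be > 0")
  r <- f_hz %% fs_hz
  ifelse(r > fs_hz / 2, fs_hz - r, r)
}

#' Fold a spectrum about the Nyquist frequency
#'
#' Models what sampling does to spectral content defined up to the sampling
#' rate: every bin above Nyquist is reflected to `fs - f` and its power added
#' to the band below. Total power is conserved exactly. If a reflected bin
#' does not coincide with an existing sub-Nyquist bin, its power is
#' accumulated into the nearest one with a warning.
#'
#' @param spectrum a [spectral_estimate()] with frequencies in `(0, fs]`.
#' @param fs_hz sampling rate in Hz.
#' @return A [spectral_estimate()] on `[0, fs/2]`.
#' @export
fold_spectrum <- function(spectrum, fs_hz) {
  stopifnot(inherits(spectrum, "spectral_estimate"))
  f <- spectrum$freqs_hz
  p <- spectrum$power
  if (any(f < 0) || any(f > fs_hz))
    stop("spectrum frequencies must lie in [0, fs]")
  fa <- alias_frequency(f, fs_hz)
  below <- f <= fs_hz / 2
  out_f <- sort(unique(f[below]))
  if (length(out_f) == 0) out_f <- sort(unique(fa))
  out_p <- numeric(length(out_f))
  tol <- 1e-9 * max(fs_hz, 1)
  snapped <- FALSE
  for (i in seq_along(f)) {
    j <- which.min(abs(out_f - fa[i]))
    if (abs(out_f[j] - fa[i]) > tol) snapped <- TRUE
    out_p[j] <- out_p[j] + p[i]
  }
  if (snapped)
    warning("frequency grid not exactly foldable; reflected power accumulated into nearest bins")
  spectral_estimate(out_f, out_p, method = spectrum$method,
                    window_params = c(spectrum$window_params, list(folded = TRUE)))
}

#' Build a filter cascade from a YAML configuration file
#'
#' Reads a key-value configuration overriding the default cascade. Recognised
#' keys: `sampling_rate_hz`, `elliptic_ripple_db`, `elliptic_stopband_db`,
#' `elliptic_corner_hz`, and an optional `stages:` list with per-stage
#' `kind`, `corner_hz`, `order`, `family` entries replacing the default chain.
#'
#' @param path path to a YAML file.
#' @return A [filter_cascade()].
#' @export
cascade_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fs <- cfg$sampling_rate_hz %||% 250
  if (!is.null(cfg$stages)) {
    stages <- lapply(cfg$stages, function(s) {
      filter_stage(kind = s$kind %||% "low_pass",
                   corner_hz = s$corner_hz,
                   order = s$order %||% 1L,
                   family = s$family %||% "first_order_cascade",
                   ripple_db = s$ripple_db %||% 0.5,
                   stopband_db = s$stopband_db %||% 40)
    })
    filter_cascade(stages, fs)
  } else {
    percept_cascade(sampling_rate_hz = fs,
                    elliptic_ripple_db = cfg$elliptic_ripple_db %||% 0.5,
                    elliptic_stopband_db = cfg$elliptic_stopband_db %||% 40,
                    elliptic_corner_hz = cfg$elliptic_corner_hz %||% 100)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
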