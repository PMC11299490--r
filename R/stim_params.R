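#' Stimulation setting
#'
#' A constant-current stimulation parameter bundle used for energy (TEED) and
#' charge-density safety arithmetic. `cycle_on_s = cycle_off_s = 0` means
#' cycling is disabled (continuous stimulation).
#'
#' @param amplitude_ma stimulation amplitude in mA.
#' @param frequency_hz pulse rate in Hz.
#' @param pulse_width_us pulse width in microseconds.
#' @param impedance_ohm electrode impedance in ohms.
#' @param cycle_on_s,cycle_off_s cycling durations in seconds; both 0 for
#'   continuous stimulation.
#' @param electrode_area_cm2 electrode surface area in cm^2 (default 0.06).
#' @return An object of class `stim_setting`.
#' @export
stim_setting <- function(amplitude_ma, frequency_hz, pulse_width_us,
                         impedance_ohm = 1000, cycle_on_s = 0, cycle_off_s = 0,
                         electrode_area_cm2 = 0.06) {
  vals <- c(amplitude_ma, frequency_hz, pulse_width_us, impedance_ohm,
            cycle_on_s, cycle_off_s, electrode_area_cm2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all stimulation parameters must be finite and nonnegative")
  structure(
    list(amplitude_ma = amplitude_ma, frequency_hz = frequency_hz,
         pulse_width_us = pulse_width_us, impedance_ohm = impedance_ohm,
         cycle_on_s = cycle_on_s, cycle_off_s = cycle_off_s,
         electrode_area_cm2 = electrode_area_cm2,
         continuous = (cycle_on_s == 0 && cycle_off_s == 0)),
    class = "stim_setting"
  )
}

#' @export
print.stim_setting <- function(x, ...) {
  cyc <- if (x$continuous) "continuous"
         else sprintf("%g s on / %g s off", x$cycle_on_s, x$cycle_off_s)
  cat(sprintf("<stim_setting> %g mA, %g Hz, %g us, %g ohm, %s\n",
              x$amplitude_ma, x$frequency_hz, x$pulse_width_us,
              x$impedance_ohm, cyc))
  invisible(x)
}

#' Reference setting of the SANTE trial
#'
#' 2 mA, 145 Hz, 90 us at an assumed 1000 ohm impedance, continuous; the
#' standard reference point for relative-TEED maps.
#'
#' @return A [stim_setting()].
#' @export
sante_setting <- function() {
  stim_setting(amplitude_ma = 2, frequency_hz = 145, pulse_width_us = 90,
               impedance_ohm = 1000)
}

# BrainSense-compatible stimulation frequencies observed on the programmer
brainsense_frequencies <- c(55, 85, 110, 125, 145, 165, 180)

#' Energy delivered per stimulation pulse
#'
#' `TEED_wave = current^2 * impedance * pulse_width` in SI units (A, ohm, s),
#' i.e. joules per pulse for a rectangular constant-current phase.
#'
#' @param s a [stim_setting()].
#' @return Energy per pulse (A^2 * ohm * s).
#' @examples
#' teed_per_pulse(sante_setting()) # 3.6e-7
#' @export
teed_per_pulse <- function(s) {
  stopifnot(inherits(s, "stim_setting"))
  (s$amplitude_ma * 1e-3)^2 * s$impedance_ohm * (s$pulse_width_us * 1e-6)
}

#' Total electrical energy delivered per day
#'
#' The per-day total as conventionally printed for DBS energy budgeting:
#' `TEED_day = TEED_wave * frequency * 1440 * cycle_on / (cycle_on +
#' cycle_off)`, where 1440 is minutes per day (kept verbatim from the
#' conventional formula rather than rescaled to seconds) and the last factor
#' is the cycling duty fraction (1 when continuous).
#'
#' @param s a [stim_setting()].
#' @return Per-day energy in the formula's units (per-pulse energy x Hz x
#'   minutes/day x duty).
#' @export
teed_per_day <- function(s) {
  stopifnot(inherits(s, "stim_setting"))
  duty <- if (s$continuous) 1
          else s$cycle_on_s / (s$cycle_on_s + s$cycle_off_s)
  teed_per_pulse(s) * s$frequency_hz * 1440 * duty
}

#' Relative TEED over an amplitude x duty-cycle grid
#'
#' TEED relative to a reference setting, on a grid of amplitudes and duty
#' cycles, where "duty cycle" is the dimensionless product frequency x
#' pulse width (seconds). Because TEED is quadratic in amplitude and linear
#' in the frequency-pulse-width product, each cell is
#' `(amp/amp_ref)^2 * duty / duty_ref` (impedance and cycling held at the
#' reference's values).
#'
#' @param amplitudes_ma numeric vector of amplitudes in mA.
#' @param duty_cycles numeric vector of frequency x pulse-width products
#'   (dimensionless, pulse width in seconds).
#' @param reference a [stim_setting()] with nonzero TEED.
#' @return A matrix (amplitudes x duty cycles) of relative TEED, with
#'   `dimnames` giving the axis values.
#' @export
relative_teed_map <- function(amplitudes_ma, duty_cycles, reference = sante_setting()) {
  stopifnot(inherits(reference, "stim_setting"))
  if (teed_per_day(reference) <= 0) stop("reference setting has zero TEED")
  ref_duty <- reference$frequency_hz * reference$pulse_width_us * 1e-6
  rel <- outer((amplitudes_ma / reference$amplitude_ma)^2,
               duty_cycles / ref_duty)
  dimnames(rel) <- list(amplitude_ma = as.character(amplitudes_ma),
                        duty_cycle = as.character(duty_cycles))
  rel
}

#' Charge-per-phase and charge-density safety check
#'
#' Charge per phase is `amplitude * pulse_width`; dividing by the electrode
#' surface area gives the charge density, which the device limits to
#' 30 uC/cm^2 per phase before warning the programmer.
#'
#' @param s a [stim_setting()].
#' @param limit_uc_per_cm2 safety limit (default 30).
#' @return A list with `charge_per_phase_uc`, `density_uc_per_cm2`, and
#'   `within_limit`.
#' @export
charge_density_check <- function(s, limit_uc_per_cm2 = 30) {
  stopifnot(inherits(s, "stim_setting"))
  if (s$electrode_area_cm2 <= 0) stop("electrode area must be > 0")
  charge_uc <- (s$amplitude_ma * 1e-3) * (s$pulse_width_us * 1e-6) * 1e6
  density <- charge_uc / s$electrode_area_cm2
  list(charge_per_phase_uc = charge_uc,
       density_uc_per_cm2 = density,
       within_limit = density < limit_uc_per_cm2)
}

#' Validate a setting against BrainSense constraints
#'
#' Flags (as character messages): a stimulation frequency outside the set the
#' programmer allows during sensing (55, 85, 110, 125, 145, 165, 180 Hz), a
#' charge-density violation, and cycling faster than 1 s on / 1 s off (which
#' the vendor warns is battery-detrimental).
#'
#' @param s a [stim_setting()].
#' @param strict if `TRUE`, raise an error when any violation is found.
#' @return Character vector of violations (empty when clean), invisibly the
#'   same when `strict`.
#' @export
validate_brainsense_setting <- function(s, strict = FALSE) {
  stopifnot(inherits(s, "stim_setting"))
  v <- character()
  if (!s$frequency_hz %in% brainsense_frequencies)
    v <- c(v, sprintf(
      "frequency %g Hz not in the BrainSense-compatible set {%s}",
      s$frequency_hz, paste(brainsense_frequencies, collapse = ", ")))
  cd <- charge_density_check(s)
  if (!cd$within_limit)
    v <- c(v, sprintf("charge density %.3g uC/cm^2 exceeds the 30 uC/cm^2 limit",
                      cd$density_uc_per_cm2))
  if (!s$continuous && (s$cycle_on_s < 1 || s$cycle_off_s < 1))
    v <- c(v, "cycling faster than 1 s on / 1 s off is battery-detrimental")
  if (strict && length(v) > 0)
    stop(paste(v, collapse = "; "))
  v
}
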