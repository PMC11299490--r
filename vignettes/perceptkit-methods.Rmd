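---
title: "Methods: device modelling and LFP analysis in perceptkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: device modelling and LFP analysis in perceptkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perceptkit)
```

## The acquisition chain

A sensing-enabled DBS implant records a bipolar LFP from the contacts
flanking the stimulation contacts. perceptkit models the chain the signal
passes through before any analysis sees it:

1. **Amplification and digitisation.** A gain-250 amplifier feeds a 16-bit
   ADC spanning ±1.2 V. Referred to the electrode this is a ±4.8 mV input
   range and an ideal resolution of `2 × 4.8 mV / 2^16 ≈ 146 nV` per LSB
   (`adc_input_range()`, `adc_ideal_resolution()`). Quantisation itself is
   not simulated; only the ideal arithmetic is exposed.

2. **Filtering.** The default `percept_cascade()` is a 1st-order analog
   high-pass at 0.5 Hz, 1st- and 3rd-order analog low-pass stages at 100 Hz,
   and a 4th-order digital elliptic low-pass. The analog stages use the
   idealised magnitude-squared family `|H|² = 1/(1 + (f/f_c)^{2n})`
   (high-pass: its complement); no specific analog topology is claimed, so
   the simplest monotone family with the right order and corner is used.
   Only the filter order of the elliptic stage is documented for the device,
   so its remaining parameters are package defaults exposed as arguments:
   0.5 dB passband ripple, 40 dB stopband attenuation, 100 Hz corner,
   designed against the 250 Hz rate via `signal::ellip`. The model is
   magnitude-only; phase and group delay are out of scope.

3. **Sampling and folding.** Content above the 125 Hz Nyquist frequency is
   folded: `alias_frequency()` reduces modulo the sampling rate and reflects
   about Nyquist, and `fold_spectrum()` applies the same bookkeeping to a
   whole spectrum, conserving summed power exactly. Spectra are treated as
   one-sided real-signal spectra throughout; frequency grids are linear, in
   Hz, at bin centres.

The spectral *background* of a resting recording is modelled as pink noise
through this cascade: `P(f) = A · f^(−χ) · |H(f)|²` with χ = 1 by default
(`ideal_spectrum()`). Published noise-floor figures for this hardware
family disagree with one another, so the noise amplitude is a free
parameter everywhere rather than an asserted constant.

## Spectral estimators

* **Welch PSD** (`welch_psd()`): Hann window, 1 s segments, 50 % overlap.
  The device names no estimator parameters, so these are the field's
  conventions: 1 s gives 1 Hz resolution, enough to separate the stimulation
  lines; Hann and 50 % overlap are the textbook compromise. The output is a
  one-sided density whose integral matches the mean squared signal within
  windowing tolerance (checked to 5 % in the tests). A constant signal
  concentrates its power in the DC main lobe of the window — exactly one
  bin only for a rectangular window, the first few bins for Hann.

* **Spectrogram** (`spectrogram()`): the same segmentation with time kept;
  its column mean equals the Welch PSD bit-for-bit, which the tests assert.
  Uniform resolution makes it the right view for narrowband stimulation
  lines.

* **Morlet scalogram** (`morlet_scalogram()`): analytic Morlet wavelet with
  centre-frequency parameter ω₀ = 6 and 12 voices per octave, computed by
  FFT convolution. The magnitude is normalised so a unit-amplitude sinusoid
  produces a ridge of magnitude ≈ 1 at its own frequency at any frequency,
  which makes ridge heights comparable across the log-spaced axis
  (constant-Q). Low frequencies get fine frequency resolution and coarse
  time resolution; high frequencies the reverse — the property the tests
  measure directly via ridge widths (in octaves) and step-response rise
  times.

* **Baseline fit** (`fit_baseline_model()`): dividing the PSD by the
  cascade's gain turns the model into a straight line in log–log space;
  amplitude and exponent come from `stats::lm`. The default fit band is
  3–95 Hz: below 3 Hz the high-pass corner and long-window variance
  dominate; above 95 Hz the elliptic transition begins, and the band also
  stays clear of the ~105 Hz hardware-switching line seen on real devices.
  Known artifact lines can be masked (±2 Hz by default). Because segment
  averaging makes the log-periodogram bias negligible at these segment
  counts, recovery bias on synthetic data is under 1 % (tests require
  < 5 % over 20 seeds).

* **Line finding** (`find_spectral_lines()`): local maxima that stand at
  least 5× above an 11-Hz running-median background, ranked by absolute
  power. The background window is deliberately wider than the Hann leakage
  skirt so a line cannot mask itself; at the grid edges the interior
  background is extended outward, since a line exactly at Nyquist (e.g.
  125 Hz stimulation, which the device phase-locks to the sample clock)
  sits in the last bin.

* **Impedance–power correlation** (`impedance_power_correlation()`):
  Pearson r on one (impedance, band-power) pair per entry, two-sided p from
  the t distribution with n−2 df, no multiple-testing correction. How pairs
  are formed (per hemisphere, per patient, pooled by lead family) is left
  to the caller, because published analyses are ambiguous on whether
  hemispheres are pooled; the function simply correlates the pairs it is
  given.

## Stimulation arithmetic

`teed_per_pulse()` is `I² · Z · pw` in SI units (A, Ω, s): 3.6 × 10⁻⁷ at
the SANTE reference (2 mA, 90 µs, 1000 Ω). `teed_per_day()` multiplies by
pulse rate, the constant 1440, and the cycling duty fraction. The 1440
(minutes per day) is kept verbatim from the conventional formula even
though mixing Hz with minutes makes the unit awkward — fidelity to the
printed convention beats unit purity here, and the quantity is used only
relatively. Cycling with `cycle_on = cycle_off = 0` means cycling disabled
(duty 1), so the degenerate "0/0 duty" case cannot arise. Charge per phase
is `I · pw`; density divides by the electrode area (0.06 cm² default) and
gates at 30 µC/cm²/phase. `validate_brainsense_setting()` additionally
flags frequencies outside the sensing-compatible set
{55, 85, 110, 125, 145, 165, 180} Hz and cycling faster than 1 s on / 1 s
off. Vendor battery-longevity tables are not shipped; an interpolation hook
would accept a user-supplied table.

Note that the "no artifact in the clean band" design property applies to
*aliased* lines: stimulation above Nyquist folds no lower than 70 Hz
(reached at 180 Hz). Stimulation at 55 Hz simply appears at 55 Hz — it is
not an aliasing artifact.

## At-home trend logs and biorhythms

The device logs a 10-minute average of band power, 144 samples/day, into a
60-day FIFO buffer (`enforce_fifo_buffer()` models the retention).
`regularize()` snaps entries to the nearest 10-minute slot, averages
duplicates, linearly interpolates gaps and records them in a mask; a masked
fraction above 20 % warns rather than fails. Timestamps are assumed to mark
the *end* of each averaging interval; nothing downstream depends on this
beyond a fixed 10-minute phase. Whether the logged "average power" is a
linear or squared-amplitude quantity is not documented; the package treats
it as an arbitrary nonnegative power unit.

`cycles_per_day_spectrum()` is the time-averaged Morlet magnitude on a
cycles/day axis (Welch behind a flag), spanning 1/14 to 72 cycles/day.
The biorhythm labels follow the device-analysis convention — hourly (24),
circadian/90 min (16), half-day (12), daily (1), two-day (0.5), weekly
(1/7 cycles/day) — with the label/value pairing kept verbatim even where a
label reads oddly against its value ("hourly" at 24 cycles/day is a 1-hour
period); all "samp/day" figures are read as cycles/day, consistent with the
144 samples/day sampling statement. `detect_biorhythms()` searches ±15 %
around each named frequency for a local maximum and reports prominence as
the ratio of peak magnitude to the spectrum's median.

The default prominence threshold (4) was calibrated once against the
package's own generator: across white-noise 28-day trends the largest
spurious peak prominence observed was ≈ 3, while sinusoidal components at
amplitude-to-noise ratio 3 produce prominences above 7.5. The threshold
sits between the two on a log scale. This calibration is specific to the
generator's Gaussian noise; heavier-tailed real-world noise may need a
higher threshold.

## The synthetic-data generator

`generate_recording()` synthesises the background directly in the frequency
domain so its one-sided PSD is *exactly* `A · f^(−χ) · |H(f)|²`, then adds:

* **Stimulation artifacts.** In the default `"pulse"` mode each segment
  contributes the Fourier-series harmonics of a rectangular pulse train at
  the programmed rate and width, each harmonic attenuated by the *analog*
  stages at its true (possibly above-Nyquist) frequency and by the digital
  stage at its aliased frequency, then sampled — so harmonics and folding
  arise from the physics rather than being placed by hand. A `"tone"` mode
  injects a single sinusoid for exact single-line tests. Artifact lines are
  synthesised in cosine phase, locked to the sample clock: the device times
  stimulation relative to sampling, and a Nyquist-rate line in sine phase
  would vanish at the sample instants. The default artifact amplitude
  (1000 signal units; 5000 in the sweep presets) reflects that the
  post-blanking residual at the amplifier input is orders of magnitude
  above the microvolt-scale neural signal — which is also why lines in the
  elliptic stopband (105–125 Hz) remain visible despite 40 dB attenuation.
  The amplifier itself (saturation, blanking transients) is not simulated;
  `blanking_feasibility()` covers the timing arithmetic separately.

* **A cardiac line** (default 1.2 Hz ≈ 72 bpm when enabled) as a pure
  sinusoid — no ECG morphology.

* **Soft-start banding**: one 40 ms broadband burst per 0.1 mA ramp step at
  the configured cadence, the ground truth for `detect_banding()`. That
  detector (rolling-median threshold at 3×, cadence-chained events,
  tolerance for one missed burst) is a heuristic of this toolkit, validated
  only against this synthetic ground truth.

`generate_trend()` produces baseline + biorhythm sinusoids + Gaussian
noise, floored at zero, 144 entries/day. Both generators are deterministic
given the seed and restore the caller's RNG state. What the generator does
**not** emulate: nonstationary neural rhythms (beta bursts, seizures),
movement artifacts, heavy-tailed or missing-not-at-random telemetry
dropouts, electrode-tissue drift, or quantisation. Passing tests therefore
demonstrate correctness of the *device arithmetic and estimator pipeline*,
not robustness to every property of clinical recordings.

## Numerical choices and problem sizes

* JSON serialisation uses 17 significant digits, so doubles round-trip
  bit-exactly; key order is fixed, making output byte-stable for a given
  configuration. Parse errors report a best-effort byte offset recovered
  from the validator's context window.
* `soft_start_added_time()` computes `ceiling(target/step)` with a 10⁻⁹
  slack because `2/0.1` exceeds 20 in binary floating point.
* Spectrum folding accumulates reflected bins into exactly matching output
  bins when the grid is foldable, and snaps to the nearest bin (with a
  warning) otherwise — power is conserved in both paths.
* The elliptic stopband is equiripple, so the ideal spectrum is strictly
  decreasing only through the transition band (checked on 100–109 Hz) and
  bounded, not monotone, beyond the first notch.
* Test and acceptance problem sizes: 60–120 s recordings at 250 Hz for
  spectral checks, 20 seeds for recovery properties, 28-day trends for
  biorhythm detection — large enough that Monte-Carlo envelopes are stable,
  small enough that the whole suite runs in well under a minute of compute
  per file.

## Limitations

Phase response, group delay, amplifier saturation and fixed-point effects
are not modelled. The JSON dialect is a minimal canonical form built from
the documented key names; real vendor exports nest additional structures
that are preserved opaquely but not interpreted. Battery-longevity
estimation requires vendor tables the package does not ship. Biorhythm
detection reports peak presence and prominence, not phase, and is not a
seizure-forecasting tool.
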