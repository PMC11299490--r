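test_that("Welch PSD localises tones, DC, and satisfies Parseval", {
  psd <- welch_psd(make_sine_rec(20, duration_s = 100, amplitude = 3))
  expect_equal(psd$freqs_hz[which.max(psd$power)], 20)
  # integrated density recovers the mean square (A^2/2 for a sine)
  df <- diff(psd$freqs_hz)[1]
  expect_equal(sum(psd$power) * df, 4.5, tolerance = 0.01)

  const <- time_domain_recording(rep(2, 1000), 250)
  pc <- welch_psd(const)
  expect_equal(pc$freqs_hz[which.max(pc$power)], 0)
  # all power concentrates at DC (the Hann main lobe spans the first bins)
  expect_gt(sum(pc$power[1:3]) / sum(pc$power), 0.999)

  expect_error(welch_psd(time_domain_recording(1:100, 250), window_s = 1),
               "shorter than one analysis window")
})

test_that("Welch PSD of shaped pink noise matches the theoretical overlay", {
  cz <- percept_cascade()
  # average over seeds to tighten the Monte-Carlo envelope
  acc <- NULL
  for (s in 1:5) {
    r <- generate_recording(synth_config(seed = s, duration_s = 60,
                                         noise = noise_model(2, 1)))
    p <- welch_psd(r)
    acc <- if (is.null(acc)) p$power else acc + p$power
  }
  acc <- acc / 5
  keep <- p$freqs_hz >= 3 & p$freqs_hz <= 95
  model <- ideal_spectrum(cz, noise_model(2, 1), p$freqs_hz[keep])
  ratio <- acc[keep] / model$power
  expect_true(all(ratio > 0.7 & ratio < 1.4))
})

test_that("Parseval holds within 5% on long stationary pink noise", {
  r <- generate_recording(synth_config(seed = 11, duration_s = 120,
                                       noise = noise_model(5, 1)))
  psd <- welch_psd(r)
  df <- diff(psd$freqs_hz)[1]
  expect_equal(sum(psd$power) * df, mean(r$samples^2), tolerance = 0.05)
})

test_that("spectrogram tracks lines in time and folds above-Nyquist tones", {
  fs <- 250
  t <- (0:14999) / fs
  # one minute of a 120 Hz artifact followed by silence
  x <- ifelse(t < 30, 20 * cos(2 * pi * 120 * t), 0)
  sg <- spectrogram(time_domain_recording(x, fs))
  i120 <- which.min(abs(sg$freqs_hz - 120))
  first <- sg$times_s < 29
  second <- sg$times_s > 31
  expect_true(all(sg$magnitude[i120, first] > 1))
  expect_true(all(sg$magnitude[i120, second] < 1e-10))

  # stationary sine: time-constant ridge
  sg2 <- spectrogram(make_sine_rec(40, 20))
  i40 <- which.min(abs(sg2$freqs_hz - 40))
  ridge <- sg2$magnitude[i40, ]
  expect_lt(stats::sd(ridge) / mean(ridge), 1e-6)

  # a 160 Hz tone sampled at 250 Hz appears at 90 Hz
  x3 <- cos(2 * pi * 160 * t)
  sg3 <- spectrogram(time_domain_recording(x3, fs))
  ridge_f <- sg3$freqs_hz[apply(sg3$magnitude, 2, which.max)]
  expect_true(all(ridge_f == 90))
})

test_that("spectrogram column-mean equals the Welch PSD", {
  r <- generate_recording(synth_config(seed = 3, duration_s = 30))
  psd <- welch_psd(r, window_s = 2, overlap_frac = 0.5)
  sg <- spectrogram(r, window_s = 2, overlap_frac = 0.5)
  expect_equal(rowMeans(sg$magnitude), psd$power, tolerance = 1e-12)
})

test_that("Morlet scalogram trades time for frequency resolution", {
  w2 <- morlet_scalogram(make_sine_rec(2, 60), c(1, 100))
  w80 <- morlet_scalogram(make_sine_rec(80, 60), c(1, 100))
  mid <- 2500:12500
  width_oct <- function(w) {
    prof <- rowMeans(w$magnitude[, mid])
    diff(range(log2(w$freqs_hz[prof > max(prof) / 2])))
  }
  # constant-Q: ridge width in octaves comparable at 2 Hz and 80 Hz
  expect_lt(abs(width_oct(w2) - width_oct(w80)), 0.25)

  # temporal response to an amplitude step is sharper at 80 Hz
  rise <- function(f0) {
    fs <- 250; t <- (0:14999) / fs
    x <- ifelse(t >= 30, 1, 0) * sin(2 * pi * f0 * t)
    sc <- morlet_scalogram(time_domain_recording(x, fs), c(1, 100))
    m <- sc$magnitude[which.min(abs(sc$freqs_hz - f0)), ]
    peak <- max(m)
    sc$times_s[min(which(m > 0.9 * peak))] - sc$times_s[min(which(m > 0.1 * peak))]
  }
  expect_lt(rise(80), rise(2) / 5)

  # silence maps to zero magnitude
  z <- morlet_scalogram(time_domain_recording(rep(0, 2500), 250), c(1, 100))
  expect_true(all(z$magnitude == 0))
})

test_that("a cardiac-like 1.2 Hz oscillation peaks in the 1-10 Hz scalogram mean", {
  cfg <- synth_config(seed = 21, duration_s = 60, noise = noise_model(1, 1),
                      cardiac_hz = 1.2, cardiac_amplitude = 3)
  sc <- morlet_scalogram(generate_recording(cfg), c(1, 10))
  prof <- rowMeans(sc$magnitude)
  fpk <- sc$freqs_hz[which.max(prof)]
  expect_equal(fpk, 1.2, tolerance = 0.07) # within one 1/12-octave bin
})

test_that("scalogram magnitude is shift invariant away from the edges", {
  fs <- 250
  x <- generate_recording(synth_config(seed = 6, duration_s = 40))$samples
  shift <- 250
  rec_a <- time_domain_recording(x[1:7500], fs)
  rec_b <- time_domain_recording(x[(1 + shift):(7500 + shift)], fs)
  wa <- morlet_scalogram(rec_a, c(4, 60))
  wb <- morlet_scalogram(rec_b, c(4, 60))
  mid <- 2000:5000
  rel <- abs(wa$magnitude[, mid + shift] - wb$magnitude[, mid]) /
    (abs(wa$magnitude[, mid + shift]) + 1e-12)
  expect_lt(stats::median(rel), 1e-6)
})

test_that("baseline model fitting recovers amplitude and exponent", {
  cz <- percept_cascade()
  r <- generate_recording(synth_config(seed = 13, duration_s = 120,
                                       noise = noise_model(4, 1)))
  fit <- fit_baseline_model(welch_psd(r), cz)
  expect_equal(fit$noise$exponent, 1, tolerance = 0.1)
  expect_equal(fit$noise$amplitude, 4, tolerance = 0.25)
  expect_gt(fit$r_squared, 0.95)

  # flat white noise against an all-pass cascade: exponent ~ 0
  allpass <- filter_cascade(list(filter_stage("low_pass", 1e9, 1L)), 250)
  rw <- generate_recording(synth_config(seed = 14, duration_s = 120,
                                        noise = noise_model(2, 0),
                                        cascade = allpass))
  fw <- fit_baseline_model(welch_psd(rw), allpass)
  expect_equal(fw$noise$exponent, 0, tolerance = 0.05)

  # scaling the PSD by 4 scales the amplitude by 4, exponent unchanged
  psd <- welch_psd(r)
  psd4 <- spectral_estimate(psd$freqs_hz, 4 * psd$power)
  f1 <- fit_baseline_model(psd, cz)
  f4 <- fit_baseline_model(psd4, cz)
  expect_equal(f4$noise$amplitude / f1$noise$amplitude, 4, tolerance = 1e-9)
  expect_equal(f4$noise$exponent, f1$noise$exponent, tolerance = 1e-9)

  # degenerate band
  expect_error(fit_baseline_model(psd, cz, fit_band_hz = c(50, 51)),
               "fewer than 5")
})

test_that("band power averages the selected bins", {
  f <- seq(1, 125, by = 1)
  flat <- spectral_estimate(f, rep(7, length(f)))
  expect_equal(band_mean_power(flat, c(40, 80)), 7)
  expect_error(band_mean_power(flat, c(200, 300)), "no PSD bins")

  pink <- spectral_estimate(f, 1 / f)
  sel <- f >= 40 & f <= 80
  expect_equal(band_mean_power(pink, c(40, 80)), mean(1 / f[sel]))
})

test_that("impedance-power correlation behaves like Pearson's r", {
  mk <- function(imp, pow) {
    mapply(function(i, p) band_power_result(p, impedance_ohm = i),
           imp, pow, SIMPLIFY = FALSE)
  }
  imp <- c(500, 800, 1100, 1500)
  res <- impedance_power_correlation(mk(imp, 2 * imp + 3))
  expect_equal(res$r, 1)
  expect_equal(res$n, 4)

  # sign equivariance
  pow <- c(1.2, 3.4, 2.2, 5.1)
  a <- impedance_power_correlation(data.frame(impedance_ohm = imp, mean_power = pow))
  b <- impedance_power_correlation(data.frame(impedance_ohm = -imp, mean_power = pow))
  expect_equal(b$r, -a$r)
  expect_equal(b$p, a$p)

  # simulation envelope: true r = 0.9, n = 8
  set.seed(101)
  for (i in 1:10) {
    z <- stats::rnorm(8)
    x <- z
    y <- 0.9 * z + sqrt(1 - 0.81) * stats::rnorm(8)
    r <- impedance_power_correlation(data.frame(impedance_ohm = 1000 + 200 * x,
                                                mean_power = 5 + y))$r
    expect_gt(r, 0.3); expect_lte(r, 1)
  }

  expect_error(impedance_power_correlation(
    data.frame(impedance_ohm = c(1, 1, 1), mean_power = c(1, 2, 3))),
    "zero variance")
  expect_error(impedance_power_correlation(
    data.frame(impedance_ohm = c(1, 2), mean_power = c(1, 2))), "at least 3")
})

test_that("spectral line finding reports the dominant injected line", {
  cfg <- synth_config(seed = 31, duration_s = 60, noise = noise_model(1, 1),
                      stim_mode = "tone",
                      stim_segments = list(
                        stim_segment(0, 60, stim_setting(2, 160, 90, 1000),
                                     amplitude = 50)))
  lines <- find_spectral_lines(welch_psd(generate_recording(cfg)))
  expect_gt(nrow(lines), 0)
  expect_equal(lines$freq_hz[1], 90)

  clean <- generate_recording(synth_config(seed = 32, duration_s = 60))
  expect_equal(nrow(find_spectral_lines(welch_psd(clean))), 0)
})
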