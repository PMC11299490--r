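# shared fixture builders; everything is generated in code at test time

make_sine_rec <- function(freq_hz, duration_s = 10, fs = 250, amplitude = 1,
                          phase = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  time_domain_recording(amplitude * sin(2 * pi * freq_hz * t + phase),
                        sampling_rate_hz = fs)
}

# independent folding oracle: scan |f - k*fs| over integers k
alias_oracle <- function(f, fs) {
  k <- 0:ceiling(f / fs + 1)
  min(abs(f - k * fs))
}

make_trend_cfg <- function(seed, days = 28, components = NULL, noise_sd = 1,
                           hemispheres = "Left", gap_slots = integer()) {
  if (is.null(components))
    components <- data.frame(cycles_per_day = 1, amplitude = 3, phase = 0)
  synth_config(seed = seed, duration_s = 1,
               trend = list(days = days, hemispheres = hemispheres,
                            baseline = 20, components = components,
                            noise_sd = noise_sd, gap_slots = gap_slots))
}

device_stim_frequencies <- c(55, 85, 110, 125, 145, 165, 180)
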