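test_that("a hand-written dialect document parses into recordings", {
  samples <- paste(rep("0.25", 2500), collapse = ",")
  txt <- sprintf(paste0(
    '{"SessionMetadata": {"Deidentified": true},',
    '"BrainSenseTimeDomain": [{"Channel": "LEFT_0-3",',
    '"SampleRateInHz": 250, "FirstPacketDateTime": "2026-03-01T12:00:00Z",',
    '"TimeDomainData": [%s],',
    '"VendorExtraField": "kept"}]}'), samples)
  rep <- parse_report(txt)
  expect_length(rep$time_domain, 1)
  expect_length(rep$time_domain[[1]]$samples, 2500) # 10 s x 250 Hz
  expect_equal(rep$time_domain[[1]]$channel_label, "LEFT_0-3")
  expect_equal(rep$time_domain[[1]]$extra$VendorExtraField, "kept")
  # the unrecognised key survives a round trip
  rep2 <- parse_report(write_report(rep))
  expect_equal(rep2$time_domain[[1]]$extra$VendorExtraField, "kept")
})

test_that("a 28-day 10-minute trend log parses to 144 entries per day", {
  tl <- generate_trend(make_trend_cfg(seed = 2, days = 28,
                                      hemispheres = c("Left", "Right")))
  rep <- percept_report(trend_logs = tl)
  rep2 <- parse_report(write_report(rep))
  for (h in c("Left", "Right")) {
    df <- rep2$trend_logs$entries_per_hemisphere[[h]]
    expect_equal(nrow(df), 28 * 144)
    expect_true(all(diff(as.numeric(df$timestamp)) == 600))
  }
})

test_that("reports round-trip exactly through the JSON dialect", {
  for (seed in 1:3) {
    cfg <- synth_config(seed = seed, duration_s = 5,
                        stim_segments = list(
                          stim_segment(0, 5, stim_setting(2, 145, 90, 1000))),
                        trend = list(days = 3, hemispheres = "Left",
                                     baseline = 20,
                                     components = data.frame(
                                       cycles_per_day = 1, amplitude = 3,
                                       phase = 0),
                                     noise_sd = 1))
    rep <- generate_report(cfg)
    rep$events <- list(
      event_record("2026-01-02T10:00:00Z", 2),
      event_record("2026-01-03T10:00:00Z", 4,
                   spectral_estimate(1:5, c(1, 2, 3, 2, 1))))
    rep$session_metadata$Nested <- list(a = 1, b = list("x", "y"))
    txt <- write_report(rep)
    rep2 <- parse_report(txt)
    expect_equal(rep2, rep)
    # serialisation is stable byte-for-byte
    expect_identical(write_report(rep2), txt)
  }
})

test_that("writing keeps sample counts and order intact", {
  cfg <- synth_config(seed = 9, duration_s = 180) # 3-minute recording
  rep <- generate_report(cfg)
  txt <- write_report(rep)
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_length(doc$BrainSenseTimeDomain[[1]]$TimeDomainData, 180 * 250)
  rep2 <- parse_report(txt)
  expect_identical(rep2$time_domain[[1]]$samples, rep$time_domain[[1]]$samples)
})

test_that("a metadata-only report writes empty sections and round-trips", {
  rep <- percept_report(session_metadata = list(DeviceId = "demo"))
  txt <- write_report(rep)
  rep2 <- parse_report(txt)
  expect_equal(rep2, rep)
  expect_equal(rep2$session_metadata$DeviceId, "demo")
})

test_that("malformed JSON fails with a byte offset, empty reports by name", {
  err <- tryCatch(parse_report('{"a": 1, b}'), error = conditionMessage)
  expect_match(err, "byte offset")
  expect_error(parse_report('{"OtherKey": 1}'), "empty report")
})

test_that("discontinuity handling merges only contiguous same-frequency runs", {
  st125 <- stim_setting(2, 125, 90, 1000)
  st145 <- stim_setting(2, 145, 90, 1000)
  t0 <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  mk <- function(start, stim) {
    time_domain_recording(rep(0.1, 250), 250, start_time = start,
                          channel_label = "LEFT_0-3", stim = stim)
  }
  # contiguous, same settings: merged on request, kept as stored otherwise
  rep <- percept_report(time_domain = list(mk(t0, st125), mk(t0 + 1, st125)))
  expect_length(split_on_discontinuity(rep), 2)
  merged <- split_on_discontinuity(rep, merge = TRUE)
  expect_length(merged, 1)
  expect_length(merged[[1]]$samples, 500)

  # a stimulation-frequency change always separates
  rep2 <- percept_report(time_domain = list(mk(t0, st125), mk(t0 + 1, st145)))
  expect_length(split_on_discontinuity(rep2, merge = TRUE), 2)

  # a time gap larger than one intersample interval always separates
  rep3 <- percept_report(time_domain = list(mk(t0, st125), mk(t0 + 3, st125)))
  expect_length(split_on_discontinuity(rep3, merge = TRUE), 2)

  # single entry returned unchanged
  rep4 <- percept_report(time_domain = list(mk(t0, st125)))
  expect_equal(split_on_discontinuity(rep4, merge = TRUE), rep4$time_domain)
})

test_that("container invariants are enforced", {
  expect_error(time_domain_recording(numeric(0)), "at least one")
  expect_error(time_domain_recording(1:5, sampling_rate_hz = 0), "sampling_rate")
  expect_error(time_domain_recording(1:5, channel_label = ""), "channel_label")
  expect_error(event_record("2026-01-01T00:00:00Z", 5), "1..4")
  df <- data.frame(timestamp = as.POSIXct("2026-01-01", tz = "UTC") + c(0, 0),
                   lfp_power = c(1, 2))
  expect_error(trend_log_series(list(Left = df)), "strictly increasing")
  df2 <- data.frame(timestamp = as.POSIXct("2026-01-01", tz = "UTC") + c(0, 600),
                    lfp_power = c(1, -2))
  expect_error(trend_log_series(list(Left = df2)), "lfp_power")
  # 75-day span requires the explicit override
  df3 <- data.frame(
    timestamp = as.POSIXct("2026-01-01", tz = "UTC") + (0:75) * 86400,
    lfp_power = 1)
  expect_error(trend_log_series(list(Left = df3)), "buffer")
  expect_s3_class(trend_log_series(list(Left = df3), allow_overfull = TRUE),
                  "trend_log_series")
})

test_that("naive timestamps are read as UTC with a warning", {
  expect_warning(r <- time_domain_recording(1, start_time = "2026-05-01T10:00:00"),
                 "UTC")
  expect_equal(format(r$start_time, "%H", tz = "UTC"), "10")
  # explicit offsets are honoured
  r2 <- time_domain_recording(1, start_time = "2026-05-01T10:00:00+02:00")
  expect_equal(format(r2$start_time, "%H", tz = "UTC"), "08")
})
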