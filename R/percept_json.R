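# Session-report JSON dialect: a minimal canonical form using the vendor's
# documented key names (BrainSenseTimeDomain / TimeDomainData / DiagnosticData
# / LFPTrendLogs / LFP / DateTime). Extra sibling keys are tolerated and
# preserved across a round trip.

format_iso_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_datetime <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  x <- as.character(x)
  if (grepl("Z$", x)) {
    out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  } else if (grepl("[+-][0-9]{2}:?[0-9]{2}$", x)) {
    x2 <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
    out <- as.POSIXct(x2, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  } else {
    warning("naive timestamp '", x, "' interpreted as UTC", call. = FALSE)
    out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  if (is.na(out)) stop("unparseable timestamp: ", x)
  out
}

#' One in-clinic time-domain LFP recording
#'
#' @param samples numeric vector of signal values. The dialect does not state
#'   units; this package treats them as microvolts and carries a `units`
#'   field (default `"uV"`).
#' @param sampling_rate_hz sampling rate in Hz (nominal 250).
#' @param start_time POSIXct (or ISO-8601 text) start of the recording.
#' @param channel_label nonempty text, `"HEMISPHERE_contactA-contactB"` with
#'   contact 0 the most distal (e.g. `"LEFT_0-3"`).
#' @param stim a [stim_setting()] active during the recording, or `NULL`.
#' @param units signal unit label.
#' @param extra list of unrecognised per-recording fields to preserve.
#' @return An object of class `time_domain_recording`.
#' @export
time_domain_recording <- function(samples, sampling_rate_hz = 250,
                                  start_time = as.POSIXct("2026-01-01 00:00:00", tz = "UTC"),
                                  channel_label = "LEFT_0-3", stim = NULL,
                                  units = "uV", extra = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("`samples` must contain at least one value")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be > 0")
  if (!nzchar(channel_label)) stop("`channel_label` must be nonempty")
  if (!is.null(stim) && !inherits(stim, "stim_setting"))
    stop("`stim` must be a stim_setting or NULL")
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 start_time = parse_datetime(start_time),
                 channel_label = channel_label, stim = stim, units = units,
                 extra = extra),
            class = "time_domain_recording")
}

#' @export
print.time_domain_recording <- function(x, ...) {
  cat(sprintf("<time_domain_recording> %s: %d samples @ %g Hz (%.1f s) from %s%s\n",
              x$channel_label, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz,
              format_iso_utc(x$start_time),
              if (is.null(x$stim)) "" else sprintf(", stim %g mA @ %g Hz",
                                                   x$stim$amplitude_ma,
                                                   x$stim$frequency_hz)))
  invisible(x)
}

#' At-home 10-minute-average band-power trend logs
#'
#' @param entries_per_hemisphere named list (hemisphere -> data.frame with
#'   columns `timestamp` (POSIXct), `lfp_power` (>= 0) and optionally
#'   `stim_amplitude_ma`), each ordered strictly increasing in time.
#' @param nominal_interval_s nominal spacing (600 s = 10 min).
#' @param buffer_days device FIFO buffer span (60 days).
#' @param allow_overfull permit a span exceeding `buffer_days` (e.g. merged
#'   downloads); otherwise such series are rejected — apply
#'   [enforce_fifo_buffer()] to model what the device retains.
#' @return An object of class `trend_log_series`.
#' @export
trend_log_series <- function(entries_per_hemisphere, nominal_interval_s = 600,
                             buffer_days = 60, allow_overfull = FALSE) {
  if (!is.list(entries_per_hemisphere) || is.null(names(entries_per_hemisphere)))
    stop("`entries_per_hemisphere` must be a named list of data.frames")
  for (h in names(entries_per_hemisphere)) {
    df <- entries_per_hemisphere[[h]]
    if (!is.data.frame(df) || !all(c("timestamp", "lfp_power") %in% names(df)))
      stop("each hemisphere needs columns `timestamp` and `lfp_power`")
    if (any(df$lfp_power < 0)) stop("`lfp_power` must be >= 0")
    if (nrow(df) > 1 && any(diff(as.numeric(df$timestamp)) <= 0))
      stop("timestamps within hemisphere '", h, "' must be strictly increasing")
    span_d <- diff(range(as.numeric(df$timestamp))) / 86400
    if (nrow(df) > 0 && span_d > buffer_days && !allow_overfull)
      stop(sprintf("span %.1f d exceeds the %g d buffer; set allow_overfull = TRUE or apply enforce_fifo_buffer()",
                   span_d, buffer_days))
  }
  structure(list(entries_per_hemisphere = entries_per_hemisphere,
                 nominal_interval_s = nominal_interval_s,
                 buffer_days = buffer_days),
            class = "trend_log_series")
}

#' @export
print.trend_log_series <- function(x, ...) {
  cat("<trend_log_series>\n")
  for (h in names(x$entries_per_hemisphere)) {
    df <- x$entries_per_hemisphere[[h]]
    cat(sprintf("  %s: %d entries", h, nrow(df)))
    if (nrow(df) > 0)
      cat(sprintf(", %s .. %s", format_iso_utc(min(df$timestamp)),
                  format_iso_utc(max(df$timestamp))))
    cat("\n")
  }
  invisible(x)
}

#' Patient- or physician-marked event
#'
#' @param timestamp POSIXct (or ISO-8601 text).
#' @param event_type integer in 1..4 (one of up to four physician-defined
#'   labels).
#' @param snapshot_psd optional [spectral_estimate()] captured at the event.
#' @return An object of class `event_record`.
#' @export
event_record <- function(timestamp, event_type = 1L, snapshot_psd = NULL) {
  event_type <- as.integer(event_type)
  if (is.na(event_type) || event_type < 1L || event_type > 4L)
    stop("`event_type` must be an integer in 1..4")
  if (!is.null(snapshot_psd) && !inherits(snapshot_psd, "spectral_estimate"))
    stop("`snapshot_psd` must be a spectral_estimate or NULL")
  structure(list(timestamp = parse_datetime(timestamp),
                 event_type = event_type, snapshot_psd = snapshot_psd),
            class = "event_record")
}

#' A full session report
#'
#' @param session_metadata free-form named list (device id, deidentified
#'   flag, ...). Unrecognised top-level keys of a parsed report are stored
#'   here.
#' @param time_domain list of [time_domain_recording()] objects, ordered by
#'   start time.
#' @param trend_logs a [trend_log_series()] or `NULL`.
#' @param events list of [event_record()] objects.
#' @return An object of class `percept_report`.
#' @export
percept_report <- function(session_metadata = list(), time_domain = list(),
                           trend_logs = NULL, events = list()) {
  if (length(time_domain) > 0) {
    ok <- vapply(time_domain, inherits, logical(1), what = "time_domain_recording")
    if (!all(ok)) stop("`time_domain` must contain time_domain_recording objects")
    st <- vapply(time_domain, function(r) as.numeric(r$start_time), numeric(1))
    if (is.unsorted(st)) stop("`time_domain` entries must be ordered by start time")
  }
  if (!is.null(trend_logs) && !inherits(trend_logs, "trend_log_series"))
    stop("`trend_logs` must be a trend_log_series or NULL")
  structure(list(session_metadata = session_metadata, time_domain = time_domain,
                 trend_logs = trend_logs, events = events),
            class = "percept_report")
}

#' @export
print.percept_report <- function(x, ...) {
  cat(sprintf("<percept_report> %d recording(s), %d event(s)%s\n",
              length(x$time_domain), length(x$events),
              if (is.null(x$trend_logs)) "" else ", with trend logs"))
  invisible(x)
}

# best-effort byte offset of a JSON syntax error, recovered from the
# validator's context snippet
json_error_offset <- function(txt, err) {
  lines <- strsplit(err, "\n", fixed = TRUE)[[1]]
  caret <- grep("\\^\\s*$", lines)
  if (length(caret) == 0 || caret[1] < 2) return(NA_integer_)
  snippet <- trimws(lines[caret[1] - 1])
  if (!nzchar(snippet)) return(NA_integer_)
  pos <- regexpr(snippet, txt, fixed = TRUE)
  if (pos < 0) return(NA_integer_)
  as.integer(pos + nchar(snippet) - 1L)
}

known_toplevel_keys <- c("SessionMetadata", "BrainSenseTimeDomain",
                         "DiagnosticData", "Events")

stim_to_json <- function(s) {
  list(AmplitudeInMilliAmps = s$amplitude_ma, RateInHertz = s$frequency_hz,
       PulseWidthInMicroSecond = s$pulse_width_us,
       ImpedanceInOhms = s$impedance_ohm,
       CycleOnSec = s$cycle_on_s, CycleOffSec = s$cycle_off_s,
       ElectrodeAreaCm2 = s$electrode_area_cm2)
}

stim_from_json <- function(x) {
  if (is.null(x)) return(NULL)
  stim_setting(amplitude_ma = x$AmplitudeInMilliAmps %||% 0,
               frequency_hz = x$RateInHertz %||% 0,
               pulse_width_us = x$PulseWidthInMicroSecond %||% 0,
               impedance_ohm = x$ImpedanceInOhms %||% 1000,
               cycle_on_s = x$CycleOnSec %||% 0,
               cycle_off_s = x$CycleOffSec %||% 0,
               electrode_area_cm2 = x$ElectrodeAreaCm2 %||% 0.06)
}

#' Parse a session-report JSON document
#'
#' Reads the dialect into a [percept_report()]: in-clinic recordings from
#' `BrainSenseTimeDomain` (one [time_domain_recording()] per entry, split
#' exactly as stored), at-home data from `DiagnosticData` -> `LFPTrendLogs`
#' with per-entry `DateTime` and `LFP` values, and events from `Events`.
#' Unrecognised top-level keys are preserved in `session_metadata`;
#' unrecognised per-recording keys in each recording's `extra`.
#'
#' @param json_text JSON text (or a length-one path is *not* accepted; read
#'   the file first, e.g. `parse_report(readLines(path))`).
#' @return A [percept_report()].
#' @export
parse_report <- function(json_text) {
  txt <- paste(json_text, collapse = "\n")
  v <- jsonlite::validate(txt)
  if (!isTRUE(v)) {
    err <- attr(v, "err") %||% "invalid JSON"
    off <- json_error_offset(txt, err)
    stop(sprintf("malformed JSON near byte offset %s: %s",
                 ifelse(is.na(off), "?", off),
                 strsplit(err, "\n")[[1]][1]), call. = FALSE)
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(doc$BrainSenseTimeDomain) &&
      is.null(doc$DiagnosticData$LFPTrendLogs))
    stop("empty report: neither BrainSenseTimeDomain nor DiagnosticData/LFPTrendLogs present",
         call. = FALSE)

  meta <- doc$SessionMetadata %||% list()
  extra_top <- doc[setdiff(names(doc), known_toplevel_keys)]
  meta <- c(meta, extra_top)

  rec_known <- c("Channel", "SampleRateInHz", "FirstPacketDateTime",
                 "TimeDomainData", "Units", "Stim")
  recs <- lapply(doc$BrainSenseTimeDomain %||% list(), function(e) {
    time_domain_recording(
      samples = as.numeric(unlist(e$TimeDomainData)),
      sampling_rate_hz = e$SampleRateInHz %||% 250,
      start_time = parse_datetime(e$FirstPacketDateTime),
      channel_label = e$Channel %||% "UNKNOWN_0-3",
      stim = stim_from_json(e$Stim),
      units = e$Units %||% "uV",
      extra = { x <- e[setdiff(names(e), rec_known)]
                if (length(x) == 0) list() else x }
    )
  })

  trends <- NULL
  tl <- doc$DiagnosticData$LFPTrendLogs
  if (!is.null(tl)) {
    per_h <- lapply(tl, function(entries) {
      ts <- do.call(c, lapply(entries, function(x) parse_datetime(x$DateTime)))
      df <- data.frame(
        timestamp = as.POSIXct(ts, tz = "UTC"),
        lfp_power = vapply(entries, function(x) as.numeric(x$LFP), numeric(1)),
        stim_amplitude_ma = vapply(entries, function(x)
          as.numeric(x$AmplitudeInMilliAmps %||% NA_real_), numeric(1))
      )
      df[order(df$timestamp), , drop = FALSE]
    })
    trends <- trend_log_series(per_h, allow_overfull = TRUE)
  }

  events <- lapply(doc$Events %||% list(), function(e) {
    psd <- NULL
    if (!is.null(e$SnapshotPSD))
      psd <- spectral_estimate(unlist(e$SnapshotPSD$FreqsHz),
                               unlist(e$SnapshotPSD$Power),
                               method = "periodogram")
    event_record(parse_datetime(e$DateTime), e$EventType %||% 1L, psd)
  })

  percept_report(session_metadata = meta, time_domain = recs,
                 trend_logs = trends, events = events)
}

#' Read a session report from a file
#'
#' @param path path to a `.json` report.
#' @return A [percept_report()].
#' @export
read_report <- function(path) {
  parse_report(readChar(path, file.info(path)$size, useBytes = TRUE))
}

#' Serialise a session report to JSON text
#'
#' Emits the dialect with stable key ordering using the documented key names;
#' the output is accepted by [parse_report()] and round-trips all recognised
#' fields exactly (full double precision).
#'
#' @param report a [percept_report()].
#' @param path optional file to write to.
#' @return JSON text, invisibly when `path` is given.
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "percept_report"))
  doc <- list(SessionMetadata = report$session_metadata)
  doc$BrainSenseTimeDomain <- lapply(report$time_domain, function(r) {
    e <- list(Channel = r$channel_label,
              SampleRateInHz = r$sampling_rate_hz,
              FirstPacketDateTime = format_iso_utc(r$start_time),
              Units = r$units,
              TimeDomainData = as.list(r$samples))
    if (!is.null(r$stim)) e$Stim <- stim_to_json(r$stim)
    c(e, r$extra)
  })
  if (!is.null(report$trend_logs)) {
    doc$DiagnosticData <- list(LFPTrendLogs = lapply(
      report$trend_logs$entries_per_hemisphere, function(df) {
        lapply(seq_len(nrow(df)), function(i) {
          e <- list(DateTime = format_iso_utc(df$timestamp[i]),
                    LFP = df$lfp_power[i])
          if (!is.null(df$stim_amplitude_ma) && !is.na(df$stim_amplitude_ma[i]))
            e$AmplitudeInMilliAmps <- df$stim_amplitude_ma[i]
          e
        })
      }))
  }
  if (length(report$events) > 0) {
    doc$Events <- lapply(report$events, function(ev) {
      e <- list(DateTime = format_iso_utc(ev$timestamp),
                EventType = ev$event_type)
      if (!is.null(ev$snapshot_psd))
        e$SnapshotPSD <- list(FreqsHz = as.list(ev$snapshot_psd$freqs_hz),
                              Power = as.list(ev$snapshot_psd$power))
      e
    })
  }
  # I(17) significant digits: doubles survive the round trip bit-exactly
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                          null = "null", pretty = FALSE)
  txt <- as.character(txt)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

same_stim_frequency <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  isTRUE(all.equal(a$frequency_hz, b$frequency_hz))
}

#' Split (or merge) recordings at discontinuities
#'
#' Each stored recording already corresponds to a segment separated by a
#' user-initiated pause or a change in programmed stimulation frequency.
#' This walks the stored entries and, with `merge = TRUE`, joins consecutive
#' entries that are contiguous (start-time gap no more than one intersample
#' interval beyond the previous entry's end) *and* share the same stimulation
#' frequency; entries differing in stimulation frequency or separated by a
#' gap are always kept apart.
#'
#' @param report a [percept_report()].
#' @param merge join contiguous same-setting segments (default `FALSE`).
#' @return A list of [time_domain_recording()] objects.
#' @export
split_on_discontinuity <- function(report, merge = FALSE) {
  stopifnot(inherits(report, "percept_report"))
  recs <- report$time_domain
  if (length(recs) <= 1 || !merge) return(recs)
  out <- list(recs[[1]])
  for (i in 2:length(recs)) {
    prev <- out[[length(out)]]
    cur <- recs[[i]]
    expected_next <- as.numeric(prev$start_time) +
      length(prev$samples) / prev$sampling_rate_hz
    gap <- as.numeric(cur$start_time) - expected_next
    contiguous <- abs(gap) <= 1 / prev$sampling_rate_hz + 1e-9
    same <- same_stim_frequency(prev$stim, cur$stim) &&
      identical(prev$channel_label, cur$channel_label) &&
      isTRUE(all.equal(prev$sampling_rate_hz, cur$sampling_rate_hz))
    if (contiguous && same) {
      prev$samples <- c(prev$samples, cur$samples)
      out[[length(out)]] <- prev
    } else {
      out[[length(out) + 1L]] <- cur
    }
  }
  out
}
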