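#' Experimental protocol for a DAM experiment
#'
#' Describes the timing of an activity-monitor run: when lights come on,
#' how many days flies acclimate, how many baseline (fed) days are scored,
#' and when the starvation window starts. Times are clock times ("HH:MM").
#' The default protocol is the common design: lights-on at 10:00, 2 days
#' acclimation, 2 baseline days, a 24 h starvation window starting at
#' 13:00 (Zeitgeber hour 3) of the day after baseline.
#'
#' @param lights_on clock time of lights-on ("HH:MM"); Zeitgeber hour 0.
#' @param acclimation_days integer days discarded before baseline scoring.
#' @param baseline_days integer days of fed (baseline) recording.
#' @param starvation_start clock time at which flies are moved to
#'   agar-only medium on the starvation day.
#' @param starvation_hours duration of the starvation window, hours.
#' @return an object of class `dam_protocol`.
#' @export
#' @examples
#' dam_protocol()
dam_protocol <- function(lights_on = "10:00", acclimation_days = 2,
                         baseline_days = 2, starvation_start = "13:00",
                         starvation_hours = 24) {
  stopifnot(acclimation_days >= 0, baseline_days >= 1, starvation_hours > 0)
  p <- list(
    lights_on = lights_on,
    acclimation_days = as.integer(acclimation_days),
    baseline_days = as.integer(baseline_days),
    starvation_start = starvation_start,
    starvation_hours = starvation_hours
  )
  # zeitgeber hour at which starvation begins (e.g. 13:00 - 10:00 = ZH3)
  p$starvation_zh <- (clock_hours(starvation_start) - clock_hours(lights_on)) %% 24
  class(p) <- "dam_protocol"
  p
}

clock_hours <- function(hhmm) {
  parts <- as.numeric(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  parts[1] + parts[2] / 60 + (if (length(parts) > 2) parts[3] / 3600 else 0)
}

#' @export
print.dam_protocol <- function(x, ...) {
  cat("DAM protocol: lights-on", x$lights_on,
      "| acclimation", x$acclimation_days, "d | baseline", x$baseline_days,
      "d | starvation", paste0(x$starvation_hours, "h"),
      "from", x$starvation_start, sprintf("(ZH%g)\n", x$starvation_zh))
  invisible(x)
}

#' Read a TriKinetics DAM monitor file
#'
#' Parses the standard 42-column DAM2-style text layout: reading index,
#' date (`"%d %b %y"`), time (`"%H:%M:%S"`), a status code, six reserved
#' columns of which the last is the light sensor, and 32 per-channel
#' beam-break counts. Sub-minute files are summed into one-minute bins so
#' that all downstream sleep metrics operate on beam breaks per minute.
#'
#' @param path path to a tab-separated monitor file.
#' @param dialect monitor format; only `"dam2"` is implemented.
#' @return a data frame of class `dam_readings` with columns `index`,
#'   `datetime` (POSIXct, UTC), `status`, `light`, and `ch1`..`ch32`.
#' @export
read_dam_file <- function(path, dialect = "dam2") {
  dialect <- match.arg(dialect, "dam2")
  if (!file.exists(path)) stop("cannot read monitor file: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) stop("monitor file is empty: ", path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42L)
  if (length(bad)) {
    stop("monitor file ", path, ": expected 42 tab-separated columns, row ",
         bad[1], " has ", nf[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 42L, byrow = TRUE)
  datetime <- as.POSIXct(strptime(paste(m[, 2], m[, 3]),
                                  "%d %b %y %H:%M:%S", tz = "UTC"))
  if (anyNA(datetime)) {
    stop("monitor file ", path, ": unparseable date/time at row ",
         which(is.na(datetime))[1])
  }
  counts <- matrix(suppressWarnings(as.integer(m[, 11:42])), ncol = 32L)
  if (anyNA(counts)) {
    stop("monitor file ", path, ": non-integer count at row ",
         which(rowSums(is.na(counts)) > 0)[1])
  }
  if (any(counts < 0)) stop("monitor file ", path, ": negative counts")
  out <- data.frame(
    index = as.integer(m[, 1]),
    datetime = datetime,
    status = as.integer(m[, 4]),
    light = as.integer(m[, 10])
  )
  colnames(counts) <- paste0("ch", 1:32)
  out <- cbind(out, as.data.frame(counts))
  if (is.unsorted(out$datetime, strictly = TRUE)) {
    stop("monitor file ", path, ": timestamps are not strictly increasing")
  }
  dt <- as.numeric(diff(out$datetime), units = "secs")
  if (length(unique(dt)) > 1) {
    stop("monitor file ", path, ": bin width is not constant")
  }
  bin <- if (length(dt)) dt[1] else 60
  if (bin < 60) out <- sum_to_minutes(out, bin)
  if (length(dt) && bin > 60) {
    stop("monitor file ", path, ": bin width ", bin, " s exceeds one minute")
  }
  structure(out, class = c("dam_readings", "data.frame"),
            dialect = dialect, bin_seconds = 60)
}

sum_to_minutes <- function(readings, bin) {
  per <- as.integer(60 / bin)
  if (per * bin != 60) stop("bin width ", bin, " s does not divide one minute")
  minute <- as.POSIXct(floor(as.numeric(readings$datetime) / 60) * 60,
                       origin = "1970-01-01", tz = "UTC")
  g <- match(minute, unique(minute))
  ch <- as.matrix(readings[paste0("ch", 1:32)])
  agg <- rowsum(ch, g)
  keep <- !duplicated(g)
  out <- readings[keep, c("index", "datetime", "status", "light")]
  out$datetime <- unique(minute)
  out$index <- seq_len(nrow(out))
  cbind(out, as.data.frame(agg))
}

#' Write readings back out in DAM monitor format
#'
#' Inverse of [read_dam_file()]; round trips counts bit-exactly.
#'
#' @param readings a `dam_readings` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dam_file <- function(readings, path) {
  ch <- as.matrix(readings[paste0("ch", 1:32)])
  # C locale month abbreviations regardless of session locale
  old <- Sys.getlocale("LC_TIME"); on.exit(Sys.setlocale("LC_TIME", old))
  Sys.setlocale("LC_TIME", "C")
  lines <- paste(
    readings$index,
    format(readings$datetime, "%d %b %y"),
    format(readings$datetime, "%H:%M:%S"),
    readings$status, 1L, 0L, 0L, 0L, 0L, readings$light,
    apply(ch, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Annotate one monitor channel as a per-minute activity trace
#'
#' Extracts a single fly's beam-break series and labels every minute with
#' Zeitgeber time (hours since lights-on), light phase (day is ZT in
#' [0, 12), night is [12, 24)), feeding condition (starved during the
#' protocol's starvation window, fed otherwise), and an acclimation flag
#' (acclimation minutes are retained but excluded from summaries).
#'
#' @param readings a `dam_readings` data frame.
#' @param channel monitor channel, 1..32.
#' @param metadata list with fly factors: `fly_id`, `line`, `population`,
#'   `sex`, `temperature` (missing entries allowed).
#' @param protocol a [dam_protocol()].
#' @return a data frame of class `activity_trace` with columns `datetime`,
#'   `zt` (hours), `phase` ("day"/"night"), `condition` ("fed"/"starved"),
#'   `acclimation` (logical), `beam_breaks`; fly factors as attributes.
#' @export
annotate_trace <- function(readings, channel, metadata = list(),
                           protocol = dam_protocol()) {
  stopifnot(channel %in% 1:32)
  datetime <- readings$datetime
  breaks <- readings[[paste0("ch", channel)]]
  lights_on_h <- clock_hours(protocol$lights_on)
  frac_day <- (as.numeric(datetime) / 3600) %% 24  # hours past UTC midnight
  zt <- (frac_day - lights_on_h) %% 24
  # experiment day 1 starts at the lights-on preceding (or at) the first reading
  t0 <- as.numeric(datetime[1]) - (zt[1] * 3600)
  elapsed_h <- (as.numeric(datetime) - t0) / 3600
  starv_start_h <- (protocol$acclimation_days + protocol$baseline_days) * 24 +
    protocol$starvation_zh
  starv_end_h <- starv_start_h + protocol$starvation_hours
  if (max(elapsed_h) < starv_end_h - 1 / 60) {
    stop("protocol coverage error: recording ends at ",
         round(max(elapsed_h), 2), " h but the starvation window ends at ",
         starv_end_h, " h")
  }
  baseline_end_h <- (protocol$acclimation_days + protocol$baseline_days) * 24
  out <- data.frame(
    datetime = datetime,
    zt = zt,
    phase = ifelse(zt < 12, "day", "night"),
    condition = ifelse(elapsed_h >= starv_start_h & elapsed_h < starv_end_h,
                       "starved", "fed"),
    acclimation = elapsed_h < protocol$acclimation_days * 24,
    # fed summaries use the baseline days only; fed minutes on the
    # starvation day before food removal carry baseline = FALSE
    baseline = elapsed_h >= protocol$acclimation_days * 24 &
      elapsed_h < baseline_end_h,
    beam_breaks = breaks
  )
  # minutes after the starvation window (if recorded) are neither baseline
  # fed nor starved; drop them from the trace
  out <- out[elapsed_h < starv_end_h, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("activity_trace", "data.frame"),
            fly_id = metadata$fly_id %||% paste0("ch", channel),
            line = metadata$line, population = metadata$population,
            sex = metadata$sex, temperature = metadata$temperature,
            protocol = protocol)
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("Activity trace for fly %s: %d minutes (%d fed, %d starved, %d acclimation), %d beam breaks total\n",
              attr(x, "fly_id"), nrow(x),
              sum(x$baseline),
              sum(x$condition == "starved"), sum(x$acclimation),
              sum(x$beam_breaks)))
  invisible(x)
}

trace_meta <- function(trace) {
  list(fly_id = attr(trace, "fly_id"), line = attr(trace, "line"),
       population = attr(trace, "population"), sex = attr(trace, "sex"),
       temperature = attr(trace, "temperature"))
}

#' Flag flies that died or escaped during recording
#'
#' A fly whose final contiguous run of zero-activity minutes is at least
#' `terminal_quiet_hours` long is flagged as dead or escaped. Flagged
#' flies should be excluded from fed-period sleep summaries. For the
#' starvation period the start of the terminal zero run is retained as a
#' rough per-fly death-time estimate (vial censuses, not monitor traces,
#' are the basis of LD50 estimation).
#'
#' @param trace an `activity_trace`.
#' @param terminal_quiet_hours threshold for the terminal zero run, hours.
#' @return a list of class `fly_qc`: `flagged` (logical),
#'   `terminal_zero_minutes`, `death_time` (datetime of the start of the
#'   terminal run if flagged, else NA), and `trace` truncated to the
#'   minutes before the terminal zero run (the full trace if unflagged).
#' @export
flag_dead_or_escaped <- function(trace, terminal_quiet_hours = 12) {
  x <- trace$beam_breaks
  n <- length(x)
  nz <- which(x > 0)
  run <- if (length(nz)) n - max(nz) else n
  flagged <- run >= terminal_quiet_hours * 60
  structure(list(
    fly_id = attr(trace, "fly_id"),
    flagged = flagged,
    terminal_zero_minutes = run,
    death_time = if (flagged && run < n) trace$datetime[n - run + 1] else
      if (flagged) trace$datetime[1] else as.POSIXct(NA),
    trace = if (flagged) trace[seq_len(n - run), , drop = FALSE] else trace
  ), class = "fly_qc")
}

#' @export
print.fly_qc <- function(x, ...) {
  cat(sprintf("Fly %s: %s (terminal zero run %.1f h)\n", x$fly_id,
              if (x$flagged) "flagged dead/escaped" else "alive",
              x$terminal_zero_minutes / 60))
  invisible(x)
}

#' Read a channel-to-fly metadata table
#'
#' @param path CSV with columns monitor, channel, line, population, sex,
#'   temperature.
#' @return a data frame.
#' @export
read_dam_metadata <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("monitor", "channel", "line", "population", "sex", "temperature")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  meta
}
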