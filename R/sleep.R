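#' Score sleep bouts from a per-minute activity trace
#'
#' Fly sleep is defined, following the standard activity-monitor
#' convention, as a maximal run of at least `min_bout` consecutive
#' minutes with zero beam breaks. Bouts are scored within one feeding
#' condition window (the baseline fed days, or the 24 h starvation
#' window); acclimation minutes are never scored. Runs are clipped to the
#' window, so a run that is shorter than `min_bout` after clipping does
#' not count as sleep.
#'
#' @param trace an [annotate_trace()] activity trace.
#' @param window feeding condition defining the scoring window, `"fed"`
#'   or `"starved"`.
#' @param min_bout minimum immobility run length counted as sleep, minutes.
#' @return a data frame of class `sleep_bouts`, one row per bout:
#'   `start` (minute index within the window, 1-based), `length`
#'   (minutes), `zt_start`, `phase_at_start`, `condition`.
#' @export
#' @examples
#' tr <- structure(
#'   data.frame(datetime = as.POSIXct("2020-01-01", tz = "UTC") + 60 * (0:99),
#'              zt = (0:99) / 60, phase = "day", condition = "fed",
#'              acclimation = FALSE,
#'              beam_breaks = rep(c(2L, 0L), times = c(10, 90))),
#'   class = c("activity_trace", "data.frame"), fly_id = "demo")
#' score_sleep(tr, "fed")
score_sleep <- function(trace, window = c("fed", "starved"), min_bout = 5) {
  window <- match.arg(window)
  w <- trace[window_select(trace, window), , drop = FALSE]
  empty <- data.frame(start = integer(), length = integer(),
                      zt_start = numeric(), phase_at_start = character(),
                      condition = character())
  if (nrow(w) < min_bout) {
    warning("window '", window, "' is shorter than min_bout; no bouts scored")
    return(structure(empty, class = c("sleep_bouts", "data.frame"),
                     window = window, min_bout = min_bout))
  }
  runs <- zero_runs(w$beam_breaks, min_bout)
  if (!length(runs$start)) {
    return(structure(empty, class = c("sleep_bouts", "data.frame"),
                     window = window, min_bout = min_bout))
  }
  out <- data.frame(
    start = runs$start,
    length = runs$length,
    zt_start = w$zt[runs$start],
    phase_at_start = w$phase[runs$start],
    condition = window
  )
  structure(out, class = c("sleep_bouts", "data.frame"),
            window = window, min_bout = min_bout)
}

# scoring window: the fed window is the baseline days; the starved window
# is the starvation period; acclimation never scores
window_select <- function(trace, window) {
  if (window == "fed") {
    if ("baseline" %in% names(trace)) trace$baseline & !trace$acclimation
    else trace$condition == "fed" & !trace$acclimation
  } else {
    trace$condition == "starved" & !trace$acclimation
  }
}

# maximal runs of zeros with length >= min_len, via run-length encoding
zero_runs <- function(x, min_len = 5) {
  if (!length(x)) return(list(start = integer(), length = integer()))
  r <- rle(x == 0)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_len
  list(start = (ends - r$lengths + 1L)[keep], length = r$lengths[keep])
}

# logical per-minute asleep indicator for a window of n minutes
asleep_indicator <- function(bouts, n) {
  asleep <- logical(n)
  for (i in seq_len(nrow(bouts))) {
    asleep[bouts$start[i]:(bouts$start[i] + bouts$length[i] - 1L)] <- TRUE
  }
  asleep
}

#' Summarize sleep phenotypes for one fly and condition
#'
#' Computes, for the whole window and its day/night portions: total sleep
#' as a percentage of window minutes, bout number, mean bout length, and
#' mean waking movement (beam breaks per awake minute). Sleep minutes of
#' a bout spanning the day/night boundary are split at the boundary so
#' that day + night sleep minutes always equal whole-window sleep
#' minutes; the bout itself is counted once, in the phase where it
#' started, and its full length enters that phase's mean bout length.
#'
#' @param trace an activity trace.
#' @param bouts bouts from [score_sleep()] on the same `window`; computed
#'   if missing.
#' @param window `"fed"` or `"starved"`.
#' @param min_bout passed to [score_sleep()] when `bouts` is missing.
#' @return a data frame of class `sleep_summary`, one row per period
#'   (`"whole"`, `"day"`, `"night"`): `fly_id`, `condition`, `period`,
#'   `minutes`, `sleep_minutes`, `total_sleep_pct`, `bout_number`,
#'   `mean_bout_length`, `mean_awake_movement`, plus the fly's factors.
#' @export
summarize_sleep <- function(trace, bouts = NULL, window = c("fed", "starved"),
                            min_bout = 5) {
  window <- match.arg(window)
  if (is.null(bouts)) bouts <- score_sleep(trace, window, min_bout)
  w <- trace[window_select(trace, window), , drop = FALSE]
  n <- nrow(w)
  asleep <- asleep_indicator(bouts, n)
  meta <- trace_meta(trace)
  row_for <- function(period, sel) {
    mins <- sum(sel)
    slp <- sum(asleep & sel)
    if (period == "whole") {
      bn <- nrow(bouts)
    } else {
      bn <- sum(bouts$phase_at_start == period)
    }
    mbl <- if (bn > 0) {
      if (period == "whole") sum(bouts$length) / bn
      else mean(bouts$length[bouts$phase_at_start == period])
    } else NA_real_
    awake <- sel & !asleep
    mam <- if (any(awake)) sum(w$beam_breaks[awake]) / sum(awake) else NA_real_
    data.frame(fly_id = meta$fly_id %||% NA_character_,
               line = meta$line %||% NA_character_,
               population = meta$population %||% NA_character_,
               sex = meta$sex %||% NA_character_,
               temperature = meta$temperature %||% NA_real_,
               condition = window, period = period,
               minutes = mins, sleep_minutes = slp,
               total_sleep_pct = 100 * slp / mins,
               bout_number = bn, mean_bout_length = mbl,
               mean_awake_movement = mam)
  }
  out <- rbind(row_for("whole", rep(TRUE, n)),
               row_for("day", w$phase == "day"),
               row_for("night", w$phase == "night"))
  structure(out, class = c("sleep_summary", "data.frame"))
}

#' Within-fly percent change in sleep under starvation
#'
#' `100 * (starved - fed) / fed`, computed per fly; negative values mean
#' starvation suppressed sleep. Flies with zero fed sleep have no defined
#' change and are returned as `NA` with a warning so they can be excluded
#' with a logged reason.
#'
#' @param fed_pct,starved_pct total sleep percentages (whole day), fed
#'   and starved; vectorized.
#' @return numeric vector of percent changes.
#' @export
#' @examples
#' percent_change_sleep(50, 40)  # -20
percent_change_sleep <- function(fed_pct, starved_pct) {
  bad <- !is.na(fed_pct) & fed_pct == 0
  if (any(bad)) {
    warning(sum(bad), " fly/flies with zero fed sleep excluded ",
            "(percent change undefined)")
  }
  out <- 100 * (starved_pct - fed_pct) / fed_pct
  out[bad] <- NA_real_
  out
}

#' Full per-fly sleep phenotype table
#'
#' Runs [score_sleep()] and [summarize_sleep()] for both conditions on a
#' list of traces and attaches the within-fly percent change in
#' whole-day sleep.
#'
#' @param traces list of activity traces.
#' @param min_bout minimum sleep bout length, minutes.
#' @return long data frame of per-fly, per-condition, per-period
#'   phenotypes; the whole-day fed rows carry `pct_change_sleep`.
#' @export
sleep_phenotypes <- function(traces, min_bout = 5) {
  rows <- lapply(traces, function(tr) {
    rbind(summarize_sleep(tr, window = "fed", min_bout = min_bout),
          summarize_sleep(tr, window = "starved", min_bout = min_bout))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fed <- out[out$condition == "fed" & out$period == "whole", ]
  stv <- out[out$condition == "starved" & out$period == "whole", ]
  chg <- percent_change_sleep(fed$total_sleep_pct,
                              stv$total_sleep_pct[match(fed$fly_id, stv$fly_id)])
  out$pct_change_sleep <- NA_real_
  out$pct_change_sleep[out$condition == "fed" & out$period == "whole"] <- chg
  out
}

#' Hourly sleep profile by group
#'
#' Mean minutes asleep per Zeitgeber hour with standard error (sample
#' sd / sqrt(n) over flies), per group of flies (population x sex x
#' temperature). For the starvation window, hours are indexed from the
#' start of starvation (hour 0 = first starved hour) when
#' `from_window_start = TRUE`.
#'
#' @param traces list of activity traces (each carrying its factors).
#' @param window `"fed"` or `"starved"`.
#' @param min_bout minimum sleep bout length, minutes.
#' @param from_window_start index hours from the window start rather
#'   than by Zeitgeber hour (the usual presentation for starvation data).
#' @return data frame: `population`, `sex`, `temperature`, `hour`,
#'   `mean_asleep_min`, `se`, `n_flies`.
#' @export
hourly_profile <- function(traces, window = c("fed", "starved"), min_bout = 5,
                           from_window_start = (window == "starved")) {
  window <- match.arg(window)
  per_fly <- lapply(traces, function(tr) {
    bouts <- score_sleep(tr, window, min_bout)
    w <- tr[window_select(tr, window), , drop = FALSE]
    asleep <- asleep_indicator(bouts, nrow(w))
    hr <- if (from_window_start) (seq_len(nrow(w)) - 1L) %/% 60L
          else floor(w$zt)
    mins <- tapply(as.numeric(asleep), hr, sum) /
      (tapply(asleep, hr, length) / 60)  # minutes asleep per full hour
    meta <- trace_meta(tr)
    data.frame(population = meta$population %||% NA, sex = meta$sex %||% NA,
               temperature = meta$temperature %||% NA,
               hour = as.numeric(names(mins)), asleep_min = as.numeric(mins))
  })
  long <- do.call(rbind, per_fly)
  key <- interaction(long$population, long$sex, long$temperature, drop = TRUE)
  for (g in levels(key)) {
    nf <- length(per_fly[vapply(per_fly, function(d)
      as.character(interaction(d$population[1], d$sex[1], d$temperature[1])) == g,
      logical(1))])
    if (nf < 2) stop("hourly_profile: group ", g, " has fewer than 2 flies")
  }
  agg <- aggregate(asleep_min ~ population + sex + temperature + hour,
                   data = long, FUN = function(v)
                     c(mean = mean(v), se = sd(v) / sqrt(length(v)),
                       n = length(v)))
  out <- cbind(agg[c("population", "sex", "temperature", "hour")],
               mean_asleep_min = agg$asleep_min[, "mean"],
               se = agg$asleep_min[, "se"], n_flies = agg$asleep_min[, "n"])
  out[order(out$population, out$sex, out$temperature, out$hour), ]
}

#' Aggregate per-fly sleep phenotypes to line or population means
#'
#' @param summaries output of [sleep_phenotypes()].
#' @param by grouping columns; line level by default.
#' @return data frame of group means and standard errors per condition
#'   and period for every phenotype, shaped like a summary table
#'   (mean and SE columns per variable, plus `n_flies`).
#' @export
aggregate_sleep <- function(summaries,
                            by = c("line", "population", "sex", "temperature")) {
  vars <- c("total_sleep_pct", "mean_bout_length", "bout_number",
            "mean_awake_movement", "pct_change_sleep")
  grp <- c(by, "condition", "period")
  se <- function(v) { v <- v[!is.na(v)]; if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_ }
  f <- summaries[c(grp, vars)]
  key <- do.call(paste, c(f[grp], sep = "\r"))
  rows <- lapply(split(f, key), function(d) {
    out <- d[1, grp, drop = FALSE]
    for (v in vars) {
      out[[paste0(v, "_mean")]] <- mean(d[[v]], na.rm = TRUE)
      out[[paste0(v, "_se")]] <- se(d[[v]])
    }
    out$n_flies <- nrow(d)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[grp]), ]
}
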