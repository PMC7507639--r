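#' LD50 starvation resistance for one vial
#'
#' Starvation resistance is the time at which half the flies in a vial
#' have died. The survival census (survivor counts at increasing elapsed
#' hours) is linearly interpolated between consecutive censuses and the
#' earliest time at which it reaches `initial_count / 2` is returned.
#' With `method = "step"` the estimate is instead the earliest census
#' time at which survivors are at or below half. Vials whose survivors
#' never fall to half are censored at the last census and flagged.
#'
#' @param census data frame with columns `elapsed_hours` and `survivors`
#'   (ordered, first row at 0 h with the full initial count).
#' @param method `"linear"` (interpolated, default) or `"step"`.
#' @param vial_id identifier used in messages and output.
#' @return one-row data frame: `vial_id`, `ld50_hours`, `censored`,
#'   `method`.
#' @export
#' @examples
#' vial_ld50(data.frame(elapsed_hours = c(0, 12), survivors = c(10, 0)))
vial_ld50 <- function(census, method = c("linear", "step"), vial_id = "vial") {
  method <- match.arg(method)
  t <- census$elapsed_hours
  s <- census$survivors
  if (length(t) < 2) stop("vial ", vial_id, ": need at least two censuses")
  if (is.unsorted(t, strictly = TRUE))
    stop("vial ", vial_id, ": census times must be strictly increasing")
  if (t[1] != 0) stop("vial ", vial_id, ": first census must be at 0 h")
  if (any(diff(s) > 0))
    stop("vial ", vial_id, ": survivor count increases over time")
  initial <- s[1]
  half <- initial / 2
  if (min(s) > half) {
    return(data.frame(vial_id = vial_id, ld50_hours = t[length(t)],
                      censored = TRUE, method = method))
  }
  i <- which(s <= half)[1]
  ld50 <- if (s[i] == half || method == "step" || i == 1) {
    t[i]
  } else {
    # earliest crossing of the piecewise-linear survival curve
    t[i - 1] + (s[i - 1] - half) / (s[i - 1] - s[i]) * (t[i] - t[i - 1])
  }
  data.frame(vial_id = vial_id, ld50_hours = ld50, censored = FALSE,
             method = method)
}

#' Vial-level LD50s for a census table
#'
#' @param censuses long data frame: `vial_id`, `elapsed_hours`,
#'   `survivors`, plus any factor columns (`line`, `population`, `sex`,
#'   `temperature`), constant within vial, which are carried through.
#' @param method passed to [vial_ld50()].
#' @return data frame with one row per vial.
#' @export
ld50_table <- function(censuses, method = c("linear", "step")) {
  method <- match.arg(method)
  factor_cols <- intersect(c("line", "population", "sex", "temperature"),
                           names(censuses))
  rows <- lapply(split(censuses, censuses$vial_id), function(d) {
    d <- d[order(d$elapsed_hours), ]
    est <- vial_ld50(d, method, vial_id = as.character(d$vial_id[1]))
    cbind(est, d[1, factor_cols, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Line-level LD50 summary
#'
#' Aggregates vial LD50s to mean and median per line (by default per
#' line x population x sex x temperature). Censored vials are excluded
#' from the statistics and their count reported; downstream models
#' consume the mean. Groups with fewer than 2 uncensored vials are
#' flagged and returned with `NA` statistics so they can be excluded
#' from models.
#'
#' @param vials output of [ld50_table()].
#' @param by grouping columns.
#' @return data frame: group columns, `mean_ld50`, `median_ld50`, `se`,
#'   `n_vials`, `n_censored`, `flagged`.
#' @export
line_ld50 <- function(vials, by = c("line", "population", "sex", "temperature")) {
  by <- intersect(by, names(vials))
  key <- do.call(paste, c(vials[by], sep = "\r"))
  rows <- lapply(split(vials, key), function(d) {
    ok <- d$ld50_hours[!d$censored]
    out <- d[1, by, drop = FALSE]
    out$mean_ld50 <- if (length(ok) >= 2) mean(ok) else NA_real_
    out$median_ld50 <- if (length(ok) >= 2) median(ok) else NA_real_
    out$se <- if (length(ok) >= 2) sd(ok) / sqrt(length(ok)) else NA_real_
    out$n_vials <- nrow(d)
    out$n_censored <- sum(d$censored)
    out$flagged <- length(ok) < 2
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_flag <- sum(out$flagged)
  if (n_flag) message(n_flag, " line group(s) with <2 uncensored vials flagged")
  out[do.call(order, out[by]), ]
}

#' Read a survival census CSV
#'
#' @param path CSV with columns vial_id, line, population, sex,
#'   temperature, elapsed_hours, survivors.
#' @return data frame.
#' @export
read_census <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("vial_id", "elapsed_hours", "survivors")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("census missing columns: ", paste(miss, collapse = ", "))
  d
}
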