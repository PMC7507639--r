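# Fixture builders and independent oracles shared across test files.

# minimal annotated trace: zt cycles from zt0, phase follows zt,
# condition/acclimation constant unless vectors are given
make_trace <- function(beam_breaks, condition = "fed", zt0 = 0,
                       acclimation = FALSE, fly_id = "fly1", line = "L01",
                       population = "ME", sex = "F", temperature = 25) {
  n <- length(beam_breaks)
  zt <- ((zt0 * 60 + seq_len(n) - 1) %% 1440) / 60
  structure(
    data.frame(
      datetime = as.POSIXct("2020-06-01 10:00:00", tz = "UTC") +
        60 * (seq_len(n) - 1),
      zt = zt,
      phase = ifelse(zt < 12, "day", "night"),
      condition = rep(condition, length.out = n),
      acclimation = rep(acclimation, length.out = n),
      baseline = rep(condition, length.out = n) == "fed" &
        !rep(acclimation, length.out = n),
      beam_breaks = as.integer(beam_breaks)
    ),
    class = c("activity_trace", "data.frame"),
    fly_id = fly_id, line = line, population = population, sex = sex,
    temperature = temperature, protocol = dam_protocol())
}

# independent oracle: minute-by-minute scan for maximal zero runs >= min_len
brute_zero_runs <- function(x, min_len = 5) {
  starts <- integer(0); lens <- integer(0)
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (x[i] == 0) {
      j <- i
      while (j < n && x[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= min_len) {
        starts <- c(starts, i); lens <- c(lens, j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  list(start = starts, length = lens)
}

# independent oracle: terminal zero-run length by backwards scan
brute_terminal_zero <- function(x) {
  run <- 0
  for (i in rev(seq_along(x))) {
    if (x[i] != 0) break
    run <- run + 1
  }
  run
}

# a readings table in the shape read_dam_file() returns, for write round trips
make_readings <- function(counts, start = as.POSIXct("2020-06-01 10:00:00",
                                                     tz = "UTC")) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 32)
  out <- data.frame(index = seq_len(nrow(counts)),
                    datetime = start + 60 * (seq_len(nrow(counts)) - 1),
                    status = 1L, light = 1L)
  colnames(counts) <- paste0("ch", 1:32)
  cbind(out, as.data.frame(counts))
}

# tiny full-protocol monitor fixture written through the simulator
tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, lines_per_population = 2, flies_per_line = 2,
             sexes = c("F", "M"), temperatures = c(21, 25), ...)
}

# random survival census honoring the invariants (non-increasing, starts full)
random_census <- function(initial = 10, n_census = 6, max_h = 48) {
  times <- sort(c(0, runif(n_census - 1, 1, max_h)))
  deaths <- sample(0:initial, n_census - 1, replace = TRUE)
  surv <- initial - pmin(cumsum(c(0, deaths)), initial)
  data.frame(elapsed_hours = times, survivors = surv)
}
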