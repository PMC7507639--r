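#' Configuration for a synthetic sleep/starvation experiment
#'
#' Defines the full study design and the generative model the simulator
#' draws from: a temperate (ME) and a tropical (PC) population, 10
#' isofemale lines each, both sexes, two rearing temperatures, a
#' 12 h:12 h light cycle with 2 acclimation days, 2 fed baseline days
#' and a 24 h starvation window starting at Zeitgeber hour 3. Sleep is a
#' two-state semi-Markov process per minute (phase-specific
#' wake-to-sleep hazard; bout lengths shifted-geometric with a 5-minute
#' floor; awake minutes emit zero-truncated Poisson beam breaks).
#' Starvation multiplies bout length (down) and waking activity (up),
#' leaving bout initiation unchanged. Line-mean death times under
#' starvation carry population/sex/temperature offsets and can be
#' coupled to line-level starved sleep with correlation `rho` (positive
#' in PC, zero in ME by default). Metabolite plates get multiplicative
#' log-normal plate effects and CantonS/Akhr control wells.
#'
#' Any element can be overridden via `...` (nested lists are replaced
#' wholesale).
#'
#' @param seed master seed; all simulator randomness derives from it.
#' @param ... named overrides of the default configuration elements.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    populations = c("ME", "PC"),
    lines_per_population = 10,
    sexes = c("F", "M"),
    temperatures = c(21, 25),
    flies_per_line = 24,          # per sex per temperature
    protocol = dam_protocol(),
    sleep = list(
      # per-minute wake-to-sleep hazard by phase
      hazard = list(ME = c(day = 0.020, night = 0.035),
                    PC = c(day = 0.020, night = 0.035)),
      # mean sleep bout length (minutes) by phase; PC sleeps in longer
      # night bouts, the main driver of its higher total sleep
      bout_mean = list(ME = c(day = 12, night = 22),
                       PC = c(day = 12, night = 40)),
      # expected beam breaks per awake minute; ME moves more
      activity = c(ME = 2.5, PC = 1.5),
      line_sd = 0.12,             # line-level log-scale sd on bout means
      starved_bout_multiplier = 0.6,
      starved_activity_multiplier = 1.3,
      bout_dist = "geometric",    # or "lognormal"
      bout_sdlog = 0.5            # spread of the log-normal alternative
    ),
    survival = list(
      base_hours = 40,
      population_offset = c(ME = 15, PC = 0),
      sex_offset = c(F = 8, M = 0),
      temperature_offset = c("21" = 6, "25" = 0),
      line_sd = 6, vial_sd = 2, fly_sd = 5,
      vials_per_line = 6, flies_per_vial = 10,
      # line-level correlation between starved sleep and death time
      rho = c(ME = 0, PC = 0.8),
      census_per_day = c("21" = 3, "25" = 6)
    ),
    metabolites = list(
      glucose = c(ME = 0.8, PC = 1.0),    # mg glucose / mg protein
      tga = c(ME = 1.2, PC = 0.9),        # mg TGA / mg protein
      line_sd = 0.10,                     # log-scale line variation
      well_cv = 0.10,                     # log-scale well noise
      plate_effect_sd = 0.15,             # log-scale multiplicative
      protein_mg = 0.5,
      cantons = c(glucose = 0.9, tga = 1.0),
      akhr_tga_factor = 3,
      wells_per_line = 4, control_wells = 4, wells_per_plate = 32,
      invert_rate = 0                     # fraction of QC-violating plates
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% c("sleep", "survival", "metabolites") && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  stopifnot(cfg$lines_per_population >= 1, cfg$flies_per_line >= 1,
            all(unlist(cfg$sleep$hazard) >= 0),
            all(unlist(cfg$sleep$bout_mean) > 0),
            cfg$sleep$starved_bout_multiplier > 0,
            all(abs(cfg$survival$rho) <= 1))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic experiment: %d populations x %d lines x %d sexes x %d temperatures, %d flies/line, seed %d\n",
    length(x$populations), x$lines_per_population, length(x$sexes),
    length(x$temperatures), x$flies_per_line, x$seed))
  invisible(x)
}

line_labels <- function(cfg) {
  unlist(lapply(cfg$populations, function(p)
    sprintf("%s_L%02d", p, seq_len(cfg$lines_per_population))))
}

# zero-truncated Poisson via inverse cdf; lambda vectorized
rztpois <- function(n, lambda) {
  qpois(runif(n, dpois(0, lambda), 1), lambda)
}

# sleep-bout length with a 5-minute floor and the configured mean:
# shifted geometric (memoryless, default) or shifted log-normal
draw_bout_length <- function(m, dist = "geometric", sdlog = 0.5) {
  if (m <= 5) return(5L)
  if (dist == "lognormal") {
    5L + as.integer(round(rlnorm(1, log(m - 5) - sdlog^2 / 2, sdlog)))
  } else {
    5L + rgeom(1, 1 / (m - 4))
  }
}

# one fly's minute-resolved wake/sleep chain and beam-break counts
simulate_fly_minutes <- function(n_min, is_day, is_starved, hazard,
                                 bout_mean, lambda, sbm, sam,
                                 bout_dist = "geometric", bout_sdlog = 0.5) {
  seg <- cumsum(c(TRUE, diff(is_day) != 0 | diff(is_starved) != 0))
  seg_end <- cumsum(tabulate(seg))         # last minute index of each segment
  asleep <- logical(n_min)
  t <- 1L
  while (t <= n_min) {
    h <- if (is_day[t]) hazard["day"] else hazard["night"]
    e <- seg_end[seg[t]]
    if (h <= 0) { t <- e + 1L; next }      # stays awake this whole segment
    w <- rgeom(1, min(h, 1)) + 1L          # wake minutes before sleep onset
    if (t + w - 1L >= e) { t <- e + 1L; next }  # redrawn next segment
    s <- t + w                             # first sleep minute
    m <- (if (is_day[s]) bout_mean["day"] else bout_mean["night"]) *
      (if (is_starved[s]) sbm else 1)
    len <- draw_bout_length(m, bout_dist, bout_sdlog)
    asleep[s:min(s + len - 1L, n_min)] <- TRUE
    t <- s + len
  }
  counts <- integer(n_min)
  awake <- !asleep
  lam <- lambda * ifelse(is_starved[awake], sam, 1)
  counts[awake] <- as.integer(rztpois(sum(awake), lam))
  list(asleep = asleep, counts = counts)
}

# window bookkeeping applying the scoring definition (>= 5-min zero runs,
# clipped to the window) to the simulator's own asleep indicator
ledger_window_stats <- function(asleep, counts, sel, is_day) {
  a <- asleep[sel]; cts <- counts[sel]; day <- is_day[sel]
  runs <- zero_runs(as.integer(!a), 5)
  scored <- logical(length(a))
  for (i in seq_along(runs$start)) {
    scored[runs$start[i]:(runs$start[i] + runs$length[i] - 1L)] <- TRUE
  }
  awake <- !scored
  list(sleep_min = sum(scored),
       day_sleep_min = sum(scored & day),
       night_sleep_min = sum(scored & !day),
       bout_number = length(runs$start),
       mean_bout_length = if (length(runs$start)) mean(runs$length) else NA_real_,
       total_sleep_pct = 100 * sum(scored) / length(a),
       mean_awake_movement = if (any(awake)) sum(cts[awake]) / sum(awake)
                             else NA_real_)
}

#' Simulate activity-monitor files
#'
#' Generates the full factorial design of flies, simulates each fly's
#' minute-resolved sleep/wake chain and beam-break counts under the
#' configured protocol, and writes standard DAM monitor files (32
#' channels each) plus a channel metadata CSV. A ground-truth ledger
#' records line-level parameters and per-fly realized phenotypes
#' computed directly from the simulator's own sleep indicator, for
#' exact cross-checks against the analysis pipeline.
#'
#' @param config a [sim_config()].
#' @param out_dir directory for monitor files and `metadata.csv`.
#' @return list of class `sim_activity`: `files`, `metadata_file`,
#'   `metadata`, `ledger` (with `lines`, `flies`, `channel_totals`).
#' @export
simulate_activity <- function(config, out_dir = tempfile("damsim")) {
  set.seed(derive_seed(config$seed, 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- config$protocol
  n_min <- (prot$acclimation_days + prot$baseline_days) * 1440 +
    round(prot$starvation_zh * 60) + round(prot$starvation_hours * 60)
  zt_min <- (seq_len(n_min) - 1L) %% 1440L
  is_day <- zt_min < 720L
  s0 <- (prot$acclimation_days + prot$baseline_days) * 1440 +
    round(prot$starvation_zh * 60)
  idx0 <- seq_len(n_min) - 1L
  is_starved <- idx0 >= s0 & idx0 < s0 + round(prot$starvation_hours * 60)
  acclim <- idx0 < prot$acclimation_days * 1440
  fed_sel <- !acclim & !is_starved &
    idx0 < (prot$acclimation_days + prot$baseline_days) * 1440

  lines <- line_labels(config)
  pop_of <- rep(config$populations, each = config$lines_per_population)
  bout_factor <- setNames(rlnorm(length(lines), 0, config$sleep$line_sd), lines)
  design <- expand.grid(rep = seq_len(config$flies_per_line),
                        temperature = config$temperatures,
                        sex = config$sexes,
                        line = lines, stringsAsFactors = FALSE)
  design$population <- pop_of[match(design$line, lines)]
  design$fly_id <- sprintf("%s_%s_%g_%02d", design$line, design$sex,
                           design$temperature, design$rep)
  n_fly <- nrow(design)
  design$monitor <- sprintf("M%03d", (seq_len(n_fly) - 1L) %/% 32L + 1L)
  design$channel <- (seq_len(n_fly) - 1L) %% 32L + 1L

  start_time <- as.POSIXct(paste("2020-06-01",
                                 paste0(prot$lights_on, ":00")), tz = "UTC")
  fly_rows <- vector("list", n_fly)
  totals <- integer(n_fly)
  files <- character(0)
  monitors <- unique(design$monitor)
  for (mon in monitors) {
    sub <- design[design$monitor == mon, ]
    cts <- matrix(0L, n_min, 32)
    for (j in seq_len(nrow(sub))) {
      pop <- sub$population[j]
      sl <- config$sleep
      sim <- simulate_fly_minutes(
        n_min, is_day, is_starved,
        hazard = sl$hazard[[pop]],
        bout_mean = sl$bout_mean[[pop]] * bout_factor[sub$line[j]],
        lambda = sl$activity[[pop]],
        sbm = sl$starved_bout_multiplier,
        sam = sl$starved_activity_multiplier,
        bout_dist = sl$bout_dist %||% "geometric",
        bout_sdlog = sl$bout_sdlog %||% 0.5)
      cts[, sub$channel[j]] <- sim$counts
      fed <- ledger_window_stats(sim$asleep, sim$counts, fed_sel, is_day)
      stv <- ledger_window_stats(sim$asleep, sim$counts, is_starved, is_day)
      i <- which(design$fly_id == sub$fly_id[j])
      totals[i] <- sum(sim$counts)
      fly_rows[[i]] <- data.frame(
        fly_id = sub$fly_id[j], line = sub$line[j], population = pop,
        sex = sub$sex[j], temperature = sub$temperature[j],
        fed_sleep_min = fed$sleep_min, fed_day_sleep_min = fed$day_sleep_min,
        fed_night_sleep_min = fed$night_sleep_min,
        fed_total_sleep_pct = fed$total_sleep_pct,
        fed_bout_number = fed$bout_number,
        fed_mean_bout_length = fed$mean_bout_length,
        fed_mean_awake_movement = fed$mean_awake_movement,
        starved_sleep_min = stv$sleep_min,
        starved_total_sleep_pct = stv$total_sleep_pct,
        starved_bout_number = stv$bout_number,
        starved_mean_bout_length = stv$mean_bout_length,
        starved_mean_awake_movement = stv$mean_awake_movement)
    }
    readings <- data.frame(index = seq_len(n_min),
                           datetime = start_time + 60 * (seq_len(n_min) - 1L),
                           status = 1L, light = as.integer(is_day))
    colnames(cts) <- paste0("ch", 1:32)
    readings <- cbind(readings, as.data.frame(cts))
    path <- file.path(out_dir, paste0(mon, ".txt"))
    write_dam_file(readings, path)
    files <- c(files, path)
  }
  flies <- do.call(rbind, fly_rows)
  meta <- design[c("monitor", "channel", "fly_id", "line", "population",
                   "sex", "temperature")]
  meta_file <- file.path(out_dir, "metadata.csv")
  write.csv(meta, meta_file, row.names = FALSE)
  ledger <- list(
    lines = data.frame(line = lines, population = pop_of,
                       bout_factor = unname(bout_factor)),
    flies = flies,
    channel_totals = data.frame(monitor = design$monitor,
                                channel = design$channel,
                                fly_id = design$fly_id, total = totals))
  structure(list(files = files, metadata_file = meta_file, metadata = meta,
                 ledger = ledger, n_min = n_min),
            class = "sim_activity")
}

#' Simulate starvation-survival censuses
#'
#' Draws line-mean death times with population, sex and temperature
#' offsets; when the configured line-level correlation `rho` between
#' starved sleep and death time is nonzero, the line death effect is
#' generated jointly with line-level starved sleep (bivariate normal).
#' Individual death times get vial and fly noise, and each vial is
#' censused on the temperature's schedule (3x/day at 21 degC, 6x/day at
#' 25 degC). Negative death times are resampled and counted.
#'
#' @param config a [sim_config()].
#' @param line_sleep optional data frame (`line`, `starved_sleep`) of
#'   line-mean starved sleep percentages to couple to (e.g. from the
#'   activity ledger); when absent, latent line sleep scores are drawn
#'   jointly and reported in the ledger.
#' @return list of class `sim_survival`: `censuses` (long census data
#'   frame), `ledger` (`lines` with true effects, `deaths` with realized
#'   per-fly death hours, `n_resampled`).
#' @export
simulate_survival <- function(config, line_sleep = NULL) {
  set.seed(derive_seed(config$seed, 2))
  sv <- config$survival
  lines <- line_labels(config)
  pop_of <- rep(config$populations, each = config$lines_per_population)
  rho <- sv$rho[pop_of]

  if (is.null(line_sleep)) {
    z_sleep <- rnorm(length(lines))
  } else {
    s <- line_sleep$starved_sleep[match(lines, line_sleep$line)]
    if (anyNA(s)) stop("simulate_survival: line_sleep missing lines")
    z_sleep <- numeric(length(lines))
    for (p in config$populations) {
      sel <- pop_of == p
      sdv <- sd(s[sel])
      z_sleep[sel] <- if (is.na(sdv) || sdv == 0) 0 else
        (s[sel] - mean(s[sel])) / sdv
    }
  }
  z_ind <- rnorm(length(lines))
  line_effect <- sv$line_sd * (rho * z_sleep + sqrt(1 - rho^2) * z_ind)

  census_rows <- list(); death_rows <- list()
  n_resampled <- 0L
  for (li in seq_along(lines)) {
    for (sex in config$sexes) {
      for (temp in config$temperatures) {
        mu <- sv$base_hours + sv$population_offset[[pop_of[li]]] +
          sv$sex_offset[[sex]] + sv$temperature_offset[[as.character(temp)]] +
          line_effect[li]
        per_day <- sv$census_per_day[[as.character(temp)]]
        interval <- 24 / per_day
        for (v in seq_len(sv$vials_per_line)) {
          vial_id <- sprintf("%s_%s_%g_v%d", lines[li], sex, temp, v)
          vmu <- mu + rnorm(1, 0, sv$vial_sd)
          d <- rnorm(sv$flies_per_vial, vmu, sv$fly_sd)
          while (any(d <= 0)) {
            n_resampled <- n_resampled + sum(d <= 0)
            d[d <= 0] <- rnorm(sum(d <= 0), vmu, sv$fly_sd)
          }
          times <- seq(0, ceiling(max(d) / interval) * interval, by = interval)
          census_rows[[vial_id]] <- data.frame(
            vial_id = vial_id, line = lines[li], population = pop_of[li],
            sex = sex, temperature = temp, elapsed_hours = times,
            survivors = vapply(times, function(t) sum(d > t), integer(1)))
          death_rows[[vial_id]] <- data.frame(
            vial_id = vial_id, line = lines[li], death_hours = d)
        }
      }
    }
  }
  censuses <- do.call(rbind, census_rows)
  rownames(censuses) <- NULL
  ledger <- list(
    lines = data.frame(line = lines, population = pop_of,
                       line_effect = line_effect, z_sleep = z_sleep,
                       rho = unname(rho)),
    deaths = do.call(rbind, death_rows),
    n_resampled = n_resampled)
  if (n_resampled) message("simulate_survival: resampled ", n_resampled,
                           " negative death time(s)")
  structure(list(censuses = censuses, ledger = ledger),
            class = "sim_survival")
}

#' Simulate metabolic assay plates
#'
#' Generates per-line glucose and TGA wells with multiplicative
#' log-normal plate effects, CantonS and Akhr control wells on every
#' plate (Akhr TGA elevated threefold, glucose matching CantonS), and
#' optionally injects QC-violating plates in which the Akhr TGA
#' elevation is inverted.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_plates`: `plates` (long well table),
#'   `ledger` (`lines` true ratios, `plate_factors`, `inverted`).
#' @export
simulate_plates <- function(config) {
  set.seed(derive_seed(config$seed, 3))
  mb <- config$metabolites
  lines <- line_labels(config)
  pop_of <- rep(config$populations, each = config$lines_per_population)
  true_glu <- mb$glucose[pop_of] * rlnorm(length(lines), 0, mb$line_sd)
  true_tga <- mb$tga[pop_of] * rlnorm(length(lines), 0, mb$line_sd)

  grid <- expand.grid(rep = seq_len(mb$wells_per_line),
                      analyte = c("glucose", "TGA"),
                      temperature = config$temperatures,
                      sex = config$sexes,
                      line = lines, stringsAsFactors = FALSE)
  grid$population <- pop_of[match(grid$line, lines)]
  grid$plate_id <- sprintf("P%03d", (seq_len(nrow(grid)) - 1L) %/%
                             mb$wells_per_plate + 1L)
  plates_ids <- unique(grid$plate_id)
  g <- setNames(rlnorm(length(plates_ids), 0, mb$plate_effect_sd), plates_ids)
  inverted <- setNames(runif(length(plates_ids)) < mb$invert_rate, plates_ids)

  well <- function(plate, genotype, analyte, ratio, sex = NA, temp = NA,
                   line = NA, population = NA) {
    protein <- rlnorm(length(ratio), log(mb$protein_mg), 0.05)
    data.frame(plate_id = plate, well = NA_character_, genotype = genotype,
               line = line, population = population, sex = sex,
               temperature = temp, analyte = analyte,
               analyte_mg = ratio * protein * g[plate] *
                 rlnorm(length(ratio), 0, mb$well_cv),
               protein_mg = protein)
  }
  i <- match(grid$line, lines)
  exp_wells <- well(grid$plate_id, grid$line, grid$analyte,
                    ifelse(grid$analyte == "glucose", true_glu[i], true_tga[i]),
                    grid$sex, grid$temperature, grid$line, grid$population)
  ctl <- lapply(plates_ids, function(p) {
    k <- mb$control_wells
    tga_factor <- if (inverted[p]) 1 / mb$akhr_tga_factor else
      mb$akhr_tga_factor
    rbind(
      well(rep(p, k), "CantonS", "glucose", rep(mb$cantons[["glucose"]], k)),
      well(rep(p, k), "CantonS", "TGA", rep(mb$cantons[["tga"]], k)),
      well(rep(p, k), "Akhr", "glucose", rep(mb$cantons[["glucose"]], k)),
      well(rep(p, k), "Akhr", "TGA",
           rep(mb$cantons[["tga"]] * tga_factor, k)))
  })
  plates <- rbind(exp_wells, do.call(rbind, ctl))
  plates$well <- sprintf("W%04d", seq_len(nrow(plates)))
  rownames(plates) <- NULL
  ledger <- list(
    lines = data.frame(line = lines, population = pop_of,
                       glucose_per_protein = true_glu,
                       tga_per_protein = true_tga),
    plate_factors = data.frame(plate_id = plates_ids, factor = unname(g)),
    inverted = names(inverted)[inverted])
  structure(list(plates = plates, ledger = ledger), class = "sim_plates")
}

#' Simulate a complete experiment
#'
#' Runs [simulate_activity()], couples [simulate_survival()] to the
#' realized line-mean starved sleep from the activity ledger, and
#' [simulate_plates()]; writes monitor files, `metadata.csv`,
#' `censuses.csv` and `plates.csv` under `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return list of class `sim_experiment` with the three component
#'   results and file paths.
#' @export
simulate_experiment <- function(config, out_dir = tempfile("simexp")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  act <- simulate_activity(config, out_dir)
  line_sleep <- aggregate(starved_total_sleep_pct ~ line, act$ledger$flies,
                          mean)
  names(line_sleep)[2] <- "starved_sleep"
  surv <- simulate_survival(config, line_sleep)
  census_file <- file.path(out_dir, "censuses.csv")
  write.csv(surv$censuses, census_file, row.names = FALSE)
  plates <- simulate_plates(config)
  plates_file <- file.path(out_dir, "plates.csv")
  write.csv(plates$plates, plates_file, row.names = FALSE)
  structure(list(activity = act, survival = surv, plates = plates,
                 census_file = census_file, plates_file = plates_file,
                 out_dir = out_dir, config = config),
            class = "sim_experiment")
}

#' Simulate a line-mean phenotype table from known coefficients
#'
#' Draws a full line x sex x temperature design (the shape consumed by
#' [fit_ld50_model()]) with continuous predictors at realistic scales
#' and the response generated from stated coefficients plus Gaussian
#' noise — the ground truth for coefficient-recovery and
#' Bayesian-calibration checks.
#'
#' @param n_lines total lines (half per population).
#' @param coefs named coefficient vector on the model-matrix scale
#'   (missing terms default to 0); names as in the fitted models, e.g.
#'   `"(Intercept)"`, `"sexM"`, `"temperature25"`, `"populationPC"`,
#'   `"pct_change_sleep"`.
#' @param sigma residual standard deviation.
#' @param flavor which predictor set to generate.
#' @param seed RNG seed.
#' @return data frame with attribute `truth` (the full coefficient
#'   vector used).
#' @export
simulate_phenotype_table <- function(n_lines = 20, coefs = NULL, sigma = 5,
                                     flavor = c("behavior", "metabolism"),
                                     seed = 1) {
  flavor <- match.arg(flavor)
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  pop <- rep(c("ME", "PC"), each = ceiling(n_lines / 2))[seq_len(n_lines)]
  d <- expand.grid(line = lines, sex = c("F", "M"),
                   temperature = c(21, 25), stringsAsFactors = FALSE)
  d$population <- pop[match(d$line, lines)]
  if (flavor == "metabolism") {
    d$glucose_per_protein <- rnorm(nrow(d), 1, 0.2)
    d$tga_per_protein <- rnorm(nrow(d), 1, 0.25)
  } else {
    d$pct_change_sleep <- rnorm(nrow(d), -20, 10)
    d$starved_mean_movement <- rnorm(nrow(d), 2, 0.5)
    d$total_sleep_starved <- rnorm(nrow(d), 30, 8)
  }
  prep <- prep_model_data(cbind(d, mean_ld50 = 0), flavor, "mean_ld50")
  X <- model.matrix(stats::delete.response(terms(prep$formula)), prep$data)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta["(Intercept)"] <- 50
  if (!is.null(coefs)) beta[names(coefs)] <- coefs
  d$mean_ld50 <- drop(X %*% beta) + rnorm(nrow(d), 0, sigma)
  attr(d, "truth") <- beta
  attr(d, "sigma") <- sigma
  d
}
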