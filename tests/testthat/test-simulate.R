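test_that("identical seed and config give byte-identical outputs", {
  cfg <- tiny_config(seed = 101)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a1 <- simulate_activity(cfg, d1)
  a2 <- simulate_activity(cfg, d2)
  for (i in seq_along(a1$files)) {
    expect_identical(readLines(a1$files[i]), readLines(a2$files[i]))
  }
  expect_identical(a1$ledger, a2$ledger)
  s1 <- simulate_survival(cfg); s2 <- simulate_survival(cfg)
  expect_identical(s1$censuses, s2$censuses)
  p1 <- simulate_plates(cfg); p2 <- simulate_plates(cfg)
  expect_identical(p1$plates, p2$plates)
  # a different seed changes the data
  a3 <- simulate_activity(tiny_config(seed = 102), withr::local_tempdir())
  expect_false(identical(readLines(a1$files[1]), readLines(a3$files[1])))
})

test_that("zero sleep hazard yields fully awake flies", {
  cfg <- sim_config(seed = 103, lines_per_population = 1, flies_per_line = 3,
                    sexes = "F", temperatures = 25,
                    sleep = list(hazard = list(
                      ME = c(day = 0, night = 0), PC = c(day = 0, night = 0))))
  act <- simulate_activity(cfg, withr::local_tempdir())
  expect_true(all(act$ledger$flies$fed_total_sleep_pct == 0))
  expect_true(all(act$ledger$flies$starved_total_sleep_pct == 0))
})

test_that("the starvation bout-length multiplier shortens realized bouts", {
  cfg <- sim_config(seed = 107, lines_per_population = 2, flies_per_line = 10,
                    sexes = "F", temperatures = 25,
                    sleep = list(starved_bout_multiplier = 0.5))
  act <- simulate_activity(cfg, withr::local_tempdir())
  fl <- act$ledger$flies
  shorter <- fl$starved_mean_bout_length < fl$fed_mean_bout_length
  expect_gte(mean(shorter, na.rm = TRUE), 0.95)
  # and bout initiation is untouched, so bout number stays comparable:
  # the starved/fed bout-count ratio stays near 1 on average (the shorter
  # bouts slightly increase initiation opportunities)
  ratio <- fl$starved_bout_number / (fl$fed_bout_number / 2)
  expect_lt(abs(mean(ratio) - 1), 0.35)
})

test_that("the log-normal bout alternative keeps the configured mean", {
  cfg <- sim_config(seed = 151, lines_per_population = 1, flies_per_line = 12,
                    sexes = "F", temperatures = 25,
                    sleep = list(bout_dist = "lognormal", line_sd = 0))
  act <- simulate_activity(cfg, withr::local_tempdir())
  fl <- act$ledger$flies
  # whole-day fed bout mean lies between the configured day and night means
  m <- cfg$sleep$bout_mean$ME
  got <- mean(fl$fed_mean_bout_length)
  expect_gt(got, m[["day"]] * 0.7)
  expect_lt(got, m[["night"]] * 1.3)
})

test_that("the configured ME/PC night-sleep contrast is recovered end-to-end", {
  cfg <- sim_config(seed = 109, lines_per_population = 2, flies_per_line = 6,
                    sexes = "F", temperatures = 25)
  act <- simulate_activity(cfg, withr::local_tempdir())
  # parse the emitted files through the analysis path
  r <- lapply(act$files, read_dam_file)
  names(r) <- sub(".txt", "", basename(act$files), fixed = TRUE)
  traces <- lapply(seq_len(nrow(act$metadata)), function(i) {
    m <- act$metadata[i, ]
    annotate_trace(r[[m$monitor]], m$channel, as.list(m), cfg$protocol)
  })
  perfly <- sleep_phenotypes(traces)
  night <- perfly[perfly$condition == "fed" & perfly$period == "night", ]
  me <- mean(night$total_sleep_pct[night$population == "ME"])
  pc <- mean(night$total_sleep_pct[night$population == "PC"])
  expect_gt(pc, me)

  # ledger consistency: the pipeline's per-fly phenotypes equal the
  # generator's own bookkeeping exactly, fly by fly
  whole <- perfly[perfly$condition == "fed" & perfly$period == "whole", ]
  led <- act$ledger$flies[match(whole$fly_id, act$ledger$flies$fly_id), ]
  expect_equal(whole$total_sleep_pct, led$fed_total_sleep_pct)
  expect_equal(whole$bout_number, led$fed_bout_number)
  expect_equal(whole$mean_awake_movement, led$fed_mean_awake_movement)
  stv <- perfly[perfly$condition == "starved" & perfly$period == "whole", ]
  led2 <- act$ledger$flies[match(stv$fly_id, act$ledger$flies$fly_id), ]
  expect_equal(stv$total_sleep_pct, led2$starved_total_sleep_pct)
})

test_that("emitted files cover every cell of the factorial design", {
  cfg <- tiny_config(seed = 113)
  ex <- simulate_experiment(cfg, withr::local_tempdir())
  want <- expand.grid(line = line <- sprintf("%s_L%02d",
                                             rep(c("ME", "PC"), each = 2),
                                             rep(1:2, 2)),
                      sex = c("F", "M"), temperature = c(21, 25),
                      stringsAsFactors = FALSE)
  meta_cells <- unique(ex$activity$metadata[c("line", "sex", "temperature")])
  expect_equal(nrow(merge(want, meta_cells)), nrow(want))
  cen_cells <- unique(ex$survival$censuses[c("line", "sex", "temperature")])
  expect_equal(nrow(merge(want, cen_cells)), nrow(want))
  plate_cells <- unique(ex$plates$plates[
    !is.na(ex$plates$plates$line), c("line", "sex", "temperature")])
  expect_equal(nrow(merge(want, plate_cells)), nrow(want))
})

test_that("survival censuses honor their invariants and schedules", {
  cfg <- tiny_config(seed = 127)
  sv <- simulate_survival(cfg)
  for (d in split(sv$censuses, sv$censuses$vial_id)) {
    expect_equal(d$survivors[1], cfg$survival$flies_per_vial)
    expect_equal(d$elapsed_hours[1], 0)
    expect_true(all(diff(d$survivors) <= 0))
    interval <- unique(diff(d$elapsed_hours))
    expect_length(interval, 1)
    expect_equal(interval,
                 24 / cfg$survival$census_per_day[[as.character(d$temperature[1])]])
  }
})

test_that("a configured population offset is recovered from the censuses", {
  cfg <- sim_config(seed = 131, lines_per_population = 10, flies_per_line = 1,
                    sexes = "F", temperatures = 25)
  sv <- simulate_survival(cfg)
  ll <- line_ld50(ld50_table(sv$censuses))
  me <- ll$mean_ld50[ll$population == "ME"]
  pc <- ll$mean_ld50[ll$population == "PC"]
  gap <- mean(me) - mean(pc)
  se <- sqrt(var(me) / length(me) + var(pc) / length(pc))
  expect_lt(abs(gap - cfg$survival$population_offset[["ME"]]), 3 * se + 1)
})

test_that("uncoupled populations show no sleep-survival correlation", {
  cors <- vapply(1:30, function(i) {
    cfg <- sim_config(seed = 200 + i, lines_per_population = 10,
                      sexes = "F", temperatures = 25,
                      survival = list(rho = c(ME = 0, PC = 0)))
    sv <- simulate_survival(cfg)
    led <- sv$ledger$lines
    cor(led$z_sleep, led$line_effect)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("plate simulation responds to its knobs", {
  cfg0 <- tiny_config(seed = 137,
                      metabolites = list(plate_effect_sd = 0, well_cv = 0.05))
  q0 <- plate_qc(simulate_plates(cfg0)$plates)
  expect_true(all(q0$verdict == "PASS"))
  cfg1 <- tiny_config(seed = 139, metabolites = list(invert_rate = 1))
  sim1 <- simulate_plates(cfg1)
  q1 <- plate_qc(sim1$plates)
  expect_true(all(q1$verdict == "FAIL"))
  expect_equal(sort(sim1$ledger$inverted), sort(q1$plate_id))
  # configured ME > PC TGA contrast comes through the summaries
  cfg2 <- tiny_config(seed = 149)
  mets <- summarize_metabolites(simulate_plates(cfg2)$plates)
  expect_gt(mean(mets$tga_per_protein[mets$population == "ME"]),
            mean(mets$tga_per_protein[mets$population == "PC"]))
})
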