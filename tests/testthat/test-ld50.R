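test_that("interpolated LD50 matches hand-computed crossings", {
  # all 10 die linearly over 12 h: half-death at the midpoint
  expect_equal(vial_ld50(data.frame(elapsed_hours = c(0, 12),
                                    survivors = c(10, 0)))$ld50_hours, 6)
  # crossing inside the 8-16 h interval: 8 + (10-5)/(10-4) * 8
  est <- vial_ld50(data.frame(elapsed_hours = c(0, 8, 16, 24),
                              survivors = c(10, 10, 4, 0)))
  expect_equal(est$ld50_hours, 8 + 5 / 6 * 8)
  expect_false(est$censored)
  # exact tie at a census time returns that census time
  expect_equal(vial_ld50(data.frame(elapsed_hours = c(0, 10, 20),
                                    survivors = c(10, 5, 0)))$ld50_hours, 10)
  # never crossing half: censored at the last census, flagged
  cens <- vial_ld50(data.frame(elapsed_hours = c(0, 24),
                               survivors = c(10, 6)))
  expect_true(cens$censored)
  expect_equal(cens$ld50_hours, 24)
  # the step-function alternative takes the earliest census at/below half
  expect_equal(vial_ld50(data.frame(elapsed_hours = c(0, 8, 16, 24),
                                    survivors = c(10, 10, 4, 0)),
                         method = "step")$ld50_hours, 16)
})

test_that("invalid censuses are rejected naming the vial", {
  expect_error(vial_ld50(data.frame(elapsed_hours = c(0, 8, 16),
                                    survivors = c(10, 4, 6)), vial_id = "v9"),
               "v9.*increases")
  expect_error(vial_ld50(data.frame(elapsed_hours = c(2, 8),
                                    survivors = c(10, 0))), "first census")
})

test_that("line summaries report both mean and median over vials", {
  vials <- data.frame(vial_id = paste0("v", 1:6),
                      ld50_hours = c(10, 12, 14, 16, 18, 20),
                      censored = FALSE, method = "linear", line = "L1")
  out <- line_ld50(vials, by = "line")
  expect_equal(out$mean_ld50, 15)
  expect_equal(out$median_ld50, 15)
  vials$ld50_hours <- c(10, 10, 10, 10, 10, 40)
  out2 <- line_ld50(vials, by = "line")
  expect_equal(out2$mean_ld50, 15)
  expect_equal(out2$median_ld50, 10)
  # all censored: flagged with NA statistics
  vials$censored <- TRUE
  expect_message(out3 <- line_ld50(vials, by = "line"), "flagged")
  expect_true(out3$flagged)
  expect_true(is.na(out3$mean_ld50))
})

test_that("LD50 is bounded by the censuses and monotone under delay", {
  set.seed(23)
  for (i in 1:200) {
    cen <- random_census()
    est <- vial_ld50(cen)
    expect_gte(est$ld50_hours, min(cen$elapsed_hours))
    expect_lte(est$ld50_hours, max(cen$elapsed_hours))
    if (!est$censored) {
      # delaying every death (shifting all post-baseline censuses later)
      # strictly increases the estimate
      shifted <- cen
      shifted$elapsed_hours[-1] <- shifted$elapsed_hours[-1] + 5
      est2 <- vial_ld50(shifted)
      expect_gt(est2$ld50_hours, est$ld50_hours)
    }
  }
})

test_that("census-schedule discretization error is below one interval", {
  set.seed(29)
  for (temp_interval in c(8, 4)) {  # 3x/day and 6x/day schedules
    for (i in 1:100) {
      deaths <- sort(rnorm(10, 50, 8))
      true_half <- deaths[5]  # survivors first reach 5 at the 5th death
      times <- seq(0, ceiling(max(deaths) / temp_interval) * temp_interval,
                   by = temp_interval)
      cen <- data.frame(
        elapsed_hours = times,
        survivors = vapply(times, function(t) sum(deaths > t), integer(1)))
      est <- vial_ld50(cen)
      expect_lt(abs(est$ld50_hours - true_half), temp_interval)
    }
  }
})

test_that("line mean and median LD50 nearly coincide for normal death times", {
  set.seed(31)
  stats <- t(vapply(1:20, function(l) {
    vial_means <- vapply(1:6, function(v) {
      deaths <- rnorm(10, 40 + l, 5)
      times <- seq(0, ceiling(max(deaths) / 4) * 4, by = 4)
      vial_ld50(data.frame(
        elapsed_hours = times,
        survivors = vapply(times, function(t) sum(deaths > t), integer(1))
      ))$ld50_hours
    }, numeric(1))
    c(mean(vial_means), median(vial_means))
  }, numeric(2)))
  expect_gt(cor(stats[, 1], stats[, 2])^2, 0.9)
})

test_that("ld50_table carries factors and read_census validates columns", {
  cen <- rbind(
    data.frame(vial_id = "v1", line = "L1", population = "ME", sex = "F",
               temperature = 25, elapsed_hours = c(0, 12),
               survivors = c(10, 0)),
    data.frame(vial_id = "v2", line = "L1", population = "ME", sex = "F",
               temperature = 25, elapsed_hours = c(0, 24),
               survivors = c(10, 2)))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(cen, f, row.names = FALSE)
  tab <- ld50_table(read_census(f))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$population, c("ME", "ME"))
  expect_equal(tab$ld50_hours[tab$vial_id == "v1"], 6)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_census(bad), "missing columns")
})
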