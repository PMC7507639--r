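test_that("pairwise tests apply the Bonferroni family rule", {
  set.seed(41)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 10), y = rnorm(30))
  d$y[d$g == "a"] <- d$y[d$g == "a"] + 0.001  # essentially identical groups
  tf <- pairwise_tests(d, "y", "g")
  expect_equal(attr(tf, "family_size"), 3)
  expect_equal(attr(tf, "threshold"), 0.05 / 3)
  expect_equal(tf$significant, !is.na(tf$p) & tf$p < 0.05 / 3)
  # identical samples give t = 0
  same <- data.frame(g = rep(c("a", "b"), each = 5), y = rep(1:5, 2))
  tf2 <- pairwise_tests(same, "y", "g")
  expect_equal(tf2$t, 0)
  expect_false(tf2$significant)
  # a family of 20 comparisons turns a raw p of 0.01 non-significant
  expect_lt(0.05 / 20, 0.01)
  # degenerate (constant) groups are skipped, not errors
  const <- data.frame(g = rep(c("a", "b"), each = 5), y = 1)
  expect_message(tf3 <- pairwise_tests(const, "y", "g"), "degenerate")
  expect_true(is.na(tf3$p))
})

test_that("family-wise error is controlled on null data", {
  set.seed(43)
  hits <- vapply(1:300, function(i) {
    d <- data.frame(g = rep(c("a", "b", "c"), each = 8), y = rnorm(24))
    any(pairwise_tests(d, "y", "g")$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.08)  # nominal 0.05 plus Monte-Carlo slack
})

test_that("the nested ANOVA carries the design's degrees of freedom", {
  d <- simulate_phenotype_table(20, sigma = 5, seed = 47)
  tab <- anova_ld50(d)$table
  terms <- trimws(rownames(tab))
  expect_equal(tab[terms == "population", "Df"], 1)
  expect_equal(tab[terms == "population:line", "Df"], 18)
  expect_equal(tab[terms == "sex", "Df"], 1)
  # missing design cells are a hard error listing the cells
  expect_error(anova_ld50(d[d$line != "L01" | d$sex != "F", ]),
               "missing design cells")
})

test_that("null responses give F statistics with mean near 1", {
  set.seed(53)
  fs <- vapply(1:150, function(i) {
    d <- simulate_phenotype_table(10, coefs = NULL, sigma = 5, seed = 1000 + i)
    d$mean_ld50 <- rnorm(nrow(d), 50, 5)  # response independent of design
    tab <- anova_ld50(d)$table
    tab[3, "F value"]  # population term
  }, numeric(1))
  expect_lt(abs(mean(fs) - 1), 0.35)
})

test_that("MANOVA detects injected effects and rejects singular responses", {
  set.seed(59)
  n <- 240
  d <- data.frame(
    population = rep(c("ME", "PC"), each = n / 2),
    line = rep(sprintf("L%02d", 1:8), each = n / 8),
    sex = rep(c("F", "M"), times = n / 2),
    temperature = rep(c(21, 25), times = n / 2),
    total_sleep_pct = rnorm(n, 40, 5),
    mean_bout_length = rnorm(n, 20, 4),
    bout_number = rnorm(n, 25, 5),
    mean_awake_movement = rnorm(n, 2, 0.3))
  # population effect on total sleep only
  d$total_sleep_pct <- d$total_sleep_pct + 8 * (d$population == "PC")
  fit <- manova_sleep(d)
  ptab <- as.data.frame(fit$pillai)
  expect_lt(ptab["population", "Pr(>F)"], 0.001)
  uni_p <- vapply(fit$univariate, function(tab) {
    tab[trimws(rownames(tab)) == "population", "Pr(>F)"]
  }, numeric(1))
  expect_equal(unname(which.min(uni_p)), 1)  # localizes to total sleep
  # duplicated response column makes the covariance singular
  d$dup <- d$total_sleep_pct
  expect_error(manova_sleep(d, responses = c("total_sleep_pct", "dup")),
               "singular")
})

test_that("null MANOVA p-values are approximately uniform", {
  set.seed(61)
  ps <- vapply(1:150, function(i) {
    n <- 64
    d <- data.frame(
      population = rep(c("ME", "PC"), each = n / 2),
      sex = rep(c("F", "M"), times = n / 2),
      a = rnorm(n), b = rnorm(n))
    fit <- manova_sleep(d, responses = c("a", "b"),
                        terms = c("sex", "population"))
    as.data.frame(fit$pillai)["population", "Pr(>F)"]
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lte(mean(ps < 0.05), 0.11)
})

test_that("per-group regressions recover exact and simulated couplings", {
  d <- data.frame(population = "PC", sex = "F",
                  line = sprintf("L%02d", 1:10),
                  total_sleep_starved = 1:10,
                  mean_ld50 = 2 * (1:10))
  fit <- suppressWarnings(regress_sleep_on_ld50(d, "total_sleep_starved"))
  expect_equal(fit$table$slope, 2)
  expect_equal(fit$table$r_squared, 1)
  expect_equal(nrow(fit$bands), 50)
  expect_true(all(fit$bands$lwr <= fit$bands$fit &
                    fit$bands$fit <= fit$bands$upr))
  # fewer than 3 points: skipped with a message
  expect_message(
    out <- regress_sleep_on_ld50(d[1:2, ], "total_sleep_starved"),
    "skipped")
  expect_null(out$table)
})

test_that("the linear models report the design's F degrees of freedom and
           recover coefficients in the noiseless limit", {
  truth <- c(sexM = -9, temperature25 = -8, populationPC = -4,
             pct_change_sleep = 0.5)
  d <- simulate_phenotype_table(20, coefs = truth, sigma = 1e-9,
                                flavor = "behavior", seed = 67)
  fit <- fit_linear_ld50(d, "behavior")
  expect_equal(unname(fit$df), c(6, 73))
  got <- coef(fit)
  expect_equal(got[names(truth)], truth, tolerance = 1e-6)
  expect_equal(unname(got["(Intercept)"]), 50, tolerance = 1e-6)

  dm <- simulate_phenotype_table(20, flavor = "metabolism", seed = 71)
  expect_equal(unname(fit_linear_ld50(dm, "metabolism")$df), c(5, 74))

  # aliased predictors are a hard error naming the terms
  d2 <- d
  d2$total_sleep_starved <- d2$pct_change_sleep
  expect_error(fit_ld50_model(d2, "behavior", "ols"), "aliased|full rank")
})

test_that("Bayesian fit agrees with OLS under weak priors", {
  d <- simulate_phenotype_table(20, coefs = c(pct_change_sleep = 0.5),
                                sigma = 5, flavor = "behavior", seed = 73)
  ols <- fit_ld50_model(d, "behavior", "ols")
  bay <- fit_ld50_model(d, "behavior", "bayes", seed = 5)
  expect_true(bay$converged)
  expect_true(all(bay$rhat < 1.05))
  sm <- bay$full_summary
  b <- setNames(sm$Estimate, sm$term)[names(coef(ols))]
  mcse <- setNames(sm$MCSE, sm$term)[names(coef(ols))]
  # generous multiple for a quick check; the large-n equivalence is the
  # acceptance-level test
  expect_true(all(abs(b - coef(ols)) < 4 * mcse + 0.02))
  # credible intervals bracket the posterior mean
  expect_true(all(sm$`l-95% CI` <= sm$Estimate & sm$Estimate <= sm$`u-95% CI`))
})

test_that("model methods behave like standard fitted-model objects", {
  d <- simulate_phenotype_table(10, sigma = 3, flavor = "metabolism",
                                seed = 79)
  for (inf in c("ols", "bayes")) {
    fit <- fit_ld50_model(d, "metabolism", inf, iter = 1500, chains = 2,
                          seed = 3)
    expect_s3_class(fit, "ld50_model")
    expect_length(predict(fit), nrow(d))
    expect_length(residuals(fit), nrow(d))
    expect_equal(predict(fit) + residuals(fit), d$mean_ld50,
                 tolerance = 1e-8, ignore_attr = TRUE)
    sims <- simulate(fit, nsim = 3, seed = 1)
    expect_equal(dim(as.data.frame(sims)), c(nrow(d), 3))
    expect_output(print(fit), "Starvation-resistance model")
  }
  bay <- fit_ld50_model(d, "metabolism", "bayes", iter = 600, chains = 2,
                        seed = 4)
  pd <- ppc_data(bay)
  expect_equal(sum(pd$draw == 0), nrow(d))
  expect_true(max(pd$draw) >= 50)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(bay); plot(fit_ld50_model(d, "metabolism", "ols"))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
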