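#' Bonferroni-corrected pairwise Welch t-tests
#'
#' Runs two-tailed Welch t-tests between all pairs of groups (or a
#' stated subset of comparisons) and flags significance under Bonferroni
#' control of the family-wise error rate: a comparison is significant
#' iff its raw p-value is below `alpha / family size`. Comparisons whose
#' groups are degenerate (constant on both sides) cannot be tested and
#' are skipped with a log message; they still count toward the family.
#'
#' @param data data frame.
#' @param value name of the numeric response column.
#' @param group name of the grouping column.
#' @param comparisons optional list of 2-vectors of group levels; all
#'   pairs by default.
#' @param alpha family-wise significance level.
#' @return data frame of class `test_family`: `comparison`, `group1`,
#'   `group2`, `t`, `p`, `significant`; attributes `family_size`,
#'   `alpha`, `threshold`.
#' @export
pairwise_tests <- function(data, value, group, comparisons = NULL,
                           alpha = 0.05) {
  g <- as.character(data[[group]])
  v <- data[[value]]
  lev <- unique(g)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lev, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    x <- v[g == cmp[1]]; y <- v[g == cmp[2]]
    out <- data.frame(comparison = paste(cmp[1], "vs", cmp[2]),
                      group1 = cmp[1], group2 = cmp[2],
                      n1 = length(x), n2 = length(y),
                      t = NA_real_, p = NA_real_, significant = NA)
    if (length(x) < 2 || length(y) < 2) {
      message("pairwise_tests: skipped ", out$comparison, " (n < 2)")
      return(out)
    }
    tt <- tryCatch(t.test(x, y), error = function(e) NULL)
    if (is.null(tt)) {
      message("pairwise_tests: skipped ", out$comparison,
              " (degenerate group variance)")
      return(out)
    }
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
    out
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha / m
  rownames(out) <- NULL
  structure(out, class = c("test_family", "data.frame"),
            family_size = m, alpha = alpha, threshold = alpha / m)
}

#' Nested ANOVA of line-mean starvation resistance
#'
#' Sequential (Type I) ANOVA of LD50 on sex, temperature, population and
#' line nested within population. With 10 lines per population in two
#' populations the nested term carries 18 degrees of freedom and the
#' population term 1, matching the design's structural dfs.
#'
#' @param lines line-level table with columns `sex`, `temperature`,
#'   `population`, `line` and the response.
#' @param response response column name (default `"mean_ld50"`).
#' @param nested include the line-within-population term.
#' @return object of class `ld50_anova`: the `aov` fit plus its table.
#' @export
anova_ld50 <- function(lines, response = "mean_ld50", nested = TRUE) {
  d <- lines
  for (f in c("sex", "temperature", "population", "line")) {
    if (f %in% names(d)) d[[f]] <- factor(d[[f]])
  }
  cells <- with(d, table(sex, temperature, line))
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    labs <- apply(miss, 1, function(i)
      paste(dimnames(cells)$sex[i[1]], dimnames(cells)$temperature[i[2]],
            dimnames(cells)$line[i[3]], sep = "/"))
    stop("anova_ld50: missing design cells: ",
         paste(utils::head(labs, 5), collapse = ", "),
         if (length(labs) > 5) " ..." else "")
  }
  keep <- Filter(function(f) f %in% names(d) && nlevels(d[[f]]) >= 2,
                 c("sex", "temperature", "population"))
  rhs <- paste(c(keep, if (nested && "population" %in% keep)
    "population:line"), collapse = " + ")
  fit <- aov(stats::as.formula(paste(response, "~", rhs)), data = d)
  tab <- summary(fit)[[1]]
  structure(list(fit = fit, table = tab, response = response),
            class = "ld50_anova")
}

#' @export
print.ld50_anova <- function(x, ...) {
  cat("Sequential ANOVA of", x$response, "\n")
  print(x$table)
  invisible(x)
}

#' MANOVA of sleep phenotypes
#'
#' Multivariate analysis of the per-fly sleep/movement phenotypes
#' (total sleep %, mean bout length, bout number, mean waking movement)
#' against experimental factors, reported as Pillai's trace with
#' univariate follow-ups per response. Default design: temperature, sex
#' and line nested within population; an hourly variant uses
#' `terms = c("sex", "population", "hour")` on hourly sleep values.
#'
#' @param data per-fly (or per-hour) data frame.
#' @param responses response column names.
#' @param terms model terms (right-hand side), in order.
#' @return list of class `sleep_manova`: the fit, the Pillai table and
#'   univariate ANOVA follow-ups.
#' @export
manova_sleep <- function(data,
                         responses = c("total_sleep_pct", "mean_bout_length",
                                       "bout_number", "mean_awake_movement"),
                         terms = c("temperature", "sex", "population/line")) {
  d <- data[complete.cases(data[responses]), , drop = FALSE]
  for (f in c("sex", "temperature", "population", "line")) {
    if (f %in% names(d)) d[[f]] <- factor(d[[f]])
  }
  Y <- as.matrix(d[responses])
  if (qr(var(Y))$rank < ncol(Y)) {
    stop("manova_sleep: response covariance is singular ",
         "(collinear or duplicated responses); reduce the response set")
  }
  fml <- stats::as.formula(paste("Y ~", paste(terms, collapse = " + ")))
  fit <- manova(fml, data = d)
  pillai <- summary(fit, test = "Pillai")
  uni <- summary.aov(fit)
  names(uni) <- responses
  structure(list(fit = fit, pillai = pillai$stats, univariate = uni,
                 responses = responses),
            class = "sleep_manova")
}

#' @export
print.sleep_manova <- function(x, ...) {
  cat("MANOVA (Pillai's trace) of:", paste(x$responses, collapse = ", "), "\n")
  print(x$pillai)
  invisible(x)
}

#' Per-population regression of starvation resistance on a sleep trait
#'
#' Ordinary least-squares fit of line-mean LD50 on a line-mean sleep
#' variable (total sleep when starved, or percent change in sleep),
#' separately per group (population x sex by default), with 95%
#' confidence-band data for plotting. Groups with fewer than 3 points
#' are skipped with a message.
#'
#' @param lines line-mean table.
#' @param predictor predictor column name.
#' @param response response column name.
#' @param by grouping columns.
#' @return list of class `ld50_regressions`: `table` (slope, se, R2, p,
#'   n per group) and `bands` (fit and 95% CI over the predictor range).
#' @export
regress_sleep_on_ld50 <- function(lines, predictor,
                                  response = "mean_ld50",
                                  by = c("population", "sex")) {
  by <- intersect(by, names(lines))
  key <- do.call(paste, c(lines[by], sep = "/"))
  tabs <- list(); bands <- list()
  for (k in unique(key)) {
    d <- lines[key == k & complete.cases(lines[c(predictor, response)]), ]
    if (nrow(d) < 3) {
      message("regress_sleep_on_ld50: group ", k, " skipped (<3 points)")
      next
    }
    fit <- lm(stats::reformulate(predictor, response), data = d)
    sm <- summary(fit)
    grid <- data.frame(seq(min(d[[predictor]]), max(d[[predictor]]),
                           length.out = 50))
    names(grid) <- predictor
    ci <- predict(fit, newdata = grid, interval = "confidence")
    tabs[[k]] <- data.frame(
      group = k, predictor = predictor, n = nrow(d),
      slope = unname(coef(fit)[2]), se = sm$coefficients[2, 2],
      r_squared = sm$r.squared, p = sm$coefficients[2, 4])
    bands[[k]] <- data.frame(group = k, grid, fit = ci[, "fit"],
                             lwr = ci[, "lwr"], upr = ci[, "upr"])
  }
  bind <- function(l) if (length(l)) {
    out <- do.call(rbind, l); rownames(out) <- NULL; out
  } else NULL
  structure(list(table = bind(tabs), bands = bind(bands)),
            class = "ld50_regressions")
}

#' @export
print.ld50_regressions <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

# ---- the central starvation-resistance model -------------------------------

flavor_predictors <- function(flavor) {
  switch(flavor,
    metabolism = c("sex", "temperature", "population",
                   "glucose_per_protein", "tga_per_protein"),
    behavior = c("sex", "temperature", "population", "pct_change_sleep",
                 "starved_mean_movement", "total_sleep_starved"),
    stop("unknown flavor: ", flavor))
}

prep_model_data <- function(data, flavor, response, standardize = FALSE) {
  preds <- flavor_predictors(flavor)
  miss <- setdiff(c(response, preds), names(data))
  if (length(miss)) stop("model data missing columns: ",
                         paste(miss, collapse = ", "))
  d <- data[complete.cases(data[c(response, preds)]), , drop = FALSE]
  # treatment coding with reference levels Female, 21 C, ME
  d$sex <- factor(d$sex)
  if ("F" %in% levels(d$sex)) d$sex <- stats::relevel(d$sex, ref = "F")
  d$temperature <- factor(d$temperature)
  d$population <- factor(d$population)
  if ("ME" %in% levels(d$population))
    d$population <- stats::relevel(d$population, ref = "ME")
  cont <- setdiff(preds, c("sex", "temperature", "population"))
  if (standardize) for (v in cont) d[[v]] <- as.numeric(scale(d[[v]]))
  # factors held constant by the design carry no information; drop them
  for (f in c("sex", "temperature", "population")) {
    if (f %in% preds && nlevels(d[[f]]) < 2) {
      message("dropping constant factor '", f, "' from the model")
      preds <- setdiff(preds, f)
    }
  }
  list(data = d,
       formula = stats::reformulate(preds, response),
       predictors = preds)
}

#' Fit the starvation-resistance model
#'
#' The central model of the package: line-mean starvation resistance
#' (LD50, hours) regressed on environmental factors plus either the
#' metabolic traits (glucose and TGA per mg protein; "metabolism"
#' flavor) or the starvation-behavior traits (percent change in sleep,
#' mean waking movement when starved, total sleep when starved;
#' "behavior" flavor). Factors use treatment coding with reference
#' levels Female, 21 degC and the temperate (ME) population, so reported
#' effects are Sex(M), Temperature(25) and Population(PC).
#'
#' Inference is either ordinary least squares (`"ols"`) or Bayesian
#' (`"bayes"`): a Gaussian linear model sampled by MCMC (JAGS) after QR
#' reparameterization of the design matrix, with weakly-informative
#' priors (near-flat normals on the rotated coefficients, half-t(3) on
#' the residual scale), 4 chains, split half warm-up. Convergence is
#' checked by the potential-scale-reduction diagnostic (rHat); if any
#' rHat exceeds 1.05 the coefficient summary is withheld.
#'
#' @param data line-mean phenotype table (one row per line x sex x
#'   temperature).
#' @param flavor `"metabolism"` or `"behavior"`.
#' @param inference `"ols"` or `"bayes"`.
#' @param response response column name.
#' @param standardize center/scale continuous predictors.
#' @param chains,iter,warmup MCMC settings (bayes only); `iter` is the
#'   total per-chain iterations including warm-up.
#' @param seed RNG seed for the sampler (bayes only).
#' @param ppc_draws number of posterior-predictive draws stored for the
#'   density-overlay check.
#' @return an object of class `ld50_model` (subclass `ld50_ols` or
#'   `ld50_bayes`) with `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `simulate` and `plot` methods.
#' @export
fit_ld50_model <- function(data, flavor = c("metabolism", "behavior"),
                           inference = c("ols", "bayes"),
                           response = "mean_ld50", standardize = FALSE,
                           chains = 4, iter = 2000, warmup = floor(iter / 2),
                           seed = 1, ppc_draws = 100) {
  flavor <- match.arg(flavor)
  inference <- match.arg(inference)
  prep <- prep_model_data(data, flavor, response, standardize)
  if (inference == "ols") {
    fit_ols_ld50(prep, flavor, response)
  } else {
    fit_mcmc_ld50(prep, flavor, response, chains, iter, warmup, seed,
                  ppc_draws)
  }
}

#' @rdname fit_ld50_model
#' @export
fit_linear_ld50 <- function(data, flavor = c("metabolism", "behavior"),
                            response = "mean_ld50", standardize = FALSE) {
  fit_ld50_model(data, flavor, inference = "ols", response = response,
                 standardize = standardize)
}

#' @rdname fit_ld50_model
#' @export
fit_bayes_ld50 <- function(data, flavor = c("metabolism", "behavior"),
                           response = "mean_ld50", standardize = FALSE,
                           chains = 4, iter = 2000, warmup = floor(iter / 2),
                           seed = 1, ppc_draws = 100) {
  fit_ld50_model(data, flavor, inference = "bayes", response = response,
                 standardize = standardize, chains = chains, iter = iter,
                 warmup = warmup, seed = seed, ppc_draws = ppc_draws)
}

fit_ols_ld50 <- function(prep, flavor, response) {
  fit <- lm(prep$formula, data = prep$data)
  if (anyNA(coef(fit))) {
    stop("fit_ld50_model: rank-deficient design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      Estimate = sm$coefficients[, 1],
                      Std.Error = sm$coefficients[, 2],
                      t = sm$coefficients[, 3],
                      p = sm$coefficients[, 4], row.names = NULL)
  structure(list(fit = fit, flavor = flavor, inference = "ols",
                 response = response, coefficients = coefs,
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(sm$fstatistic["value"]),
                 df = unname(sm$fstatistic[c("numdf", "dendf")]),
                 n = nrow(prep$data), data = prep$data,
                 formula = prep$formula),
            class = c("ld50_ols", "ld50_model"))
}

jags_lm_string <- "
model {
  for (i in 1:N) { y[i] ~ dnorm(mu[i], tau) }
  mu <- Qs %*% theta
  for (j in 1:P) { theta[j] ~ dnorm(0, prec_theta) }
  tau <- pow(sigma, -2)
  sigma ~ dt(0, prec_sigma, 3) T(0,)
}"

fit_mcmc_ld50 <- function(prep, flavor, response, chains, iter, warmup,
                          seed, ppc_draws) {
  d <- prep$data
  y <- d[[response]]
  X <- model.matrix(stats::as.formula(paste(
    "~", paste(prep$predictors, collapse = " + "))), d)
  if (qr(X)$rank < ncol(X)) stop("fit_ld50_model: design matrix not full rank")
  n <- nrow(X); p <- ncol(X)
  # thin, scaled QR reparameterization: X = Qs Rs with Qs'Qs = (n-1) I
  qx <- qr(X)
  Qs <- qr.Q(qx)[, seq_len(p), drop = FALSE] * sqrt(n - 1)
  Rs <- qr.R(qx)[seq_len(p), seq_len(p), drop = FALSE] / sqrt(n - 1)
  sigma_scale <- max(2.5, mad(y))
  dat <- list(y = y, Qs = Qs, N = n, P = p,
              prec_theta = (1000 * max(sd(y), 1))^-2,
              prec_sigma = sigma_scale^-2)
  inits <- lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, k))
  })
  adapt <- max(100, floor(warmup / 2))
  jm <- rjags::jags.model(textConnection(jags_lm_string), data = dat,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = TRUE)
  update(jm, max(0, warmup - adapt), progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("theta", "sigma"), n.iter = iter - warmup,
                              progress.bar = "none")
  # rotate each chain back to the coefficient scale
  beta_chains <- lapply(samp, function(ch) {
    m <- as.matrix(ch)
    theta <- m[, paste0("theta[", seq_len(p), "]"), drop = FALSE]
    beta <- t(backsolve(Rs, t(theta)))
    colnames(beta) <- colnames(X)
    coda::mcmc(cbind(beta, sigma = m[, "sigma"]),
               start = stats::start(ch), thin = coda::thin(ch))
  })
  ml <- coda::mcmc.list(beta_chains)
  draws <- as.matrix(ml)
  rhat <- coda::gelman.diag(ml, autoburnin = FALSE,
                            multivariate = FALSE)$psrf[, 1]
  ess <- coda::effectiveSize(ml)
  est <- colMeans(draws)
  sds <- apply(draws, 2, sd)
  qs <- t(apply(draws, 2, quantile, c(0.025, 0.975)))
  coefs <- data.frame(term = colnames(draws), Estimate = est,
                      Est.Error = sds, `l-95% CI` = qs[, 1],
                      `u-95% CI` = qs[, 2], Rhat = rhat,
                      ESS = unname(ess), MCSE = sds / sqrt(pmax(ess, 1)),
                      check.names = FALSE, row.names = NULL)
  converged <- all(is.finite(rhat)) && max(rhat) <= 1.05
  if (!converged) {
    warning("fit_ld50_model: convergence failure (max rHat = ",
            round(max(rhat), 3), "); coefficient summary withheld")
  }
  # posterior predictive draws for the density-overlay check
  take <- round(seq(1, nrow(draws), length.out = min(ppc_draws, nrow(draws))))
  beta_d <- draws[take, colnames(X), drop = FALSE]
  sig_d <- draws[take, "sigma"]
  mu_rep <- beta_d %*% t(X)
  set.seed(derive_seed(seed, 999))
  yrep <- mu_rep + matrix(rnorm(length(mu_rep), 0, rep(sig_d, ncol(mu_rep))),
                          nrow = nrow(mu_rep))
  structure(list(flavor = flavor, inference = "bayes", response = response,
                 coefficients = if (converged) coefs else NULL,
                 full_summary = coefs, rhat = rhat, converged = converged,
                 draws = draws, chains = chains, iter = iter, warmup = warmup,
                 X = X, y = y, yrep = yrep, n = n, data = d,
                 formula = prep$formula, seed = seed),
            class = c("ld50_bayes", "ld50_model"))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.ld50_model <- function(x, ...) {
  cat(sprintf("Starvation-resistance model (%s flavor, %s inference), n = %d\n",
              x$flavor, x$inference, x$n))
  if (inherits(x, "ld50_ols")) {
    cat(sprintf("adjusted R-squared %.4f; F = %.2f on %d and %d DF\n",
                x$adj_r_squared, x$f_statistic, x$df[1], x$df[2]))
    print(x$coefficients, row.names = FALSE, digits = 4)
  } else if (is.null(x$coefficients)) {
    cat("NOT CONVERGED (max rHat =", round(max(x$rhat), 3),
        "); summary withheld\n")
  } else {
    print(x$coefficients[c("term", "Estimate", "Est.Error",
                           "l-95% CI", "u-95% CI", "Rhat")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.ld50_model <- function(object, ...) {
  print(object)
  invisible(if (inherits(object, "ld50_bayes")) object$full_summary
            else object$coefficients)
}

#' @export
coef.ld50_model <- function(object, ...) {
  if (inherits(object, "ld50_ols")) return(coef(object$fit))
  est <- object$full_summary$Estimate
  names(est) <- object$full_summary$term
  est[names(est) != "sigma"]
}

#' @export
predict.ld50_model <- function(object, newdata = NULL, ...) {
  if (inherits(object, "ld50_ols")) {
    if (is.null(newdata)) return(predict(object$fit))
    return(predict(object$fit, newdata = newdata))
  }
  X <- if (is.null(newdata)) object$X else
    model.matrix(stats::delete.response(terms(object$formula)), newdata)
  drop(X %*% coef(object))
}

#' @export
residuals.ld50_model <- function(object, ...) {
  if (inherits(object, "ld50_ols")) return(residuals(object$fit))
  object$y - predict(object)
}

#' @export
simulate.ld50_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(object, "ld50_ols")) {
    return(simulate(object$fit, nsim = nsim))
  }
  idx <- sample(nrow(object$draws), nsim, replace = nsim > nrow(object$draws))
  beta <- object$draws[idx, colnames(object$X), drop = FALSE]
  sig <- object$draws[idx, "sigma"]
  mu <- object$X %*% t(beta)
  out <- mu + matrix(rnorm(length(mu), 0, rep(sig, each = nrow(mu))),
                     nrow = nrow(mu))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Posterior-predictive density overlay
#'
#' For a Bayesian fit, plots the kernel density of the observed response
#' (black) over densities of posterior-predictive replicates (grey); a
#' well-fitting model's replicates envelop the observed curve. For an
#' OLS fit, plots observed vs fitted values.
#'
#' @param x an `ld50_model`.
#' @param ... passed to `plot`.
#' @export
plot.ld50_model <- function(x, ...) {
  if (inherits(x, "ld50_bayes")) {
    dens <- density(x$y)
    reps <- apply(x$yrep, 1, function(r) density(r, from = min(dens$x),
                                                 to = max(dens$x)))
    ylim <- range(c(dens$y, vapply(reps, function(d) max(d$y), 0)))
    plot(dens, main = "Posterior predictive check", xlab = x$response,
         ylim = ylim, type = "n", ...)
    for (d in reps) lines(d, col = grey(0.7, alpha = 0.4))
    lines(dens, lwd = 2)
    legend("topright", c("observed", "predicted"), lwd = c(2, 1),
           col = c("black", grey(0.7)), bty = "n")
  } else {
    plot(predict(x), x$y, xlab = "fitted", ylab = "observed",
         main = sprintf("%s model: observed vs fitted", x$flavor), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Posterior-predictive overlay data
#'
#' The observed response vector and stored posterior-predictive
#' replicate matrix in long form, for writing to disk or custom
#' plotting.
#'
#' @param object an `ld50_bayes` fit.
#' @return data frame: `draw` (0 = observed), `row`, `value`.
#' @export
ppc_data <- function(object) {
  stopifnot(inherits(object, "ld50_bayes"))
  obs <- data.frame(draw = 0L, row = seq_along(object$y), value = object$y)
  rep <- data.frame(draw = rep(seq_len(nrow(object$yrep)),
                               each = ncol(object$yrep)),
                    row = rep(seq_len(ncol(object$yrep)),
                              times = nrow(object$yrep)),
                    value = as.vector(t(object$yrep)))
  rbind(obs, rep)
}
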