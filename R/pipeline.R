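#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: obtain inputs (simulate a
#' complete experiment from `config`, or use supplied files), parse and
#' annotate monitor traces, flag dead/escaped flies, score sleep and
#' build per-fly and line-mean phenotypes, estimate vial and line LD50s,
#' normalize and QC metabolic plates, assemble the line phenotype table,
#' and fit the statistical layer (population contrasts, nested ANOVA,
#' per-population sleep-vs-LD50 regressions, linear and Bayesian
#' starvation-resistance models). Report tables are written as CSV under
#' `out_dir` together with the tidy intermediates they are computed
#' from, and a QC log.
#'
#' @param config a [sim_config()]; also supplies the master seed.
#' @param out_dir output directory.
#' @param inputs optional list with `monitor_files`, `metadata_file`,
#'   `census_file`, `plates_file` to analyze real data instead of
#'   simulating.
#' @param min_bout minimum sleep bout length, minutes.
#' @param terminal_quiet_hours dead/escaped-fly QC threshold, hours.
#' @param bayes fit the Bayesian models (slower).
#' @param chains,iter MCMC settings for the Bayesian models.
#' @return (invisibly) a list of class `flysleep_run` with every
#'   intermediate and fitted object, plus `files` naming the written
#'   outputs.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("flysleep"),
                         inputs = NULL, min_bout = 5,
                         terminal_quiet_hours = 12, bayes = TRUE,
                         chains = 4, iter = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  if (is.null(inputs)) {
    sim <- simulate_experiment(config, file.path(out_dir, "inputs"))
    inputs <- list(monitor_files = sim$activity$files,
                   metadata_file = sim$activity$metadata_file,
                   census_file = sim$census_file,
                   plates_file = sim$plates_file)
    note("simulated experiment with seed ", config$seed)
  } else sim <- NULL

  # ---- activity traces and QC ----
  meta <- read_dam_metadata(inputs$metadata_file)
  readings <- lapply(inputs$monitor_files, read_dam_file)
  names(readings) <- sub("[.][^.]*$", "", basename(inputs$monitor_files))
  traces <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    traces[[i]] <- annotate_trace(
      readings[[as.character(meta$monitor[i])]], meta$channel[i],
      metadata = list(fly_id = meta$fly_id[i] %||%
                        paste(meta$monitor[i], meta$channel[i], sep = "_"),
                      line = meta$line[i], population = meta$population[i],
                      sex = meta$sex[i], temperature = meta$temperature[i]),
      protocol = config$protocol)
  }
  qc <- lapply(traces, flag_dead_or_escaped, terminal_quiet_hours)
  flagged <- vapply(qc, `[[`, logical(1), "flagged")
  if (any(flagged)) {
    note(sum(flagged), " fly/flies flagged dead or escaped and excluded ",
         "from sleep summaries: ",
         paste(vapply(qc[flagged], `[[`, character(1), "fly_id"),
               collapse = ", "))
  } else note("fly QC: no dead/escaped flies flagged")

  # ---- sleep phenotypes ----
  perfly <- sleep_phenotypes(traces[!flagged], min_bout = min_bout)
  line_sleep <- aggregate_sleep(perfly)
  pop_sleep <- aggregate_sleep(perfly, by = c("population", "sex",
                                              "temperature"))
  contrasts <- population_contrasts(perfly)

  # ---- starvation resistance ----
  censuses <- read_census(inputs$census_file)
  vials <- ld50_table(censuses)
  lines_ld50 <- line_ld50(vials)
  note(sum(vials$censored), " censored vial(s) of ", nrow(vials))

  # ---- metabolites ----
  plates <- read.csv(inputs$plates_file, stringsAsFactors = FALSE)
  qc_plates <- plate_qc(plates)
  note("plate QC: ", sum(qc_plates$verdict == "PASS"), " pass, ",
       sum(qc_plates$verdict == "FAIL"), " fail, ",
       sum(qc_plates$verdict == "indeterminate"), " indeterminate")
  metabolites <- summarize_metabolites(plates, qc_plates)

  # ---- line phenotype table ----
  pheno <- line_phenotype_table(lines_ld50, perfly, metabolites)

  # ---- statistics ----
  anova_fit <- anova_ld50(pheno)
  reg_sleep <- regress_sleep_on_ld50(pheno, "total_sleep_starved")
  reg_chg <- regress_sleep_on_ld50(pheno, "pct_change_sleep")
  ols_metab <- fit_ld50_model(pheno, "metabolism", "ols")
  ols_behav <- fit_ld50_model(pheno, "behavior", "ols")
  bayes_fits <- NULL
  if (bayes) {
    bayes_fits <- list(
      metabolism = fit_ld50_model(pheno, "metabolism", "bayes",
                                  chains = chains, iter = iter,
                                  seed = derive_seed(config$seed, 11)),
      behavior = fit_ld50_model(pheno, "behavior", "bayes",
                                chains = chains, iter = iter,
                                seed = derive_seed(config$seed, 12)))
  }

  # ---- reports ----
  out <- function(name) file.path(out_dir, name)
  write.csv(perfly, out("sleep_per_fly.csv"), row.names = FALSE)
  write.csv(line_sleep, out("sleep_by_line.csv"), row.names = FALSE)
  write.csv(pop_sleep, out("sleep_by_population.csv"), row.names = FALSE)
  write.csv(contrasts, out("population_contrasts.csv"), row.names = FALSE)
  write.csv(vials, out("ld50_by_vial.csv"), row.names = FALSE)
  write.csv(lines_ld50, out("ld50_by_line.csv"), row.names = FALSE)
  write.csv(metabolites, out("metabolites_by_line.csv"), row.names = FALSE)
  write.csv(pheno, out("line_phenotypes.csv"), row.names = FALSE)
  write.csv(reg_table(reg_sleep, reg_chg), out("regressions.csv"),
            row.names = FALSE)
  write.csv(linear_model_table(ols_metab, ols_behav),
            out("linear_models.csv"), row.names = FALSE)
  if (bayes) {
    write.csv(bayes_table(bayes_fits), out("bayes_models.csv"),
              row.names = FALSE)
    write.csv(ppc_data(bayes_fits$behavior), out("ppc_behavior.csv"),
              row.names = FALSE)
  }
  anova_txt <- utils::capture.output(print(anova_fit))
  writeLines(anova_txt, out("anova_ld50.txt"))
  writeLines(log_lines, out("qc_log.txt"))

  invisible(structure(list(
    config = config, sim = sim, traces = traces, qc = qc, perfly = perfly,
    line_sleep = line_sleep, pop_sleep = pop_sleep, contrasts = contrasts,
    vials = vials, lines_ld50 = lines_ld50, plate_qc = qc_plates,
    metabolites = metabolites, pheno = pheno, anova = anova_fit,
    regressions = list(total_sleep_starved = reg_sleep,
                       pct_change_sleep = reg_chg),
    ols = list(metabolism = ols_metab, behavior = ols_behav),
    bayes = bayes_fits, out_dir = out_dir,
    files = list.files(out_dir, recursive = TRUE, full.names = TRUE)),
    class = "flysleep_run"))
}

#' @export
print.flysleep_run <- function(x, ...) {
  cat("flysleep pipeline run:", nrow(x$pheno), "line phenotype rows,",
      length(x$traces), "traces,", nrow(x$vials), "vials\n")
  cat("outputs in", x$out_dir, "\n")
  invisible(x)
}

# ME-vs-PC Welch tests per sex x temperature, one Bonferroni family per
# condition x period summary block
population_contrasts <- function(perfly, value = "total_sleep_pct") {
  blocks <- unique(perfly[c("condition", "period")])
  rows <- list()
  for (i in seq_len(nrow(blocks))) {
    d <- perfly[perfly$condition == blocks$condition[i] &
                  perfly$period == blocks$period[i], ]
    d$grp <- paste(d$population, d$sex, d$temperature, sep = "/")
    combos <- unique(d[c("sex", "temperature")])
    cmps <- lapply(seq_len(nrow(combos)), function(j) {
      paste(c("ME", "PC"), combos$sex[j], combos$temperature[j], sep = "/")
    })
    cmps <- Filter(function(cmp) all(cmp %in% d$grp), cmps)
    if (!length(cmps)) next
    tf <- pairwise_tests(d, value, "grp", comparisons = cmps)
    tf$condition <- blocks$condition[i]
    tf$period <- blocks$period[i]
    rows[[i]] <- as.data.frame(tf)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# join line-mean LD50, sleep and metabolite phenotypes into the
# one-row-per-line x sex x temperature model table
line_phenotype_table <- function(lines_ld50, perfly, metabolites) {
  key <- function(d) paste(d$line, d$sex, d$temperature, sep = "\r")
  fed <- perfly[perfly$condition == "fed" & perfly$period == "whole", ]
  stv <- perfly[perfly$condition == "starved" & perfly$period == "whole", ]
  agg <- function(d, col) {
    a <- aggregate(d[[col]], list(key = key(d)), mean, na.rm = TRUE)
    setNames(a$x, a$key)
  }
  chg <- agg(fed, "pct_change_sleep")
  mov <- agg(stv, "mean_awake_movement")
  slp <- agg(stv, "total_sleep_pct")
  out <- lines_ld50[!lines_ld50$flagged, , drop = FALSE]
  k <- key(out)
  out$pct_change_sleep <- unname(chg[k])
  out$starved_mean_movement <- unname(mov[k])
  out$total_sleep_starved <- unname(slp[k])
  mk <- key(metabolites)
  out$glucose_per_protein <- metabolites$glucose_per_protein[match(k, mk)]
  out$tga_per_protein <- metabolites$tga_per_protein[match(k, mk)]
  rownames(out) <- NULL
  out
}

reg_table <- function(...) {
  fits <- list(...)
  do.call(rbind, lapply(fits, function(f) f$table))
}

linear_model_table <- function(...) {
  fits <- list(...)
  do.call(rbind, lapply(fits, function(f) {
    cbind(flavor = f$flavor, f$coefficients,
          adj_r_squared = f$adj_r_squared, f_statistic = f$f_statistic,
          df1 = f$df[1], df2 = f$df[2])
  }))
}

bayes_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tab <- f$full_summary[c("term", "Estimate", "Est.Error",
                            "l-95% CI", "u-95% CI", "Rhat")]
    cbind(flavor = nm, tab, converged = f$converged)
  }))
}

#' Read a pipeline run configuration from YAML
#'
#' A YAML file with any of the [sim_config()] elements (plus `seed`)
#' under a `simulate:` block, and optional top-level `min_bout`,
#' `terminal_quiet_hours`, `bayes`, `chains`, `iter`.
#'
#' @param path YAML file.
#' @return list with `config` (a `sim_config`) and `args` for
#'   [run_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  simblock <- y$simulate %||% list()
  cfg <- do.call(sim_config, c(list(seed = y$seed %||% 1), simblock))
  args <- y[intersect(names(y), c("min_bout", "terminal_quiet_hours",
                                  "bayes", "chains", "iter"))]
  list(config = cfg, args = args)
}
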