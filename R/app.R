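# End-to-end pipeline: simulate -> classify -> reduce -> optimize ->
# scenarios/validate, with per-stage derived seeds, structured logging and
# a deterministic summary JSON.

#' Build a pipeline run configuration
#'
#' @param seed Global seed; per-stage seeds are derived from it via
#'   [derive_seed()] so stages can be re-run independently.
#' @param n_per_pattern Individuals per pattern (default 375).
#' @param days_per_person Days per person (default 1).
#' @param db_path Optional CSV path for the food database (default: shipped
#'   fixture).
#' @param bootstrap_B Bootstrap replicates for the uncertainty table
#'   (default 1000).
#' @param generations,pop_size NSGA-II settings (defaults 100 / 200).
#' @param tsne Run the t-SNE embedding stage (default `FALSE`; the exact
#'   O(n^2) embedding is slow at n = 1500).
#' @param scenario_lambdas Named per-scenario shift intensities.
#' @param requirements_path Optional CSV of requirement thresholds.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 42, n_per_pattern = 375, days_per_person = 1,
                       db_path = NULL, bootstrap_B = 1000,
                       generations = 100, pop_size = 200, tsne = FALSE,
                       scenario_lambdas = NULL, requirements_path = NULL) {
  cfg <- list(seed = as.integer(seed), n_per_pattern = n_per_pattern,
              days_per_person = days_per_person, db_path = db_path,
              bootstrap_B = bootstrap_B, generations = generations,
              pop_size = pop_size, tsne = tsne,
              scenario_lambdas = scenario_lambdas,
              requirements_path = requirements_path)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys match the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, y)
}

log_stage <- function(stage, ...) {
  message(sprintf("[dietsim] %s %s", stage, sprintf(...)))
}

write_json_deterministic <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order -- population simulation, bootstrap
#' uncertainty quantification, random-forest classification, adequacy
#' regression, PCA (optionally t-SNE), NSGA-II optimization with the three
#' weighting schemes, intervention scenarios, and benchmark validation --
#' writing every artifact plus an aggregated `summary.json` into `out_dir`.
#' Two runs with the same configuration and seed produce byte-identical
#' summaries.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if missing).
#' @return The summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config",
                                            call. = FALSE)
  if (missing(out_dir)) stop("`out_dir` is required", call. = FALSE)
  db <- if (is.null(config$db_path)) default_food_db() else {
    load_food_table(config$db_path)
  }
  requirements <- if (is.null(config$requirements_path)) {
    default_requirements()
  } else {
    default_requirements(config$requirements_path)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  summary <- list(seed = config$seed)

  # -- simulate --------------------------------------------------------------
  sim_cfg <- default_sim_config(db = db,
                                n_per_pattern = config$n_per_pattern,
                                days_per_person = config$days_per_person)
  pop <- simulate_population(sim_cfg, seed = derive_seed(config$seed,
                                                         "simulate"))
  write_population(pop, file.path(out_dir, "population.csv"))
  summary$config_hash <- attr(pop, "config_hash")
  log_stage("simulate", "n = %d rows (%.1fs)", nrow(pop),
            as.numeric(Sys.time() - t0, units = "secs"))

  pattern_means <- do.call(rbind, lapply(split(pop, pop$pattern), function(g) {
    data.frame(pattern = g$pattern[1], n = nrow(g),
               t(colMeans(g[, c(POP_NUTRIENTS, "ghg_kgco2e", "water_l",
                                "cost_usd", "diversity_score")])))
  }))
  rownames(pattern_means) <- NULL
  utils::write.csv(pattern_means, file.path(out_dir, "pattern_means.csv"),
                   row.names = FALSE)
  summary$pattern_means <- pattern_means
  iron_thr <- requirement_threshold(requirements, "iron_mg", pop$sex)
  ca_thr <- requirement_threshold(requirements, "calcium_mg", pop$sex)
  summary$population <- list(
    n = nrow(pop),
    energy_mean = mean(pop$energy_kcal), energy_sd = stats::sd(pop$energy_kcal),
    protein_mean = mean(pop$protein_g), iron_mean = mean(pop$iron_mg),
    calcium_mean = mean(pop$calcium_mg), ghg_mean = mean(pop$ghg_kgco2e),
    water_mean = mean(pop$water_l), cost_mean = mean(pop$cost_usd),
    diversity_mean = mean(pop$diversity_score),
    iron_adequacy_pct = adequacy_prevalence(pop$iron_mg, iron_thr),
    calcium_adequacy_pct = adequacy_prevalence(pop$calcium_mg, ca_thr),
    med_minus_west_ghg =
      mean(pop$ghg_kgco2e[pop$pattern == "Mediterranean"]) -
      mean(pop$ghg_kgco2e[pop$pattern == "Western"])
  )

  # -- bootstrap uncertainty -------------------------------------------------
  boot_seed <- derive_seed(config$seed, "bootstrap")
  boot_metrics <- c(energy_kcal = "energy_kcal", protein_g = "protein_g",
                    iron_mg = "iron_mg", calcium_mg = "calcium_mg",
                    ghg_kgco2e = "ghg_kgco2e", water_l = "water_l")
  boot_tab <- do.call(rbind, lapply(names(boot_metrics), function(m) {
    bs <- bootstrap_summary(pop[[boot_metrics[[m]]]], B = config$bootstrap_B,
                            seed = derive_seed(boot_seed, m))
    data.frame(metric = m, mean = bs$point_mean, se = bs$se,
               ci_low = bs$ci_low, ci_high = bs$ci_high, cv_pct = bs$cv_pct)
  }))
  utils::write.csv(boot_tab, file.path(out_dir, "bootstrap.csv"),
                   row.names = FALSE)
  summary$bootstrap <- boot_tab
  log_stage("bootstrap", "B = %d x %d metrics", config$bootstrap_B,
            nrow(boot_tab))

  # -- classify --------------------------------------------------------------
  clf <- train_pattern_classifier(pop, seed = derive_seed(config$seed,
                                                          "classify"))
  summary$classifier <- list(
    accuracy = clf$metrics$accuracy, macro_f1 = clf$metrics$macro_f1,
    weighted_f1 = clf$metrics$weighted_f1,
    per_class = clf$metrics$per_class,
    confusion = as.data.frame.matrix(clf$metrics$confusion),
    importances = clf$importances
  )
  write_json_deterministic(summary$classifier,
                           file.path(out_dir, "classifier_report.json"))
  reg <- fit_adequacy_regression(pop, requirements = requirements,
                                 seed = derive_seed(config$seed,
                                                    "regression"))
  summary$adequacy_regression <- list(
    r2 = reg$r2, rmse = reg$rmse, mape_pct = reg$mape_pct,
    per_pattern_r2 = as.list(reg$per_pattern_r2)
  )
  log_stage("classify", "accuracy %.3f, regression R2 %.3f",
            clf$metrics$accuracy, reg$r2)

  # -- reduce ----------------------------------------------------------------
  pca <- run_pca(pop)
  utils::write.csv(
    data.frame(feature = rownames(pca$loadings), pca$loadings),
    file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
  summary$pca <- list(explained_pct = pca$explained_pct,
                      cumulative_pct = pca$cumulative_pct)
  if (isTRUE(config$tsne)) {
    emb <- run_tsne(pop, seed = derive_seed(config$seed, "tsne"))
    utils::write.csv(data.frame(pattern = pop$pattern, emb$coords),
                     file.path(out_dir, "tsne_coords.csv"),
                     row.names = FALSE)
    summary$tsne_final_kl <- emb$final_kl
  }
  log_stage("reduce", "PC1+PC2 %.1f%% of variance", pca$cumulative_pct[2])

  # -- optimize --------------------------------------------------------------
  norms <- default_norms(cost_max = max(pop$cost_usd))
  summary$norms <- norms
  pareto <- nsga2_search(db, requirements, norms,
                         control = list(pop_size = config$pop_size,
                                        generations = config$generations),
                         seed = derive_seed(config$seed, "optimize"))
  utils::write.csv(as.data.frame(pareto), file.path(out_dir, "pareto.csv"),
                   row.names = FALSE)
  schemes <- list(nutrient = c(0.70, 0.15, 0.15),
                  sustainability = c(0.15, 0.70, 0.15),
                  balanced = c(0.33, 0.33, 0.33))
  summary$optimization <- lapply(schemes, function(w) {
    sel <- weighted_scenario_select(pareto, w)
    list(weights = w, f1_adequacy = sel$f1_adequacy,
         f2_environment = sel$f2_environment, f3_cost = sel$f3_cost,
         energy_kcal = sel$energy_kcal, cost_usd = sel$cost_usd,
         shares = as.list(sel[1, seq_along(FOOD_GROUPS)]),
         total_mass_kg = sel$total_mass_kg, score = attr(sel, "score"))
  })
  log_stage("optimize", "Pareto set of %d solutions", nrow(pareto))

  # -- scenarios + validation ------------------------------------------------
  scen <- run_scenarios(pop, db, lambdas = config$scenario_lambdas,
                        requirements = requirements)
  utils::write.csv(scen, file.path(out_dir, "scenarios.csv"),
                   row.names = FALSE)
  summary$scenarios <- as.data.frame(scen)
  validation_summary <- c(summary$population,
                          list(energy_mean = mean(pop$energy_kcal),
                               protein_mean = mean(pop$protein_g),
                               iron_mean = mean(pop$iron_mg),
                               calcium_mean = mean(pop$calcium_mg)))
  val <- rbind(
    validate_against_benchmarks(validation_summary,
                                load_benchmarks("sustainability")),
    validate_against_benchmarks(validation_summary,
                                load_benchmarks("nhanes"))
  )
  val$deviation_pct_reported <- ifelse(is.na(val$deviation_pct), NA,
                                       format_reported_pct(val$deviation_pct))
  utils::write.csv(val, file.path(out_dir, "validation.csv"),
                   row.names = FALSE)
  summary$validation <- val
  log_stage("scenarios", "%d scenarios, %d benchmark rows", nrow(scen),
            nrow(val))

  write_json_deterministic(summary, file.path(out_dir, "summary.json"))
  log_stage("done", "total %.1fs", as.numeric(Sys.time() - t0,
                                              units = "secs"))
  invisible(summary)
}

#' Render a human-readable report from a pipeline run directory
#'
#' Deterministic plain-text rendering of `summary.json` (pattern means,
#' bootstrap table, classification report, optimization selections,
#' scenario table, validation table).
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @param path Optional output file; when `NULL` the text is returned only.
#' @return Character vector of report lines, invisibly.
#' @export
make_report <- function(run_dir, path = NULL) {
  sj <- file.path(run_dir, "summary.json")
  if (!file.exists(sj)) {
    missing <- setdiff(c("summary.json", "population.csv", "pareto.csv",
                         "scenarios.csv", "validation.csv"),
                       list.files(run_dir))
    stop("incomplete run directory; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- jsonlite::read_json(sj, simplifyVector = TRUE)
  fmt_tab <- function(df) {
    utils::capture.output(print(format(df, digits = 4), row.names = FALSE))
  }
  lines <- c(
    "dietsim pipeline report",
    sprintf("seed %s | config %s | n = %s", s$seed, s$config_hash,
            s$population$n),
    "", "== Pattern means ==", fmt_tab(s$pattern_means),
    "", "== Bootstrap uncertainty (B = 1000 unless configured) ==",
    fmt_tab(s$bootstrap),
    "", "== Classification ==",
    sprintf("accuracy %.3f | macro F1 %.3f | weighted F1 %.3f",
            s$classifier$accuracy, s$classifier$macro_f1,
            s$classifier$weighted_f1),
    fmt_tab(s$classifier$per_class),
    "", "== Adequacy regression ==",
    sprintf("R2 %.3f | RMSE %.3f | MAPE %.1f%%", s$adequacy_regression$r2,
            s$adequacy_regression$rmse, s$adequacy_regression$mape_pct),
    "", "== Optimization (weighted selections) ==",
    vapply(names(s$optimization), function(nm) {
      o <- s$optimization[[nm]]
      sprintf("%-14s f1 %.3f  f2 %.3f  f3 %.3f  energy %.0f kcal  cost %.2f USD",
              nm, o$f1_adequacy, o$f2_environment, o$f3_cost,
              o$energy_kcal, o$cost_usd)
    }, character(1)),
    "", "== Scenarios ==", fmt_tab(s$scenarios),
    "", "== Benchmark validation ==",
    fmt_tab(s$validation[, c("metric", "model_estimate", "comparison",
                             "reference", "deviation_pct_reported", "pass")])
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
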