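# Synthetic population generator: four dietary-pattern archetypes, Dirichlet
# food-group composition, truncated-normal total daily food mass, demographic
# attributes, and derived intakes / footprints / cost / diversity.

PATTERNS <- c("Mediterranean", "Western", "Plant-based", "Mixed")

#' Default dietary-pattern specifications
#'
#' One row per pattern: Dirichlet base shares over the eight food groups
#' (summing to 1), concentration parameter alpha0, the truncated-normal
#' parameters of total daily food mass (kg/day, truncated to
#' `[mass_lower, mass_upper]`), and demographic / diversity parameters
#' (target post-truncation means and SDs). The shipped values were calibrated
#' once against the published pattern-level intake, footprint and cost means
#' (see the methods vignette and `scripts/calibrate_defaults.R`).
#'
#' @param path CSV of the same shape as the shipped fixture.
#' @return A `pattern_specs` data frame with 4 rows.
#' @export
pattern_specs <- function(path = dietsim_file("pattern_defaults.csv")) {
  specs <- utils::read.csv(path, stringsAsFactors = FALSE)
  share_cols <- paste0("share_", tolower(FOOD_GROUPS))
  needed <- c("pattern", share_cols, "concentration", "mass_mu", "mass_sigma",
              "mass_lower", "mass_upper", "age_mean", "age_sd", "bmi_mean",
              "bmi_sd", "female_frac", "income_mean", "income_sd",
              "tertiary_frac", "diversity_mean", "diversity_sd")
  missing <- setdiff(needed, names(specs))
  if (length(missing) > 0) {
    stop("pattern spec table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_pattern_specs(specs)
  class(specs) <- c("pattern_specs", "data.frame")
  specs
}

validate_pattern_specs <- function(specs) {
  share_cols <- paste0("share_", tolower(FOOD_GROUPS))
  shares <- as.matrix(specs[, share_cols])
  if (any(shares < 0)) stop("base shares must be nonnegative", call. = FALSE)
  if (any(abs(rowSums(shares) - 1) > 1e-9)) {
    stop("base shares must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(specs$concentration <= 0)) {
    stop("Dirichlet concentration must be positive", call. = FALSE)
  }
  invisible(specs)
}

spec_row <- function(specs, pattern) {
  i <- match(pattern, specs$pattern)
  if (is.na(i)) stop("unknown pattern '", pattern, "'", call. = FALSE)
  specs[i, , drop = FALSE]
}

base_shares <- function(specs, pattern) {
  s <- as.numeric(spec_row(specs, pattern)[, paste0("share_",
                                                    tolower(FOOD_GROUPS))])
  names(s) <- FOOD_GROUPS
  s
}

#' Sample food-group composition shares for a pattern
#'
#' Draws from Dirichlet(concentration x base shares): nonnegative vectors on
#' the 8-simplex whose expectation equals the pattern's base shares and whose
#' within-pattern dispersion shrinks as the concentration grows.
#'
#' @param spec One row of a `pattern_specs` table (or the table plus
#'   `pattern=` name).
#' @param n Number of draws.
#' @param pattern Pattern name if `spec` has several rows.
#' @return An `n` x 8 matrix of shares (columns in food-group order).
#' @export
sample_shares <- function(spec, n = 1, pattern = NULL) {
  if (nrow(spec) > 1) spec <- spec_row(spec, pattern)
  validate_pattern_specs(spec)
  s <- as.numeric(spec[, paste0("share_", tolower(FOOD_GROUPS))])
  alpha <- spec$concentration * s
  draws <- rdirichlet(n, alpha)
  colnames(draws) <- FOOD_GROUPS
  draws
}

#' Sample demographic attributes for a pattern
#'
#' Age and BMI are truncated normals (age on \[18, 80\] years, BMI on
#' \[15, 50\] kg/m2) whose *post-truncation* means match the pattern
#' targets; sex and tertiary education are Bernoulli; income quintile is a
#' discretized normal clipped to 1..5; season is uniform on 1..4.
#'
#' @inheritParams sample_shares
#' @return A data frame with columns `age_years`, `sex`, `bmi_kg_m2`,
#'   `income_quintile`, `education_tertiary`, `season`.
#' @export
sample_demographics <- function(spec, n = 1, pattern = NULL) {
  if (nrow(spec) > 1) spec <- spec_row(spec, pattern)
  age_mu <- truncnorm_location_for_mean(spec$age_mean, spec$age_sd, 18, 80)
  bmi_mu <- truncnorm_location_for_mean(spec$bmi_mean, spec$bmi_sd, 15, 50)
  data.frame(
    age_years = rtruncnorm(n, age_mu, spec$age_sd, 18, 80),
    sex = ifelse(stats::runif(n) < spec$female_frac, "female", "male"),
    bmi_kg_m2 = rtruncnorm(n, bmi_mu, spec$bmi_sd, 15, 50),
    income_quintile = pmin(pmax(round(stats::rnorm(
      n, spec$income_mean, spec$income_sd)), 1L), 5L),
    education_tertiary = stats::runif(n) < spec$tertiary_frac,
    season = sample.int(4L, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

POP_NUTRIENTS <- c("energy_kcal", "protein_g", "iron_mg", "calcium_mg",
                   "zinc_mg", "vitd_ug", "b12_ug")

as_consumption_matrix <- function(consumption_kg) {
  if (is.data.frame(consumption_kg)) consumption_kg <- as.matrix(consumption_kg)
  if (is.null(dim(consumption_kg))) {
    consumption_kg <- matrix(consumption_kg, nrow = 1)
  }
  if (ncol(consumption_kg) != length(FOOD_GROUPS)) {
    stop("consumption must have ", length(FOOD_GROUPS),
         " components (one per food group)", call. = FALSE)
  }
  if (any(consumption_kg < 0)) {
    stop("consumption must be nonnegative", call. = FALSE)
  }
  consumption_kg
}

#' Nutrient intakes from food-group consumption
#'
#' Weighted sum over the eight food groups: for each nutrient,
#' intake = sum_j consumption_kg\[j\] x density-per-kg\[j\], where per-100 g
#' densities in the database are converted to per-kg (x10) exactly once.
#' Deterministic and order-independent.
#'
#' @param consumption_kg Length-8 vector (or n x 8 matrix) of daily
#'   consumption in kg, in food-group order (Animal, Dairy, Fruit, Grain,
#'   Legume, Nuts, Oil, Vegetable).
#' @param db A `food_db` data frame.
#' @return Data frame with columns `energy_kcal`, `protein_g`, `iron_mg`,
#'   `calcium_mg`, `zinc_mg`, `vitd_ug`, `b12_ug` (one row per input row).
#' @export
#' @examples
#' db <- default_food_db()
#' compute_intakes(c(1, 0, 0, 0, 0, 0, 0, 0), db)$protein_g  # 242 g
compute_intakes <- function(consumption_kg, db) {
  cons <- as_consumption_matrix(consumption_kg)
  dens <- db_density_matrix(db, POP_NUTRIENTS)
  as.data.frame(cons %*% dens)
}

#' Environmental footprints and cost from food-group consumption
#'
#' GHG = sum_j C_j x EF_j, water = sum_j C_j x WF_j, cost = sum_j C_j x
#' price_j, with per-kg emission factors, water footprints and prices taken
#' from the database.
#'
#' @inheritParams compute_intakes
#' @return Data frame with columns `ghg_kgco2e`, `water_l`, `cost_usd`.
#' @export
#' @examples
#' db <- default_food_db()
#' compute_footprints(c(1, 0, 0, 0, 0, 0, 0, 0), db)  # 10.58, 6678, 11.50
compute_footprints <- function(consumption_kg, db) {
  cons <- as_consumption_matrix(consumption_kg)
  dens <- db_density_matrix(db, DB_FOOTPRINTS)
  out <- as.data.frame(cons %*% dens)
  names(out) <- c("ghg_kgco2e", "water_l", "cost_usd")
  out
}

#' Default simulation configuration
#'
#' @param db Food database.
#' @param specs Pattern specifications.
#' @param n_per_pattern Individuals per pattern (default 375, i.e. 1500
#'   total across the four patterns).
#' @param days_per_person Days simulated per person; rows of the population
#'   table are person-days (default 1).
#' @param pa_ratio_cap Cap applied to the plant/animal mass ratio when the
#'   animal + dairy denominator is ~0 (default 100).
#' @return A `sim_config` list.
#' @export
default_sim_config <- function(db = default_food_db(),
                               specs = pattern_specs(),
                               n_per_pattern = 375,
                               days_per_person = 1,
                               pa_ratio_cap = 100) {
  cfg <- list(db = db, specs = specs, n_per_pattern = n_per_pattern,
              days_per_person = days_per_person, pa_ratio_cap = pa_ratio_cap)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the dietary-pattern population
#'
#' Generates `n_per_pattern` individuals per pattern (default 375 x 4 =
#' 1500). Each person-day draws demographic attributes, Dirichlet food-group
#' shares, and a truncated-normal total daily mass; consumption = shares x
#' mass, from which nutrient intakes, footprints and cost are derived by
#' weighted summation over the food groups. The dietary diversity score
#' (distinct foods per day) is a discretized-normal sampled attribute, and
#' the plant/animal ratio is the mass ratio of non-animal, non-dairy groups
#' to animal + dairy (capped for near-zero denominators). Deterministic
#' given `seed`.
#'
#' @param config A `sim_config` list, see [default_sim_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A `diet_population` data frame (one row per person-day) with
#'   attributes `seed`, `config_hash` and `generated_at`.
#' @export
#' @examples
#' pop <- simulate_population(default_sim_config(n_per_pattern = 25), seed = 1)
#' table(pop$pattern)
simulate_population <- function(config = default_sim_config(), seed = 42) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config",
                                            call. = FALSE)
  validate_food_db(config$db, require_extension = TRUE)
  validate_pattern_specs(config$specs)
  npp <- config$n_per_pattern
  if (npp < 1 || npp != round(npp)) {
    stop("`n_per_pattern` must be a positive integer", call. = FALSE)
  }
  days <- config$days_per_person
  hash <- config_hash(list(specs = as.data.frame(config$specs),
                           db = as.data.frame(config$db),
                           n_per_pattern = npp, days = days,
                           pa_cap = config$pa_ratio_cap))
  pop <- with_seed(seed, {
    blocks <- lapply(seq_len(nrow(config$specs)), function(i) {
      spec <- config$specs[i, , drop = FALSE]
      n <- npp * days
      demo_people <- sample_demographics(spec, npp)
      demo <- demo_people[rep(seq_len(npp), each = days), , drop = FALSE]
      shares <- sample_shares(spec, n)
      mass <- rtruncnorm(n, spec$mass_mu, spec$mass_sigma,
                         spec$mass_lower, spec$mass_upper)
      cons <- shares * mass
      colnames(cons) <- paste0("consumption_", tolower(FOOD_GROUPS), "_kg")
      diversity <- pmin(pmax(round(stats::rnorm(
        n, spec$diversity_mean, spec$diversity_sd)), 4L), 20L)
      animal_mass <- cons[, 1] + cons[, 2]  # Animal + Dairy
      plant_mass <- mass - animal_mass
      pa_ratio <- pmin(plant_mass / pmax(animal_mass, 1e-12),
                       config$pa_ratio_cap)
      cbind(
        data.frame(pattern = spec$pattern, demo,
                   day = rep(seq_len(days), times = npp),
                   total_mass_kg = mass, stringsAsFactors = FALSE),
        as.data.frame(cons),
        compute_intakes(cons, config$db),
        compute_footprints(cons, config$db),
        data.frame(diversity_score = diversity, plant_animal_ratio = pa_ratio)
      )
    })
    do.call(rbind, blocks)
  })
  person_ids <- rep(seq_len(nrow(config$specs) * npp), each = days)
  pop <- cbind(person_id = person_ids, pop)
  rownames(pop) <- NULL
  structure(pop,
            seed = as.integer(seed), config_hash = hash,
            generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            class = c("diet_population", "data.frame"))
}

population_required_columns <- function() {
  c("person_id", "pattern", "age_years", "sex", "bmi_kg_m2",
    "income_quintile", "education_tertiary", "season", "day",
    "total_mass_kg", paste0("consumption_", tolower(FOOD_GROUPS), "_kg"),
    POP_NUTRIENTS, "ghg_kgco2e", "water_l", "cost_usd",
    "diversity_score", "plant_animal_ratio")
}

#' Write a simulated population to CSV (+ JSON metadata sidecar)
#'
#' The table is written at full precision (15 significant digits) so that a
#' read/write round trip is lossless at documented precision; metadata
#' (seed, config hash, package version, generation time) goes to
#' `<path>.meta.json`.
#'
#' @param pop A `diet_population`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  if (nrow(pop) == 0) stop("refusing to write an empty population",
                           call. = FALSE)
  df <- as.data.frame(pop)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, digits = 15, scientific = FALSE, trim = TRUE))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = attr(pop, "seed"),
               config_hash = attr(pop, "config_hash"),
               generated_at = attr(pop, "generated_at"),
               package_version = as.character(utils::packageVersion("dietsim")),
               n_rows = nrow(pop))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a population table written by [write_population()]
#'
#' @param path CSV path.
#' @return A `diet_population` data frame.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(pop) == 0) stop("population table is empty", call. = FALSE)
  missing <- setdiff(population_required_columns(), names(pop))
  if (length(missing) > 0) {
    stop("population table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pop$education_tertiary <- as.logical(pop$education_tertiary)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(pop, "seed") <- meta$seed
    attr(pop, "config_hash") <- meta$config_hash
    attr(pop, "generated_at") <- meta$generated_at
  }
  class(pop) <- c("diet_population", "data.frame")
  pop
}

#' Recompute derived fields from stored consumption
#'
#' Re-derives nutrient intakes, footprints, cost and the plant/animal ratio
#' from the consumption columns and a database; used by scenario
#' construction and by the internal consistency checks.
#'
#' @param pop A `diet_population`.
#' @param db A `food_db`.
#' @param pa_ratio_cap Plant/animal ratio cap (default 100).
#' @return `pop` with derived columns replaced.
#' @export
recompute_derived <- function(pop, db, pa_ratio_cap = 100) {
  cons <- as.matrix(pop[, paste0("consumption_", tolower(FOOD_GROUPS), "_kg")])
  intakes <- compute_intakes(cons, db)
  foot <- compute_footprints(cons, db)
  pop[, names(intakes)] <- intakes
  pop[, names(foot)] <- foot
  pop$total_mass_kg <- rowSums(cons)
  animal_mass <- cons[, 1] + cons[, 2]
  pop$plant_animal_ratio <- pmin((pop$total_mass_kg - animal_mass) /
                                   pmax(animal_mass, 1e-12), pa_ratio_cap)
  pop
}
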