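# Food-group composition database: nutrient densities (per 100 g),
# environmental footprint factors and prices (per kg), with SDs and food
# counts. All downstream aggregation (intakes, footprints, cost) is
# parameterized by this table.

FOOD_GROUPS <- c("Animal", "Dairy", "Fruit", "Grain", "Legume",
                 "Nuts", "Oil", "Vegetable")

# Core columns are printed reference values; zinc/vitd/b12 are calibrated
# extension densities shipped as a separate synthetic fixture.
DB_CORE_NUTRIENTS <- c("energy_kcal", "protein_g", "iron_mg", "calcium_mg")
DB_EXT_NUTRIENTS  <- c("zinc_mg", "vitd_ug", "b12_ug")
DB_NUTRIENTS      <- c(DB_CORE_NUTRIENTS, DB_EXT_NUTRIENTS)
DB_FOOTPRINTS     <- c("ghg_kgco2e", "water_l", "price_usd")

db_mean_columns <- function() c(DB_NUTRIENTS, DB_FOOTPRINTS)
db_sd_columns <- function() paste0(sub("_[a-z0-9]+$", "", db_mean_columns()), "_sd")

db_required_columns <- function(extended = FALSE) {
  means <- c(DB_CORE_NUTRIENTS, if (extended) DB_EXT_NUTRIENTS, DB_FOOTPRINTS)
  sds <- paste0(sub("_[a-z0-9]+$", "", means), "_sd")
  c("group", as.vector(rbind(means, sds)), "n_foods")
}

validate_food_db <- function(db, require_extension = FALSE) {
  if (!is.data.frame(db) || nrow(db) == 0) {
    stop("food database must be a non-empty data frame", call. = FALSE)
  }
  required <- db_required_columns(extended = require_extension)
  missing_cols <- setdiff(required, names(db))
  if (length(missing_cols) > 0) {
    stop("food database is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(db$group)) {
    stop("duplicate food group name(s): ",
         paste(unique(db$group[duplicated(db$group)]), collapse = ", "),
         call. = FALSE)
  }
  missing_groups <- setdiff(FOOD_GROUPS, db$group)
  if (length(missing_groups) > 0) {
    stop("incomplete food database; missing group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(db$group, FOOD_GROUPS)
  if (length(extra) > 0) {
    stop("unknown food group(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(intersect(names(db), c(db_mean_columns(), db_sd_columns(),
                                             "n_foods")), "group")
  for (col in num_cols) {
    vals <- db[[col]]
    if (!is.numeric(vals) || anyNA(vals)) {
      stop("column '", col, "' must be numeric with no missing values",
           call. = FALSE)
    }
    if (any(vals < 0)) {
      bad <- db$group[which(vals < 0)[1]]
      stop("negative value in column '", col, "', row '", bad, "'",
           call. = FALSE)
    }
  }
  if (any(db$n_foods <= 0) || any(db$n_foods != round(db$n_foods))) {
    stop("'n_foods' must be positive integers", call. = FALSE)
  }
  invisible(db)
}

#' Load a food-group composition table
#'
#' Reads the 8-group composition database (nutrient densities per 100 g;
#' greenhouse-gas, water and price factors per kg; SDs mirroring each mean;
#' per-group food counts) from CSV and validates it. When the optional
#' zinc / vitamin D / vitamin B12 density columns are absent they are filled
#' from the shipped calibrated fixture, with a warning.
#'
#' @param path Path to a CSV file with one row per food group. Column names
#'   follow the shipped default fixture (see `dietsim_file("food_groups.csv")`).
#' @param fill_extension Fill missing zinc/vitd/b12 columns from the shipped
#'   calibration fixture (default `TRUE`).
#' @return A validated `food_db` data frame with 8 rows ordered as
#'   Animal, Dairy, Fruit, Grain, Legume, Nuts, Oil, Vegetable.
#' @export
#' @examples
#' db <- load_food_table(dietsim_file("food_groups.csv"))
#' db$protein_g[db$group == "Animal"]
load_food_table <- function(path, fill_extension = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_food_db(db)
  missing_ext <- setdiff(DB_EXT_NUTRIENTS, names(db))
  if (length(missing_ext) > 0 && fill_extension) {
    ext <- utils::read.csv(dietsim_file("extension_nutrients_synthetic.csv"),
                           stringsAsFactors = FALSE)
    cols <- as.vector(rbind(missing_ext,
                            paste0(sub("_[a-z0-9]+$", "", missing_ext), "_sd")))
    db <- merge(db, ext[, c("group", cols)], by = "group", sort = FALSE)
    warning("extension nutrient column(s) ",
            paste(missing_ext, collapse = ", "),
            " absent; filled from the shipped calibrated fixture",
            call. = FALSE)
  }
  db <- db[match(FOOD_GROUPS, db$group), , drop = FALSE]
  rownames(db) <- NULL
  validate_food_db(db, require_extension = fill_extension)
  class(db) <- c("food_db", "data.frame")
  db
}

#' Write a food-group composition table to CSV
#'
#' Round-trips losslessly with [load_food_table()] at full double precision.
#'
#' @param db A `food_db` data frame (complete 8-group set).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(db, path) {
  validate_food_db(db)
  ok <- tryCatch({
    utils::write.csv(db, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Path to a packaged data fixture
#'
#' @param ... File name components under the package `extdata` directory.
#' @return Absolute file path.
#' @export
dietsim_file <- function(...) {
  system.file("extdata", ..., package = "dietsim", mustWork = TRUE)
}

#' Default food-group composition database
#'
#' The shipped 8-group fixture: printed reference means/SDs for energy,
#' protein, iron, calcium, GHG, water and price, plus calibrated synthetic
#' zinc / vitamin D / B12 densities.
#'
#' @return A `food_db` data frame (8 rows).
#' @export
default_food_db <- function() {
  suppressWarnings(load_food_table(dietsim_file("food_groups.csv")))
}

#' Per-kg density matrix for a food database
#'
#' Nutrient densities are stored per 100 g and converted (x10) to per-kg
#' exactly once here; footprint and price factors are already per kg.
#'
#' @param db A `food_db` data frame.
#' @param columns Mean columns to extract (default: all nutrients and
#'   footprint factors).
#' @return An 8 x p numeric matrix, rows ordered as `db$group`.
#' @export
db_density_matrix <- function(db, columns = db_mean_columns()) {
  validate_food_db(db, require_extension = all(DB_EXT_NUTRIENTS %in% columns))
  m <- as.matrix(db[, columns, drop = FALSE])
  rownames(m) <- db$group
  nutr <- intersect(columns, DB_NUTRIENTS)
  m[, nutr] <- m[, nutr] * 10  # per 100 g -> per kg
  m
}

#' Default nutrient requirement thresholds
#'
#' Per-nutrient, per-sex cut-points used by adequacy operations: iron EAR
#' 8 mg/day (male) and 18 mg/day (female); calcium 1000 mg/day both sexes;
#' zinc EAR 11/8 mg/day (male/female); vitamin D RDA 20 ug/day; vitamin B12
#' RDA 6 ug/day; protein RDA 0.8 g/kg body weight/day. All configurable by
#' editing the returned data frame or supplying a CSV of the same shape.
#'
#' @param path Optional CSV with columns `nutrient`, `sex`, `threshold`,
#'   `kind`; defaults to the shipped fixture.
#' @return A `requirement_set` data frame.
#' @export
default_requirements <- function(path = dietsim_file("requirements.csv")) {
  req <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("nutrient", "sex", "threshold", "kind")
  if (!all(needed %in% names(req))) {
    stop("requirement table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(req$threshold <= 0)) stop("requirement thresholds must be positive",
                                    call. = FALSE)
  nutrients <- c("iron_mg", "calcium_mg", "zinc_mg", "vitd_ug", "b12_ug",
                 "protein_g_per_kg")
  for (n in nutrients) for (s in c("male", "female")) {
    if (!any(req$nutrient == n & req$sex == s)) {
      stop("missing requirement for ", n, " (", s, ")", call. = FALSE)
    }
  }
  class(req) <- c("requirement_set", "data.frame")
  req
}

#' Look up a requirement threshold
#'
#' @param requirements A `requirement_set` data frame.
#' @param nutrient Nutrient name, e.g. `"iron_mg"`.
#' @param sex `"male"`, `"female"`, or a vector of either (vectorized lookup).
#' @return Numeric threshold(s).
#' @export
requirement_threshold <- function(requirements, nutrient, sex) {
  sub <- requirements[requirements$nutrient == nutrient, , drop = FALSE]
  if (nrow(sub) == 0) stop("no requirement for nutrient '", nutrient, "'",
                           call. = FALSE)
  idx <- match(sex, sub$sex)
  if (anyNA(idx)) stop("no ", nutrient, " requirement for sex: ",
                       paste(unique(sex[is.na(idx)]), collapse = ", "),
                       call. = FALSE)
  sub$threshold[idx]
}
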