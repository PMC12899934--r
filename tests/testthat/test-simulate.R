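test_that("Dirichlet share draws live on the simplex and match their moments", {
  specs <- pattern_specs()
  set.seed(1)
  for (p in specs$pattern) {
    draws <- sample_shares(specs, n = 200, pattern = p)
    expect_true(all(draws >= 0))
    expect_equal(rowSums(draws), rep(1, 200), tolerance = 1e-12)
  }
  # component means -> base shares (3 MC-SE band at 10,000 draws)
  spec <- specs[specs$pattern == "Mediterranean", ]
  draws <- sample_shares(spec, n = 10000)
  base <- as.numeric(spec[, paste0("share_", tolower(c(
    "Animal", "Dairy", "Fruit", "Grain", "Legume", "Nuts", "Oil",
    "Vegetable")))])
  se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - base) < 3 * se + 1e-12))
  # 10x concentration shrinks every component's variance
  tight <- spec
  tight$concentration <- spec$concentration * 10
  vt <- apply(sample_shares(tight, n = 10000), 2, var)
  expect_true(all(vt < apply(draws, 2, var)))
  # zero concentration is a parameter error
  bad <- spec; bad$concentration <- 0
  expect_error(sample_shares(bad), "concentration")
})

test_that("demographic sampling matches pattern targets after truncation", {
  specs <- pattern_specs()
  set.seed(2)
  plant <- sample_demographics(specs, n = 10000, pattern = "Plant-based")
  expect_true(abs(mean(plant$age_years) - 45.8) < 3 * 11.6 / sqrt(10000))
  expect_true(all(plant$age_years >= 18 & plant$age_years <= 80))
  west <- sample_demographics(specs, n = 10000, pattern = "Western")
  expect_true(abs(mean(west$bmi_kg_m2) - 27.3) < 3 * 4.8 / sqrt(10000))
  expect_true(all(west$income_quintile %in% 1:5))
  expect_true(all(west$season %in% 1:4))
  # boundary: female fraction 0 gives all males
  males <- specs[1, ]; males$female_frac <- 0
  expect_true(all(sample_demographics(males, n = 500)$sex == "male"))
})

test_that("intake aggregation is an exact weighted sum over food groups", {
  db <- test_db()
  expect_equal(compute_intakes(consumption(Animal = 1), db)$protein_g, 242)
  mix <- compute_intakes(consumption(Vegetable = 0.5, Legume = 0.2), db)
  expect_equal(mix$energy_kcal, 5 * 39.0 + 2 * 197.0)  # 589
  expect_equal(mix$iron_mg, 5 * 0.73 + 2 * 5.54)       # 14.73
  expect_equal(unlist(compute_intakes(numeric(8), db)), rep(0, 7),
               ignore_attr = TRUE)
  expect_error(compute_intakes(c(-1, rep(0, 7)), db), "nonnegative")
})

test_that("footprint aggregation matches the per-kg factors", {
  db <- test_db()
  animal <- compute_footprints(consumption(Animal = 1), db)
  expect_equal(unlist(animal), c(ghg_kgco2e = 10.58, water_l = 6678,
                                 cost_usd = 11.50))
  mix <- compute_footprints(consumption(Vegetable = 0.5, Legume = 0.2), db)
  expect_equal(mix$ghg_kgco2e, 0.763)
  expect_equal(mix$water_l, 1030)
  expect_equal(mix$cost_usd, 2.206)
  expect_equal(unlist(compute_footprints(numeric(8), db)),
               c(ghg_kgco2e = 0, water_l = 0, cost_usd = 0))
})

test_that("population generation is deterministic and internally consistent", {
  pop <- small_pop()
  expect_equal(nrow(pop), 200)
  expect_equal(unname(table(pop$pattern)), rep(50L, 4), ignore_attr = TRUE)
  expect_false(anyDuplicated(pop$person_id) > 0)

  pop2 <- simulate_population(default_sim_config(n_per_pattern = 50),
                              seed = 1)
  strip_ts <- function(x) { attr(x, "generated_at") <- NULL; x }
  expect_identical(strip_ts(as.data.frame(pop)),
                   strip_ts(as.data.frame(pop2)))

  # derived fields reproduce the weighted-sum contract to 1e-9 relative
  re <- recompute_derived(as.data.frame(pop), test_db())
  for (col in c("energy_kcal", "iron_mg", "ghg_kgco2e", "water_l",
                "cost_usd")) {
    expect_equal(re[[col]], pop[[col]], tolerance = 1e-9)
  }
  expect_true(all(as.matrix(pop[, grep("consumption_", names(pop))]) >= 0))
  expect_true(all(pop$plant_animal_ratio >= 0))

  expect_error(simulate_population(default_sim_config(n_per_pattern = 0)),
               "positive integer")
})

test_that("population CSV round trip preserves the table", {
  pop <- small_pop()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, tf)
  expect_true(file.exists(paste0(tf, ".meta.json")))
  back <- read_population(tf)
  expect_equal(as.data.frame(back), as.data.frame(pop), tolerance = 1e-12)
  expect_equal(attr(back, "seed"), attr(pop, "seed"))

  # schema violations are named
  df <- as.data.frame(pop)
  df$iron_mg <- NULL
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, tf2, row.names = FALSE)
  expect_error(read_population(tf2), "iron_mg")
  write.csv(df[0, ], tf2, row.names = FALSE)
  expect_error(read_population(tf2), "empty")
  expect_error(write_population(pop[0, ], tf2), "empty")
})

test_that("same-seed populations are byte-identical on disk", {
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_population(simulate_population(
    default_sim_config(n_per_pattern = 30), seed = 9), t1)
  write_population(simulate_population(
    default_sim_config(n_per_pattern = 30), seed = 9), t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
})
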