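test_that("scenario construction honours its limiting cases", {
  pop <- small_pop()
  db <- test_db()

  # lambda = 0 is the identity on every field
  same <- build_scenario(pop, "mediterranean_shift", db, lambda = 0)
  expect_equal(as.data.frame(same), as.data.frame(pop), tolerance = 1e-12)
  expect_identical(as.data.frame(build_scenario(pop, "baseline", db)),
                   as.data.frame(pop))

  # lambda = 1 plant_forward: every person's shares equal the plant target
  full <- build_scenario(pop, "plant_forward", db, lambda = 1)
  cons <- as.matrix(full[, grep("consumption_", names(full))])
  shares <- cons / rowSums(cons)
  target <- base_shares(pattern_specs(), "Plant-based")
  expect_equal(shares, matrix(target, nrow(shares), 8, byrow = TRUE,
                              dimnames = dimnames(shares)),
               tolerance = 1e-9)
  expect_lt(max(shares[, 1]), 0.07)  # animal share near the pattern floor

  expect_error(build_scenario(pop, "keto", db), "unknown scenario")
  expect_error(build_scenario(pop, "seasonal", db, lambda = 2), "lambda")
})

test_that("scenario populations stay internally consistent", {
  pop <- small_pop()
  db <- test_db()
  for (nm in c("mediterranean_shift", "plant_forward", "seasonal",
               "affordability")) {
    sp <- build_scenario(pop, nm, db)
    re <- recompute_derived(as.data.frame(sp), db)
    for (col in c("energy_kcal", "calcium_mg", "ghg_kgco2e", "cost_usd")) {
      expect_equal(re[[col]], sp[[col]], tolerance = 1e-9)
    }
    # total mass per person is preserved by the share transformations
    expect_equal(sp$total_mass_kg, pop$total_mass_kg, tolerance = 1e-9)
  }
})

test_that("plant-forward cuts emissions and affordability cuts cost", {
  pop <- default_pop()
  db <- test_db()
  pf <- build_scenario(pop, "plant_forward", db)
  expect_lt(mean(pf$ghg_kgco2e), mean(pop$ghg_kgco2e))
  af <- build_scenario(pop, "affordability", db)
  expect_lt(mean(af$cost_usd), mean(pop$cost_usd))
})

test_that("percent change and feasibility follow their formulas", {
  expect_equal(percent_change(66, 100), -34)
  expect_equal(percent_change(117, 100), 17)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "nonzero")

  expect_true(scenario_feasible(2500, 0.15))
  expect_false(scenario_feasible(3600, 0.15))
  expect_false(scenario_feasible(1800, 0.15))
  expect_false(scenario_feasible(2500, 0.40))
  expect_false(scenario_feasible(2500, 0.05))
})

test_that("percentage deviation reproduces the published signed values", {
  expect_equal(format_reported_pct(
    percentage_deviation(3309.7, 2100.0, signed = TRUE)), 57.6)
  expect_equal(format_reported_pct(
    percentage_deviation(111.6, 82.0, signed = TRUE)), 36.1)
  expect_equal(format_reported_pct(
    percentage_deviation(24.0, 15.5, signed = TRUE)), 54.8)
  # calcium: raw signed deviation is -4.547; the reporting convention
  # (half-away-from-zero at 2 dp then 1 dp) prints -4.6
  raw <- percentage_deviation(906.8, 950.0, signed = TRUE)
  expect_equal(raw, -4.5473684, tolerance = 1e-6)
  expect_equal(format_reported_pct(raw), -4.6)
  expect_equal(percentage_deviation(7, 7, signed = TRUE), 0)
  expect_equal(percentage_deviation(80, 100), 20)  # absolute form
  expect_error(percentage_deviation(1, 0), "nonzero")
})

test_that("benchmark validation applies each comparison rule", {
  bench <- load_benchmarks("sustainability")
  s <- list(ghg_mean = 3.88, water_mean = 4086, iron_adequacy_pct = 96.7,
            calcium_adequacy_pct = 92.1, diversity_mean = 11.4,
            med_minus_west_ghg = -0.14)
  v <- validate_against_benchmarks(s, bench)
  expect_true(all(v$evaluable))
  expect_true(all(v$pass))

  s$ghg_mean <- 6.0
  v2 <- validate_against_benchmarks(s, bench)
  expect_false(v2$pass[v2$metric == "ghg_kgco2e_per_day"])

  s$diversity_mean <- NULL
  v3 <- validate_against_benchmarks(s, bench)
  row <- v3[v3$metric == "dietary_diversity_score", ]
  expect_false(row$evaluable)
  expect_equal(nrow(v3), nrow(bench))  # never silently dropped

  nh <- load_benchmarks("nhanes")
  v4 <- validate_against_benchmarks(
    list(energy_mean = 3309.7, protein_mean = 111.6, calcium_mean = 906.8,
         iron_mean = 24.0), nh)
  expect_equal(format_reported_pct(v4$deviation_pct),
               c(57.6, 36.1, -4.6, 54.8))
  expect_equal(v4$pass, c(FALSE, FALSE, TRUE, FALSE))  # 20% rule
  expect_equal(v4$within_reference_range, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("the scenario table covers all five interventions", {
  pop <- small_pop()
  tab <- run_scenarios(pop, test_db())
  expect_equal(tab$name, c("baseline", "mediterranean_shift",
                           "plant_forward", "seasonal", "affordability"))
  base <- tab[tab$name == "baseline", ]
  expect_equal(base$ghg_pct_of_baseline, 100)
  expect_equal(base$water_pct_of_baseline, 100)
  expect_true(all(tab$iron_adequacy_pct >= 0 & tab$iron_adequacy_pct <= 100))
})
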