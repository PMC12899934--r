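test_that("objective evaluation matches its defining ratios", {
  db <- test_db()
  d <- diet_vector(rep(1 / 8, 8), 2)
  intk <- compute_intakes(d$shares * d$total_mass_kg, db)
  foot <- compute_footprints(d$shares * d$total_mass_kg, db)

  # thresholds set equal to the achieved intakes make every ratio 1
  req <- default_requirements()
  req$threshold[req$nutrient == "iron_mg"] <- intk$iron_mg
  req$threshold[req$nutrient == "calcium_mg"] <- intk$calcium_mg
  req$threshold[req$nutrient == "zinc_mg"] <- intk$zinc_mg
  req$threshold[req$nutrient == "protein_g_per_kg"] <- intk$protein_g / 70
  norms <- list(ghg_max = foot$ghg_kgco2e, water_l = NULL,
                water_max = foot$water_l, cost_max = foot$cost_usd)
  ev <- evaluate_objectives(d, db, req, norms)
  expect_equal(ev$f1_adequacy, 1, tolerance = 1e-12)
  expect_equal(ev$f2_environment, 1, tolerance = 1e-12)
  expect_equal(ev$f3_cost, 1, tolerance = 1e-12)

  # at half the normalization maxima the composite is 0.5
  norms2 <- list(ghg_max = 2 * foot$ghg_kgco2e,
                 water_max = 2 * foot$water_l,
                 cost_max = 2 * foot$cost_usd)
  expect_equal(evaluate_objectives(d, db, req, norms2)$f2_environment, 0.5,
               tolerance = 1e-12)

  bad <- req
  bad$threshold[bad$nutrient == "iron_mg"] <- -1
  expect_error(evaluate_objectives(d, db, bad), "positive")
})

test_that("price scaling moves f3 proportionally and leaves f1/f2 alone", {
  db <- test_db()
  d <- diet_vector(rep(1 / 8, 8), 2)
  norms <- default_norms(cost_max = 30)
  base <- evaluate_objectives(d, db, norms = norms)
  scaled_db <- db
  scaled_db$price_usd <- db$price_usd * 3
  scaled <- evaluate_objectives(d, scaled_db, norms = norms)
  expect_equal(scaled$f3_cost, 3 * base$f3_cost, tolerance = 1e-12)
  expect_equal(scaled$f1_adequacy, base$f1_adequacy)
  expect_equal(scaled$f2_environment, base$f2_environment)
})

test_that("constraint checks mirror the feasibility definition", {
  db <- test_db()
  ok <- check_constraints(diet_vector(rep(1 / 8, 8), 1.2), db)
  expect_true(ok$energy_ok && ok$protein_ratio_ok && ok$shares_ok)
  expect_true(ok$feasible)

  low <- check_constraints(diet_vector(rep(1 / 8, 8), 0.6), db)
  expect_false(low$energy_ok)
  expect_false(low$feasible)

  # a raw share list with a 0.5 component fails the cap check
  d <- list(shares = c(0.5, 0.5, 0, 0, 0, 0, 0, 0), total_mass_kg = 1.5)
  expect_false(check_constraints(d, db)$shares_ok)
  expect_error(diet_vector(c(0.5, 0.5, rep(0, 6)), 1), "cap")
})

test_that("share repair lands on the capped simplex from anywhere", {
  set.seed(30)
  for (i in 1:200) {
    raw <- runif(8) * sample(c(1, 10, 0.01), 1)
    if (i %% 7 == 0) raw[sample(8, 6)] <- 0
    s <- repair_shares(raw)
    expect_equal(sum(s), 1, tolerance = 1e-9)
    expect_true(all(s >= 0 & s <= 0.4 + 1e-9))
  }
  expect_equal(repair_shares(c(5, 5, 0, 0, 0, 0, 0, 0)),
               c(0.4, 0.4, rep(0.2 / 6, 6)), tolerance = 1e-12)
  valid <- c(0.3, 0.2, 0.1, 0.1, 0.1, 0.1, 0.05, 0.05)
  expect_equal(repair_shares(valid), valid, tolerance = 1e-12)
})

test_that("the engine recovers a known bi-objective front", {
  # minimize (x^2, (x-1)^2) for x in [0, 1]: the whole interval is optimal
  fitness <- function(g) list(obj = cbind(g[, 1]^2, (g[, 1] - 1)^2))
  res <- nsga2_engine(fitness, 1, pop_size = 80, generations = 60, seed = 2)
  xs <- res$genomes[res$rank == 1, 1]
  expect_gt(length(xs), 40)
  expect_lt(min(xs), 0.05)
  expect_gt(max(xs), 0.95)
  # hypervolume wrt reference (1.1, 1.1): staircase area of the
  # non-dominated subset sorted by the first objective
  hv <- function(pts, ref = c(1.1, 1.1)) {
    pts <- pts[order(pts[, 1]), , drop = FALSE]
    keep <- cummin(pts[, 2]) == pts[, 2]
    pts <- pts[keep, , drop = FALSE]
    sum((ref[2] - pts[, 2]) * diff(c(pts[, 1], ref[1])))
  }
  x_true <- seq(0, 1, length.out = 2000)
  hv_true <- hv(cbind(x_true^2, (1 - x_true)^2))
  hv_got <- hv(res$obj[res$rank == 1, , drop = FALSE])
  expect_gt(hv_got, 0.95 * hv_true)
})

test_that("the Pareto set is feasible, non-dominated and reproducible", {
  db <- test_db()
  norms <- default_norms(cost_max = 30)
  ctl <- list(pop_size = 60, generations = 40)
  ps <- nsga2_search(db, norms = norms, control = ctl, seed = 3)
  expect_gt(nrow(ps), 5)
  # every member satisfies the constraints exactly
  for (i in seq_len(nrow(ps))) {
    cc <- check_constraints(list(shares = as.numeric(ps[i, 1:8]),
                                 total_mass_kg = ps$total_mass_kg[i]), db)
    expect_true(cc$feasible)
  }
  # exhaustive pairwise non-domination (maximize f1, minimize f2, f3)
  obj <- cbind(-ps$f1_adequacy, ps$f2_environment, ps$f3_cost)
  for (i in seq_len(nrow(obj))) {
    dominated <- apply(obj, 1, function(o) {
      all(o <= obj[i, ]) && any(o < obj[i, ])
    })
    expect_false(any(dominated))
  }
  ps2 <- nsga2_search(db, norms = norms, control = ctl, seed = 3)
  expect_identical(as.data.frame(ps), as.data.frame(ps2))
})

test_that("weighted selection picks extremes and breaks ties by f2 then f3", {
  ps <- data.frame(f1_adequacy = c(1.0, 0.8, 0.6),
                   f2_environment = c(0.9, 0.4, 0.2),
                   f3_cost = c(0.9, 0.6, 0.2))
  expect_equal(weighted_scenario_select(ps, c(1, 0, 0))$f1_adequacy, 1.0)
  expect_equal(weighted_scenario_select(ps, c(0, 1, 0))$f2_environment, 0.2)
  # hand-scored: weights (1/3, 1/3, 1/3) tie between rows 1 and 3 at 0.066
  # within rounding; row 3 wins on lower f2
  sel <- weighted_scenario_select(ps, c(0.33, 0.33, 0.33))
  expect_equal(sel$f1_adequacy, 0.6)
  expect_error(weighted_scenario_select(ps[0, ], c(1, 0, 0)), "empty")
  expect_error(weighted_scenario_select(ps, c(1, 1, 1)), "summing")
})

test_that("capped composition enumeration matches hand counts", {
  # step 0.5 over 2 effective parts: compositions of 2 units into 2 parts
  two <- capped_compositions(2, 2, 2)
  expect_equal(nrow(two), 3)  # (0,2), (1,1), (2,0)
  expect_true(all(rowSums(two) == 2))
  # cap excludes corners: parts <= 1 leaves only (1,1)
  expect_equal(nrow(capped_compositions(2, 2, 1)), 1)
  # 8 groups at step 0.25 with cap 0.5: brute-force check of the count
  grid <- capped_compositions(4, 8, 2)
  expect_true(all(rowSums(grid) == 4))
  expect_true(all(grid <= 2))
  brute <- expand.grid(rep(list(0:2), 8))
  expect_equal(nrow(grid), sum(rowSums(brute) == 4))
})

test_that("an energy-starved database yields no feasible grid diet", {
  db <- as.data.frame(test_db())
  db$energy_kcal <- db$energy_kcal / 100  # max ~50 kcal/kg: 2000 unreachable
  class(db) <- c("food_db", "data.frame")
  res <- grid_oracle(db, grid_step = 0.25, mass_grid = seq(0.5, 6, 0.5))
  expect_false(res$feasible)
  expect_identical(res$score, -Inf)
})
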