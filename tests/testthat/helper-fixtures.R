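# Shared fixtures. Expensive objects (the full default population, trained
# classifier) are built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small population for structural tests (200 rows).
small_pop <- function(seed = 1) {
  memoize(paste0("small_pop_", seed), {
    simulate_population(default_sim_config(n_per_pattern = 50), seed = seed)
  })
}

# Full default-scale population (1500 rows) at the default seed.
default_pop <- function() {
  memoize("default_pop", simulate_population(seed = 42))
}

# Default database, loaded once.
test_db <- function() memoize("db", default_food_db())

# A consumption vector in food-group order with named components set.
consumption <- function(...) {
  v <- stats::setNames(numeric(8), c("Animal", "Dairy", "Fruit", "Grain",
                                     "Legume", "Nuts", "Oil", "Vegetable"))
  args <- list(...)
  v[names(args)] <- unlist(args)
  v
}

# Well-separated 4-cluster synthetic table shaped like a population, for
# classifier sanity checks.
separable_pop <- function(n_per_class = 60, seed = 7, spread = 0.5) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    feats <- classifier_features()
    centers <- matrix(rnorm(4 * length(feats), sd = 6), 4)
    rows <- lapply(1:4, function(k) {
      x <- matrix(rnorm(n_per_class * length(feats), sd = spread),
                  n_per_class) + matrix(centers[k, ], n_per_class,
                                        length(feats), byrow = TRUE)
      df <- as.data.frame(x)
      names(df) <- feats
      df$pattern <- paste0("P", k)
      df
    })
    out <- do.call(rbind, rows)
    out$sex <- ifelse(out$sex > median(out$sex), "female", "male")
    out
  })
}

# Label vectors realizing integer confusion counts consistent with the
# shipped reference class-metric table (supports 107/125/64/154; diagonal
# 12/38/4/122; predicted-class totals 23/96/8/323, summing to 450).
reference_confusion_labels <- function() {
  classes <- c("Mediterranean", "Western", "Plant-based", "Mixed")
  cm <- matrix(c(12,  0, 4,  91,
                 11, 38, 0,  76,
                  0, 26, 4,  34,
                  0, 32, 0, 122),
               4, 4, byrow = TRUE, dimnames = list(classes, classes))
  true <- rep(classes, times = rowSums(cm))
  pred <- unlist(lapply(classes, function(cl) {
    rep(classes, times = cm[cl, ])
  }))
  list(true = true, pred = pred, counts = cm)
}
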