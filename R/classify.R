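# Dietary-pattern classification (random forest with Gini importances) and
# the nutrient-adequacy OLS regression with R2 / RMSE / MAPE metrics.

#' Default classifier feature list
#'
#' The twelve features used for pattern classification: demographics (age,
#' sex, BMI), socioeconomic (income quintile), season, intakes (energy,
#' protein), footprints (GHG, water), cost, diversity score and the
#' plant/animal mass ratio.
#'
#' @return Character vector of column names.
#' @export
classifier_features <- function() {
  c("age_years", "sex", "bmi_kg_m2", "income_quintile", "season",
    "energy_kcal", "protein_g", "ghg_kgco2e", "water_l", "cost_usd",
    "diversity_score", "plant_animal_ratio")
}

# Stratified train/test split: returns logical vector (TRUE = train).
stratified_split <- function(labels, train_frac) {
  train <- logical(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    n_train <- round(length(idx) * train_frac)
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

#' F1 score from precision and recall
#'
#' Harmonic mean 2PR/(P+R); defined as 0 when both are 0.
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return Numeric vector of F1 scores.
#' @export
#' @examples
#' f1_score(0.522, 0.112)  # ~0.185
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Confusion-matrix classification metrics
#'
#' Tabulates true vs predicted labels and derives per-class precision
#' (positive predictive value), recall (sensitivity), F1 and support;
#' overall accuracy (trace / total); macro averages (unweighted means over
#' classes) and support-weighted averages. Classes with an empty prediction
#' column get precision 0 (and F1 accordingly), with a message.
#'
#' @param true_labels,predicted_labels Equal-length label vectors over the
#'   same label set.
#' @param labels Optional explicit label ordering.
#' @return A `classifier_metrics` list: `confusion` (rows = true, cols =
#'   predicted), `per_class` data frame, `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `weighted_precision`, `weighted_recall`,
#'   `weighted_f1`, `n`.
#' @export
confusion_metrics <- function(true_labels, predicted_labels, labels = NULL) {
  if (length(true_labels) == 0) stop("empty label input", call. = FALSE)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (is.null(labels)) labels <- sort(unique(c(as.character(true_labels),
                                               as.character(predicted_labels))))
  tt <- factor(as.character(true_labels), levels = labels)
  pp <- factor(as.character(predicted_labels), levels = labels)
  cm <- table(true = tt, predicted = pp)
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  if (any(pred_tot == 0)) {
    message("class(es) never predicted (precision set to 0): ",
            paste(labels[pred_tot == 0], collapse = ", "))
  }
  precision <- ifelse(pred_tot == 0, 0, tp / pred_tot)
  recall <- ifelse(support == 0, 0, tp / support)
  f1 <- f1_score(precision, recall)
  per_class <- data.frame(class = labels, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          support = as.numeric(support))
  w <- support / sum(support)
  structure(list(
    confusion = unclass(cm),
    per_class = per_class,
    accuracy = sum(tp) / sum(cm),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    weighted_precision = sum(w * precision),
    weighted_recall = sum(w * recall),
    weighted_f1 = sum(w * f1),
    n = sum(cm)
  ), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat("Classification report (n =", x$n, ")\n")
  cat(sprintf("accuracy %.3f | macro F1 %.3f | weighted F1 %.3f\n",
              x$accuracy, x$macro_f1, x$weighted_f1))
  print(cbind(round(x$per_class[, 2:4], 3), support = x$per_class$support))
  invisible(x)
}

#' Train the dietary-pattern random-forest classifier
#'
#' Stratified 70/30 train/test split, a 500-tree random forest (maximum
#' depth 20, minimum 5 samples per leaf, 4 candidate features per split),
#' evaluation on the held-out 30%, and normalized Gini (impurity-decrease)
#' feature importances with standard errors estimated from independent
#' sub-forest batches (see the methods vignette).
#'
#' @param pop A `diet_population` (>= 2 patterns).
#' @param features Feature columns (default [classifier_features()]).
#' @param seed Split/forest seed (default 42).
#' @param num_trees,max_depth,min_node_size,mtry Forest hyperparameters.
#' @param train_frac Training fraction (default 0.7).
#' @param importance_batches Number of sub-forests used for importance SEs.
#' @return A `pattern_classifier` list: `metrics` (a `classifier_metrics`),
#'   `importances` (data frame feature/mean/se, means summing to 1),
#'   `model` (the ranger forest), `split_seed`, `features`.
#' @export
train_pattern_classifier <- function(pop, features = classifier_features(),
                                     seed = 42, num_trees = 500,
                                     max_depth = 20, min_node_size = 5,
                                     mtry = 4, train_frac = 0.7,
                                     importance_batches = 20) {
  if (length(unique(pop$pattern)) < 2) {
    stop("need at least two patterns to classify", call. = FALSE)
  }
  missing <- setdiff(features, names(pop))
  if (length(missing) > 0) {
    stop("unknown feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- pop[, c("pattern", features)]
  df$pattern <- factor(df$pattern)
  for (col in features) if (is.character(df[[col]])) {
    df[[col]] <- factor(df[[col]])
  }
  with_seed(seed, {
    train <- stratified_split(df$pattern, train_frac)
    fit <- ranger::ranger(pattern ~ ., data = df[train, ],
                          num.trees = num_trees, mtry = mtry,
                          min.node.size = min_node_size,
                          max.depth = max_depth, importance = "impurity",
                          seed = derive_seed(seed, "forest"),
                          num.threads = 1)
    pred <- stats::predict(fit, df[!train, ], num.threads = 1)$predictions
    metrics <- confusion_metrics(df$pattern[!train], pred,
                                 labels = levels(df$pattern))
    imp_mean <- fit$variable.importance
    imp_mean <- imp_mean / sum(imp_mean)
    # SE from across-tree dispersion, estimated via independent sub-forests:
    # sd over K batches of m trees estimates sd_tree/sqrt(m), so
    # sd(batches)/sqrt(K) estimates sd_tree/sqrt(m*K) = sd_tree/sqrt(T).
    m <- max(1, floor(num_trees / importance_batches))
    batch_imp <- vapply(seq_len(importance_batches), function(b) {
      bf <- ranger::ranger(pattern ~ ., data = df[train, ],
                           num.trees = m, mtry = mtry,
                           min.node.size = min_node_size,
                           max.depth = max_depth, importance = "impurity",
                           seed = derive_seed(seed, paste0("imp", b)),
                           num.threads = 1)
      v <- bf$variable.importance
      v / sum(v)
    }, numeric(length(imp_mean)))
    imp_se <- apply(batch_imp, 1, stats::sd) / sqrt(importance_batches)
    structure(list(
      metrics = metrics,
      importances = data.frame(feature = names(imp_mean),
                               mean = as.numeric(imp_mean),
                               se = as.numeric(imp_se), row.names = NULL),
      model = fit, split_seed = as.integer(seed), features = features
    ), class = "pattern_classifier")
  })
}

#' Fit the nutrient-adequacy regression
#'
#' Ordinary least squares for a continuous adequacy ratio (default: iron
#' intake divided by the sex-specific iron EAR) on a feature set, with the
#' same stratified 70/30 split protocol as the classifier. Reports held-out
#' R2 (1 - SSE/SST), RMSE and MAPE (%); rows with zero response are excluded
#' from MAPE with a message; per-pattern R2 is computed within the held-out
#' subset of each pattern.
#'
#' @param pop A `diet_population`.
#' @param response Response column name, or `"iron_adequacy"` (computed from
#'   `iron_mg` and the requirement set).
#' @param predictors Predictor columns (default [classifier_features()]).
#' @param requirements Requirement set for adequacy responses.
#' @param seed Split seed.
#' @param train_frac Training fraction (default 0.7).
#' @return A `regression_report` list: `intercept`, `coefficients`, `r2`,
#'   `rmse`, `mape_pct`, `per_pattern_r2`, `n_test`.
#' @export
fit_adequacy_regression <- function(pop, response = "iron_adequacy",
                                    predictors = classifier_features(),
                                    requirements = default_requirements(),
                                    seed = 42, train_frac = 0.7) {
  df <- as.data.frame(pop)
  if (identical(response, "iron_adequacy") && !"iron_adequacy" %in% names(df)) {
    thr <- requirement_threshold(requirements, "iron_mg", df$sex)
    df$iron_adequacy <- df$iron_mg / thr
  }
  if (!response %in% names(df)) stop("unknown response column '", response,
                                     "'", call. = FALSE)
  y_all <- df[[response]]
  if (stats::var(y_all) == 0) stop("response is constant", call. = FALSE)
  if (nrow(df) < length(predictors) + 2) {
    stop("need at least p + 2 rows", call. = FALSE)
  }
  for (col in predictors) if (is.character(df[[col]])) {
    df[[col]] <- factor(df[[col]])
  }
  form <- stats::as.formula(paste(response, "~",
                                  paste(predictors, collapse = " + ")))
  with_seed(derive_seed(seed, "regression"), {
    train <- stratified_split(df$pattern, train_frac)
    fit <- stats::lm(form, data = df[train, ])
    aliased <- names(which(is.na(stats::coef(fit))))
    if (length(aliased) > 0) {
      stop("rank-deficient design; collinear term(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    test <- df[!train, ]
    pred <- stats::predict(fit, test)
    y <- test[[response]]
    metrics <- regression_metrics(y, pred)
    per_pattern <- vapply(split(seq_len(nrow(test)), test$pattern),
                          function(idx) {
                            regression_metrics(y[idx], pred[idx])$r2
                          }, numeric(1))
    structure(list(
      intercept = unname(stats::coef(fit)[1]),
      coefficients = stats::coef(fit)[-1],
      r2 = metrics$r2, rmse = metrics$rmse, mape_pct = metrics$mape_pct,
      per_pattern_r2 = per_pattern, n_test = nrow(test), model = fit
    ), class = "regression_report")
  })
}

#' Regression error metrics
#'
#' R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2); RMSE =
#' sqrt(mean((y - yhat)^2)); MAPE = 100 x mean(|y - yhat| / y), computed
#' over nonzero `y` (excluded zeros are reported with a message).
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return List with `r2`, `rmse`, `mape_pct`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4))  # rmse 0.577, mape 11.1
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  nz <- y != 0
  if (any(!nz)) message(sum(!nz), " zero response value(s) excluded from MAPE")
  list(
    r2 = if (sst == 0) NA_real_ else 1 - sse / sst,
    rmse = sqrt(mean((y - yhat)^2)),
    mape_pct = 100 * mean(abs((y[nz] - yhat[nz]) / y[nz]))
  )
}
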