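# Latent-structure analysis: PCA on the standardized feature matrix, a
# seed-deterministic exact t-SNE embedding, and convex-hull summaries of
# labelled 2-D embeddings.

#' Default dimensionality-reduction feature list
#'
#' Fourteen features (cost excluded, so that the latent structure reflects
#' nutritional and environmental composition rather than market pricing):
#' age, sex, BMI, income quintile, season, energy, protein, iron, calcium,
#' zinc, diversity, plant/animal ratio, GHG, water.
#'
#' @return Character vector of column names.
#' @export
reduction_features <- function() {
  c("age_years", "sex", "bmi_kg_m2", "income_quintile", "season",
    "energy_kcal", "protein_g", "iron_mg", "calcium_mg", "zinc_mg",
    "diversity_score", "plant_animal_ratio", "ghg_kgco2e", "water_l")
}

# Numeric feature matrix (sex coded 0/1; logicals to numeric).
feature_matrix <- function(pop, features) {
  missing <- setdiff(features, names(pop))
  if (length(missing) > 0) {
    stop("unknown feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(features, function(f) {
    v <- pop[[f]]
    if (is.character(v)) v <- as.numeric(factor(v)) - 1
    as.numeric(v)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- features
  x
}

#' Principal component analysis of a population feature table
#'
#' Z-score standardization followed by singular value decomposition.
#' Component signs are fixed by forcing the largest-magnitude loading of
#' each component to be positive, making outputs comparable across runs.
#'
#' @param pop A `diet_population` (or any data frame).
#' @param features Numeric feature columns (default [reduction_features()]).
#' @return A `pca_result` list: `loadings` (p x p orthonormal),
#'   `singular_values` (descending), `scores` (n x p), `explained_pct`,
#'   `cumulative_pct`, `center`, `scale`.
#' @export
run_pca <- function(pop, features = reduction_features()) {
  x <- feature_matrix(pop, features)
  if (nrow(x) <= ncol(x)) stop("need n > p observations", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(x)
  sv <- svd(z)
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(sv$v, 2, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d), 2, flip, `*`)
  var_expl <- sv$d^2 / sum(sv$d^2) * 100
  dimnames(loadings) <- list(features, paste0("PC", seq_along(features)))
  colnames(scores) <- paste0("PC", seq_along(features))
  structure(list(loadings = loadings, singular_values = sv$d,
                 scores = scores, explained_pct = var_expl,
                 cumulative_pct = cumsum(var_expl),
                 center = attr(z, "scaled:center"),
                 scale = attr(z, "scaled:scale")),
            class = "pca_result")
}

# Perplexity calibration: bisection on the Gaussian kernel precision for one
# point's squared-distance row, targeting log(perplexity) entropy.
tsne_p_row <- function(d2, target_entropy, tol = 1e-5, max_iter = 50) {
  beta <- 1
  beta_min <- -Inf
  beta_max <- Inf
  for (it in seq_len(max_iter)) {
    p <- exp(-d2 * beta)
    sum_p <- sum(p)
    if (sum_p == 0) {
      h <- 0
      p <- p * 0
    } else {
      h <- log(sum_p) + beta * sum(d2 * p) / sum_p
      p <- p / sum_p
    }
    diff <- h - target_entropy
    if (abs(diff) < tol) break
    if (diff > 0) {
      beta_min <- beta
      beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
    } else {
      beta_max <- beta
      beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
    }
  }
  p
}

#' t-SNE embedding of a population feature table
#'
#' Exact (O(n^2)) symmetric t-SNE on the z-scored feature matrix: Gaussian
#' input similarities calibrated per point to the requested perplexity,
#' Student-t (one degree of freedom) low-dimensional kernel, gradient
#' descent with early exaggeration (x4 for the first 100 iterations) and
#' momentum (0.5, then 0.8 after iteration 250). Deterministic given
#' `seed`; the final Kullback-Leibler divergence is reported.
#'
#' @param pop A `diet_population` (or data frame).
#' @param features Feature columns (default [reduction_features()]).
#' @param perplexity Effective neighbourhood size (default 30; requires
#'   n > 3 x perplexity).
#' @param learning_rate Gradient step size (default 200).
#' @param iterations Gradient iterations (default 1000).
#' @param seed Seed for the random initialization.
#' @return An `embedding_result` list: `coords` (n x 2), `final_kl`,
#'   `params`.
#' @export
run_tsne <- function(pop, features = reduction_features(), perplexity = 30,
                     learning_rate = 200, iterations = 1000, seed = 42) {
  x <- feature_matrix(pop, features)
  n <- nrow(x)
  if (n <= 3 * perplexity) {
    stop("n must exceed 3 x perplexity (n = ", n, ", perplexity = ",
         perplexity, ")", call. = FALSE)
  }
  z <- scale(x)
  d2 <- as.matrix(stats::dist(z))^2
  target_entropy <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p[i, -i] <- tsne_p_row(d2[i, -i], target_entropy)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  exaggeration <- 4
  exag_iter <- 100
  y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  vel <- matrix(0, n, 2)
  kl <- NA_real_
  for (it in seq_len(iterations)) {
    pe <- if (it <= exag_iter) p * exaggeration else p
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    w <- (pe - q) * num
    grad <- 4 * (diag(rowSums(w)) - w) %*% y
    momentum <- if (it < 250) 0.5 else 0.8
    vel <- momentum * vel - learning_rate * grad
    y <- y + vel
    y <- sweep(y, 2, colMeans(y))
    if (it == iterations) kl <- sum(p * log(p / q))
  }
  structure(list(coords = y, final_kl = kl,
                 params = list(perplexity = perplexity,
                               learning_rate = learning_rate,
                               iterations = iterations,
                               seed = as.integer(seed))),
            class = "embedding_result")
}

# Shoelace polygon area for points in hull order.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Convex-hull areas and pairwise overlaps of a labelled embedding
#'
#' For each label, the convex hull area of its points; for each ordered
#' label pair (i, j), the fraction of hull i's area lying inside hull j,
#' estimated by seeded Monte-Carlo rejection sampling with point-in-polygon
#' tests. Degenerate (collinear) label sets get area 0 and overlap 0.
#'
#' @param coords n x 2 coordinate matrix.
#' @param labels Label vector (>= 3 points per label).
#' @param n_mc Monte-Carlo samples per hull (default 20000).
#' @param seed Sampling seed.
#' @return List with `areas` (named numeric) and `overlap` (matrix;
#'   `overlap[i, j]` = fraction of hull i inside hull j).
#' @export
convex_hull_summary <- function(coords, labels, n_mc = 20000, seed = 1) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (any(table(labels) < 3)) stop("need >= 3 points per label",
                                   call. = FALSE)
  hulls <- lapply(lv, function(l) {
    pts <- coords[labels == l, , drop = FALSE]
    pts[grDevices::chull(pts), , drop = FALSE]
  })
  names(hulls) <- lv
  areas <- vapply(hulls, function(h) {
    if (nrow(h) < 3) 0 else polygon_area(h)
  }, numeric(1))
  overlap <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  diag(overlap) <- ifelse(areas > 0, 1, 0)
  with_seed(seed, {
    for (i in seq_along(lv)) {
      if (areas[i] == 0) next
      h <- hulls[[i]]
      # uniform samples inside hull i by bounding-box rejection
      bb <- apply(h, 2, range)
      samp <- matrix(numeric(0), 0, 2)
      while (nrow(samp) < n_mc) {
        cand <- cbind(stats::runif(n_mc, bb[1, 1], bb[2, 1]),
                      stats::runif(n_mc, bb[1, 2], bb[2, 2]))
        inside <- mgcv::in.out(rbind(h, h[1, ]), cand)
        samp <- rbind(samp, cand[inside, , drop = FALSE])
      }
      samp <- samp[seq_len(n_mc), , drop = FALSE]
      for (j in seq_along(lv)) {
        if (j == i || areas[j] == 0) next
        hj <- hulls[[j]]
        overlap[i, j] <- mean(mgcv::in.out(rbind(hj, hj[1, ]), samp))
      }
    }
  })
  list(areas = areas, overlap = overlap)
}
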