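# Internal numeric and RNG helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside package
#' functions do not perturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
#' @examples
#' with_seed(1, runif(2))
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed for a named stage
#'
#' One global seed fans out to per-stage seeds so that pipeline stages can be
#' re-run independently while staying reproducible. The derivation hashes the
#' stage name into a 31-bit integer.
#'
#' @param seed Integer parent seed.
#' @param stage Character stage name.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629 + 1)
}

#' Truncated-normal sampler
#'
#' Exact inverse-CDF sampling from a normal distribution truncated to
#' `[lower, upper]`.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the underlying normal.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' summary(rtruncnorm(100, 0, 1, lower = 0))
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Moment-matched truncated-normal sampler
#'
#' Draws from a normal truncated to `[lower, upper]` whose *post-truncation*
#' mean and SD equal the requested values (the underlying location and scale
#' are solved numerically). Useful when published moments describe the
#' truncated population itself.
#'
#' @inheritParams rtruncnorm
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- with_seed(1, rtruncnorm_matched(5000, 24, 12.1, lower = 0))
#' c(mean(x), sd(x))
rtruncnorm_matched <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  obj <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    m <- truncnorm_mean(mu, sig, lower, upper)
    v <- truncnorm_var(mu, sig, lower, upper)
    (m - mean)^2 / sd^2 + (sqrt(v) - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(maxit = 5000, reltol = 1e-14))
  rtruncnorm(n, fit$par[1], exp(fit$par[2]), lower, upper)
}

# Mean of a normal truncated to [lower, upper].
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Variance of a normal truncated to [lower, upper].
truncnorm_var <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  ta <- if (is.finite(a)) a * da else 0
  tb <- if (is.finite(b)) b * db else 0
  sd^2 * (1 + (ta - tb) / z - ((da - db) / z)^2)
}

# Solve for the underlying location of a truncated normal whose *truncated*
# mean equals `target`, holding sd and bounds fixed.
truncnorm_location_for_mean <- function(target, sd, lower, upper) {
  stats::uniroot(
    function(mu) truncnorm_mean(mu, sd, lower, upper) - target,
    interval = c(target - 4 * sd, target + 4 * sd), tol = 1e-10
  )$root
}

# Dirichlet sampler: n draws from Dirichlet(alpha), returned as n x k matrix.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
              nrow = n, ncol = k)
  sums <- rowSums(g)
  zero <- sums == 0
  if (any(zero)) { # numerically possible only for tiny alpha
    g[zero, ] <- rep(alpha / sum(alpha), each = sum(zero))
    sums[zero] <- 1
  }
  g / sums
}

# Stable hash of an arbitrary R object (md5 of its version-2 serialization).
config_hash <- function(object) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, "wb")
  serialize(object, con, version = 2)
  close(con)
  unname(tools::md5sum(tf))
}

# Half-away-from-zero rounding (base round() is round-half-even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
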