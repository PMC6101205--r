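#' Simulation scenario
#'
#' Bundles a model specification, true parameters (with the rank-`d`
#' constrained block stored as corner-form factors) and a per-column
#' predictor law, so that estimator and inference claims can be exercised
#' on synthetic data of any size.
#'
#' @param spec An [rr_spec()].
#' @param true_params An [rr_params()] whose `beta1` has rank exactly
#'   `spec$d`.
#' @param predictor_law A list of length `p` (original column order); each
#'   element is a list with `type` one of `"binary"` (field `prob`),
#'   `"normal"` (fields `mean`, `sd`) or `"uniform"` (fields `min`, `max`).
#' @param n Default sample size.
#' @param seed Default seed.
#' @return An object of class `rr_scenario`.
#' @export
rr_scenario <- function(spec, true_params, predictor_law, n, seed = NULL) {
  stopifnot(inherits(spec, "rr_spec"), inherits(true_params, "rr_params"))
  if (length(predictor_law) != spec$p) {
    stop("`predictor_law` must have one entry per predictor.", call. = FALSE)
  }
  if (spec$r > 0L) {
    rk <- qr(true_params$beta1)$rank
    if (rk != spec$d) {
      stop("true `beta1` must have rank exactly d = ", spec$d,
        " (got ", rk, ").",
        call. = FALSE
      )
    }
    if (is.null(true_params$C)) {
      fc <- factorize_corner(true_params$beta1, spec$d)
      true_params$C <- fc$C
      true_params$B <- fc$B
    }
  }
  structure(
    list(
      spec = spec, true_params = true_params,
      predictor_law = predictor_law, n = as.integer(n), seed = seed
    ),
    class = "rr_scenario"
  )
}

#' @export
print.rr_scenario <- function(x, ...) {
  cat("<rr_scenario> ", x$spec$family$name, ", n = ", x$n,
    ", p = ", x$spec$p, " (r = ", x$spec$r, ", d = ", x$spec$d, ")\n",
    sep = ""
  )
  invisible(x)
}

draw_predictors <- function(predictor_law, n) {
  cols <- lapply(predictor_law, function(law) {
    switch(law$type,
      binary = stats::rbinom(n, 1L, law$prob),
      normal = stats::rnorm(n, law$mean, law$sd),
      uniform = stats::runif(n, law$min, law$max),
      stop("unknown predictor law type ", sQuote(law$type), call. = FALSE)
    )
  })
  X <- do.call(cbind, cols)
  storage.mode(X) <- "double"
  X
}

# Vectorized conditional sampler given an n x k matrix of natural params.
sample_conditional <- function(fam, eta) {
  n <- nrow(eta)
  switch(fam$name,
    multinomial = {
      P <- cbind(mean_rows(fam, eta), 0)
      P[, fam$q] <- pmax(1 - rowSums(P), 0)
      u <- stats::runif(n)
      cum <- t(apply(P, 1L, cumsum))
      as.integer(1L + rowSums(u > cum[, -fam$q, drop = FALSE]))
    },
    poisson = {
      lam <- exp(eta)
      matrix(stats::rpois(n * fam$q, lam), n, fam$q)
    },
    gaussian = {
      if (fam$k2 == 0L) {
        mu <- fam$sigma^2 * eta
        mu + matrix(stats::rnorm(n * fam$q, sd = fam$sigma), n, fam$q)
      } else {
        s2 <- -1 / (2 * eta[, fam$k])
        mu <- eta[, seq_len(fam$q), drop = FALSE] * s2
        mu + matrix(stats::rnorm(n * fam$q), n, fam$q) * sqrt(s2)
      }
    }
  )
}

#' Simulate a dataset from a scenario
#'
#' Draws `n` i.i.d. predictor rows from the scenario's predictor law and,
#' for each row, a response from the family at
#' \eqn{\eta_x = (\bar\eta_1 + \beta_1 x_1 + \beta_2 x_2, \bar\eta_2)}.
#' Reproducible given `seed`.
#'
#' @param scenario An [rr_scenario()].
#' @param n Sample size (defaults to the scenario's).
#' @param seed Seed (defaults to the scenario's).
#' @return A list with `X` (`n x p` matrix, original column order, named
#'   columns), `Y` (labels or matrix) and `data` (a tibble with the
#'   response in column `y` or columns `y1..yq`, then the predictors).
#' @export
simulate_dataset <- function(scenario, n = scenario$n, seed = scenario$seed) {
  spec <- scenario$spec
  fam <- spec$family
  if (!is.null(seed)) set.seed(seed)
  X <- draw_predictors(scenario$predictor_law, n)
  colnames(X) <- spec$x_names
  Xr <- spec_reorder_x(X, spec)
  eta <- eta_rows(scenario$true_params, Xr, spec)
  bad <- which(!in_domain_rows(fam, eta))
  if (length(bad) > 0L) {
    stop("true parameters give eta outside H at simulated row ", bad[1L],
      "; check `true_params` (e.g. the variance coordinate).",
      call. = FALSE
    )
  }
  Y <- sample_conditional(fam, eta)
  ydf <- if (is.matrix(Y)) {
    colnames(Y) <- paste0("y", seq_len(ncol(Y)))
    tibble::as_tibble(Y)
  } else {
    tibble::tibble(y = Y)
  }
  list(X = X, Y = Y, data = dplyr::bind_cols(ydf, tibble::as_tibble(X)))
}

#' Workforce-style multinomial scenario
#'
#' A synthetic look-alike of a marital-status classification design: a
#' 4-category multinomial response (reference category most frequent),
#' twelve independent binary lifestyle/psychological predictors with
#' moderate prevalences forming the rank-constrained block, and two
#' continuous unconstrained covariates (a centred age-like variable and a
#' log-education-like variable). The true constrained coefficient matrix is
#' rank 1, \eqn{\beta_1 = C B} in corner form, with entry magnitudes of
#' order 0 to 1.1; the third log-odds row is roughly twice the first. The
#' specification has `k1 = 3`, `p = 14`, `r = 12`, `d = 1`, giving 45
#' unrestricted and 24 restricted parameters.
#'
#' @param n Sample size (default 4105).
#' @param seed Optional seed stored in the scenario.
#' @return An [rr_scenario()].
#' @export
workforce_scenario <- function(n = 4105, seed = NULL) {
  fam <- rr_family("multinomial", q = 4)
  x_names <- c(
    "binge", "smokenow", "sun", "nerves", "nervous", "hurt",
    "tense", "miserable", "fedup", "worry", "worrier", "mood",
    "age30", "logedu1"
  )
  spec <- rr_spec(fam, p = 14, constrained = 1:12, d = 1, x_names = x_names)
  # rank-1 constrained block in corner form: first row is B, C = (1, c2, c3)
  B <- matrix(c(
    0.55, 0.50, 0.45, -0.50, 0.52, 0.48,
    0.50, 0.45, 0.48, 0.42, -0.50, -0.45
  ), nrow = 1)
  C <- matrix(c(1, 1.38, 1.95), ncol = 1)
  beta2 <- matrix(c(
    -0.191, 0.012, 0.086, # age-like
    0.338, -0.365, -0.089 # log-education-like
  ), nrow = 3)
  eta_bar1 <- c(-1.5, -2.0, -2.6)
  params <- rr_params(eta_bar1, C %*% B, beta2, C = C, B = B)
  prev <- c(
    0.25, 0.35, 0.30, 0.25, 0.25, 0.40,
    0.25, 0.30, 0.35, 0.40, 0.40, 0.35
  )
  law <- c(
    lapply(prev, function(p) list(type = "binary", prob = p)),
    list(
      list(type = "normal", mean = 8, sd = 10),
      list(type = "uniform", min = 0, max = 1.8)
    )
  )
  rr_scenario(spec, params, law, n = n, seed = seed)
}
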