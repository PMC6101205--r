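#' Canonical exponential families
#'
#' Constructs a canonical exponential family with density
#' \eqn{f_\eta(y) = \exp\{\eta^\top T(y) - \psi(\eta)\} h(y)}, where
#' \eqn{T(y)} is the sufficient statistic, \eqn{\eta} the natural parameter
#' and \eqn{\psi} the cumulant (log-normalizer). The natural parameter is
#' split into a block of dimension `k1` that is modelled as a linear function
#' of predictors and a block of dimension `k2` that is free of them
#' (`k = k1 + k2`).
#'
#' Supported families:
#' \describe{
#'   \item{`"multinomial"`}{A single draw over `q` categories. The last
#'     category is the reference; \eqn{\eta_i = \log(p_i/p_q)} for
#'     \eqn{i = 1, \dots, q-1}, so `k1 = q - 1`, `k2 = 0`,
#'     \eqn{T(y)} the indicators of the first `q - 1` categories, and
#'     \eqn{\psi(\eta) = \log(1 + \sum_i e^{\eta_i})} (the softmax
#'     normalizer, computed with a max-shift for overflow safety).}
#'   \item{`"poisson"`}{`q` independent Poisson counts with log link:
#'     \eqn{T(y) = y}, \eqn{\psi(\eta) = \sum_j e^{\eta_j}}, `k1 = q`,
#'     `k2 = 0`.}
#'   \item{`"gaussian"`}{A `q`-variate normal with identity link and
#'     isotropic variance. With `sigma` supplied the variance is known and
#'     `k1 = q`, `k2 = 0`, \eqn{T(y) = y},
#'     \eqn{\psi(\eta) = \sigma^2 \|\eta\|^2/2}. With `sigma = NULL` the
#'     variance is a free natural parameter: `k1 = q`, `k2 = 1`,
#'     \eqn{T(y) = (y, \|y\|^2)} with \eqn{\eta_2 = -1/(2\sigma^2) < 0} and
#'     \eqn{\psi(\eta) = -\|\eta_1\|^2/(4\eta_2) + (q/2)\log(-\pi/\eta_2)}.}
#' }
#'
#' @param name One of `"multinomial"`, `"poisson"`, `"gaussian"`.
#' @param q Response dimension (number of categories for the multinomial).
#' @param sigma For the Gaussian family only: a known standard deviation.
#'   `NULL` (default) treats the variance as a free natural parameter.
#' @return An object of class `rr_family` with elements `name`, `q`, `k`,
#'   `k1`, `k2` and (for the fixed-variance Gaussian) `sigma`.
#' @examples
#' fam <- rr_family("multinomial", q = 4)
#' psi(fam, c(0, 0, 0)) # log(4)
#' grad_psi(fam, c(0, 0, 0)) # rep(1/4, 3)
#' @export
rr_family <- function(name = c("multinomial", "poisson", "gaussian"),
                      q, sigma = NULL) {
  name <- match.arg(name)
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != round(q)) {
    stop("`q` must be a positive integer.", call. = FALSE)
  }
  q <- as.integer(q)
  fam <- switch(name,
    multinomial = {
      if (q < 2) stop("multinomial family needs q >= 2 categories.", call. = FALSE)
      list(name = name, q = q, k1 = q - 1L, k2 = 0L)
    },
    poisson = list(name = name, q = q, k1 = q, k2 = 0L),
    gaussian = {
      if (!is.null(sigma)) {
        if (!is.numeric(sigma) || sigma <= 0) {
          stop("`sigma` must be a positive number.", call. = FALSE)
        }
        list(name = name, q = q, k1 = q, k2 = 0L, sigma = sigma)
      } else {
        list(name = name, q = q, k1 = q, k2 = 1L)
      }
    }
  )
  fam$k <- fam$k1 + fam$k2
  class(fam) <- c(paste0("rr_family_", name), "rr_family")
  fam
}

#' @export
print.rr_family <- function(x, ...) {
  cat("<rr_family> ", x$name, " (q = ", x$q, ", k1 = ", x$k1,
    ", k2 = ", x$k2, ")\n",
    sep = ""
  )
  invisible(x)
}

check_eta <- function(family, eta) {
  if (!is.numeric(eta) || length(eta) != family$k) {
    stop("`eta` must be a numeric vector of length k = ", family$k, ".",
      call. = FALSE
    )
  }
  if (anyNA(eta) || any(!is.finite(eta))) {
    stop("`eta` must be finite.", call. = FALSE)
  }
  if (!all(in_domain_rows(family, matrix(eta, nrow = 1)))) {
    stop("`eta` lies outside the natural-parameter domain H: ",
      domain_message(family),
      call. = FALSE
    )
  }
  invisible(eta)
}

domain_message <- function(family) {
  if (family$name == "gaussian" && family$k2 > 0L) {
    "the variance coordinate eta[k] must be strictly negative."
  } else {
    "all coordinates must be finite."
  }
}

# Row-wise domain predicate for an n x k matrix of natural parameters.
in_domain_rows <- function(family, eta) {
  ok <- rowSums(!is.finite(eta)) == 0
  if (family$name == "gaussian" && family$k2 > 0L) {
    ok & eta[, family$k] < 0
  } else {
    ok
  }
}

# Vectorized cumulant over rows of an n x k matrix.
psi_rows <- function(family, eta) {
  UseMethod("psi_rows")
}

#' @export
psi_rows.rr_family_multinomial <- function(family, eta) {
  # log(1 + sum exp(eta)) with max-shift
  m <- pmax(apply(eta, 1L, max), 0)
  m + log(exp(-m) + rowSums(exp(eta - m)))
}

#' @export
psi_rows.rr_family_poisson <- function(family, eta) {
  rowSums(exp(eta))
}

#' @export
psi_rows.rr_family_gaussian <- function(family, eta) {
  q <- family$q
  if (family$k2 == 0L) {
    0.5 * family$sigma^2 * rowSums(eta^2)
  } else {
    e1 <- eta[, seq_len(q), drop = FALSE]
    e2 <- eta[, q + 1L]
    -rowSums(e1^2) / (4 * e2) + (q / 2) * log(-pi / e2)
  }
}

# Vectorized mean of T(Y): n x k matrix.
mean_rows <- function(family, eta) {
  UseMethod("mean_rows")
}

#' @export
mean_rows.rr_family_multinomial <- function(family, eta) {
  exp(eta - psi_rows(family, eta))
}

#' @export
mean_rows.rr_family_poisson <- function(family, eta) {
  exp(eta)
}

#' @export
mean_rows.rr_family_gaussian <- function(family, eta) {
  q <- family$q
  if (family$k2 == 0L) {
    family$sigma^2 * eta
  } else {
    e1 <- eta[, seq_len(q), drop = FALSE]
    e2 <- eta[, q + 1L]
    mu <- -e1 / (2 * e2)
    cbind(mu, rowSums(mu^2) - q / (2 * e2))
  }
}

# Per-row variance of T(Y): array of dim (n, k, k).
hess_rows <- function(family, eta) {
  UseMethod("hess_rows")
}

#' @export
hess_rows.rr_family_multinomial <- function(family, eta) {
  n <- nrow(eta)
  k <- family$k1
  p <- mean_rows(family, eta)
  H <- array(0, c(n, k, k))
  for (s in seq_len(k)) {
    for (t in seq_len(k)) {
      H[, s, t] <- -p[, s] * p[, t] + if (s == t) p[, s] else 0
    }
  }
  H
}

#' @export
hess_rows.rr_family_poisson <- function(family, eta) {
  n <- nrow(eta)
  k <- family$k
  H <- array(0, c(n, k, k))
  lam <- exp(eta)
  for (s in seq_len(k)) H[, s, s] <- lam[, s]
  H
}

#' @export
hess_rows.rr_family_gaussian <- function(family, eta) {
  n <- nrow(eta)
  q <- family$q
  if (family$k2 == 0L) {
    H <- array(0, c(n, q, q))
    for (s in seq_len(q)) H[, s, s] <- family$sigma^2
    return(H)
  }
  k <- q + 1L
  e1 <- eta[, seq_len(q), drop = FALSE]
  e2 <- eta[, k]
  s2 <- -1 / (2 * e2)
  mu <- e1 * s2
  H <- array(0, c(n, k, k))
  for (s in seq_len(q)) {
    H[, s, s] <- s2
    H[, s, k] <- H[, k, s] <- 2 * s2 * mu[, s]
  }
  H[, k, k] <- 4 * s2 * rowSums(mu^2) + 2 * q * s2^2
  H
}

# Map raw responses to the n x k sufficient-statistic matrix.
suff_stat <- function(family, Y) {
  UseMethod("suff_stat")
}

#' @export
suff_stat.rr_family_multinomial <- function(family, Y) {
  q <- family$q
  if (is.matrix(Y) || is.data.frame(Y)) {
    Y <- as.matrix(Y)
    if (ncol(Y) == q) {
      # indicator matrix over all q categories
      return(Y[, seq_len(q - 1L), drop = FALSE])
    }
    if (ncol(Y) == q - 1L) {
      return(Y)
    }
    if (ncol(Y) == 1L) Y <- drop(Y)
  }
  lab <- as.integer(Y)
  if (anyNA(lab) || any(lab < 1L | lab > q)) {
    bad <- which(is.na(lab) | lab < 1L | lab > q)[1L]
    stop("multinomial labels must lie in 1..", q, "; offending row ", bad, ".",
      call. = FALSE
    )
  }
  Tm <- matrix(0, length(lab), q - 1L)
  keep <- lab < q
  Tm[cbind(which(keep), lab[keep])] <- 1
  Tm
}

#' @export
suff_stat.rr_family_poisson <- function(family, Y) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == family$q)
  Y
}

#' @export
suff_stat.rr_family_gaussian <- function(family, Y) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == family$q)
  if (family$k2 == 0L) Y else cbind(Y, rowSums(Y^2))
}

#' Cumulant function, mean and variance of the sufficient statistic
#'
#' `psi()` evaluates the log-normalizer \eqn{\psi(\eta)} of a canonical
#' exponential family at a single natural-parameter vector. `grad_psi()`
#' returns its gradient, which equals \eqn{E_\eta[T(Y)]}, and `hess_psi()`
#' its Hessian, which equals \eqn{\mathrm{var}_\eta[T(Y)]} and is symmetric
#' positive definite everywhere on the natural-parameter domain.
#'
#' @param family An [rr_family()] object.
#' @param eta Numeric vector of length `family$k`.
#' @return `psi()` a scalar; `grad_psi()` a length-`k` vector; `hess_psi()`
#'   a `k x k` symmetric positive definite matrix.
#' @examples
#' fam <- rr_family("poisson", q = 1)
#' psi(fam, 0) # exp(0) = 1
#' @export
psi <- function(family, eta) {
  check_eta(family, eta)
  psi_rows(family, matrix(eta, nrow = 1L))[1L]
}

#' @rdname psi
#' @export
grad_psi <- function(family, eta) {
  check_eta(family, eta)
  drop(mean_rows(family, matrix(eta, nrow = 1L)))
}

#' @rdname psi
#' @export
hess_psi <- function(family, eta) {
  check_eta(family, eta)
  H <- hess_rows(family, matrix(eta, nrow = 1L))
  matrix(H[1L, , ], family$k, family$k)
}

#' Draw i.i.d. responses from an exponential family
#'
#' Samples `n` independent responses from the family density at natural
#' parameter `eta`. Multinomial responses are returned as integer category
#' labels in `1..q`; Poisson and Gaussian responses as an `n x q` matrix.
#'
#' @inheritParams psi
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector (multinomial) or numeric matrix (other families).
#' @export
sample_response <- function(family, eta, n, seed = NULL) {
  check_eta(family, eta)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer.", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  switch(family$name,
    multinomial = {
      p_head <- exp(eta - psi(family, eta))
      probs <- c(p_head, 1 - sum(p_head))
      sample.int(family$q, size = n, replace = TRUE, prob = probs)
    },
    poisson = {
      matrix(stats::rpois(n * family$q, rep(exp(eta), each = n)), n, family$q)
    },
    gaussian = {
      if (family$k2 == 0L) {
        mu <- family$sigma^2 * eta
        sd <- family$sigma
      } else {
        s2 <- -1 / (2 * eta[family$k])
        mu <- eta[seq_len(family$q)] * s2
        sd <- sqrt(s2)
      }
      matrix(stats::rnorm(n * family$q, mean = rep(mu, each = n), sd = sd),
        n, family$q
      )
    }
  )
}
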