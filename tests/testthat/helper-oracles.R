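# Independent oracles and small fixture builders used across the suite.

# All outcomes of a single multinomial draw with q categories, as
# sufficient-statistic vectors (indicators of the first q - 1 categories).
multinom_outcomes <- function(q) {
  lapply(seq_len(q), function(i) {
    v <- numeric(q - 1L)
    if (i < q) v[i] <- 1
    v
  })
}

# Brute-force normalizer, mean and variance of T for the multinomial,
# by direct summation over the q outcomes.
multinom_enum <- function(eta) {
  q <- length(eta) + 1L
  outs <- multinom_outcomes(q)
  w <- vapply(outs, function(t) exp(sum(eta * t)), numeric(1))
  Z <- sum(w)
  p <- w / Z
  m <- Reduce(`+`, Map(`*`, outs, p))
  V <- Reduce(`+`, Map(function(t, pi) pi * tcrossprod(t - m), outs, p))
  list(logZ = log(Z), mean = m, var = V)
}

# Central finite differences of a scalar- or vector-valued function.
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(length(f(x))))
}

# Random parameters consistent with a spec (Gaussian free-variance block
# gets a negative coordinate).
random_params <- function(spec, scale = 0.5) {
  fam <- spec$family
  k1 <- fam$k1
  rr_params(
    eta_bar1 = stats::rnorm(k1, sd = scale),
    beta1 = matrix(stats::rnorm(k1 * spec$r, sd = scale), k1, spec$r),
    beta2 = matrix(stats::rnorm(k1 * (spec$p - spec$r), sd = scale), k1,
      spec$p - spec$r
    ),
    eta_bar2 = if (fam$k2 > 0L) -abs(stats::rnorm(fam$k2, 1, 0.2))
  )
}

# Small Gaussian unit-variance reduced-rank instance for estimator tests.
gaussian_instance <- function(n = 200, p = 6, q = 4, d = 2) {
  X <- matrix(stats::rnorm(n * p), n, p)
  bt <- matrix(stats::rnorm(q * d), q, d) %*% matrix(stats::rnorm(d * p), d, p)
  Y <- X %*% t(bt) + matrix(stats::rnorm(n * q), n, q)
  list(
    X = X, Y = Y, beta = bt,
    spec = rr_spec(rr_family("gaussian", q = q, sigma = 1),
      p = p, constrained = seq_len(p), d = d
    )
  )
}
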