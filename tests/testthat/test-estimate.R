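test_that("mean log-likelihood matches hand values and density oracles", {
  fam <- rr_family("multinomial", q = 4)
  spec <- rr_spec(fam, p = 1, constrained = NULL)
  params <- rr_params(c(0, 0, 0), matrix(0, 3, 0), matrix(0, 3, 1))
  expect_equal(
    rr_loglik(params, matrix(1.7, 1, 1), 2L, spec),
    -log(4)
  )

  # Gaussian unit variance: equals the log-density average up to the
  # carrier constant -q/2 log(2*pi) - |y|^2/2 absorbed in h(y)
  set.seed(3)
  famg <- rr_family("gaussian", q = 2, sigma = 1)
  specg <- rr_spec(famg, p = 2, constrained = NULL)
  X <- matrix(stats::rnorm(20), 10, 2)
  bt <- matrix(c(0.5, -0.3, 0.2, 0.1), 2, 2)
  Y <- X %*% t(bt) + matrix(stats::rnorm(20), 10, 2)
  pg <- rr_params(c(0, 0), matrix(0, 2, 0), bt)
  mu <- X %*% t(bt)
  dens <- mean(rowSums(stats::dnorm(Y, mean = mu, log = TRUE)))
  carrier <- mean(-rowSums(Y^2) / 2) - log(2 * pi)
  expect_equal(rr_loglik(pg, X, Y, specg), dens - carrier, tolerance = 1e-12)
})

test_that("full-rank Gaussian MLE equals row-wise least squares", {
  set.seed(4)
  n <- 120
  X <- matrix(stats::rnorm(n * 3), n, 3)
  bt <- matrix(stats::rnorm(6), 2, 3)
  Y <- X %*% t(bt) + matrix(stats::rnorm(n * 2), n, 2)
  fam <- rr_family("gaussian", q = 2, sigma = 1)
  spec <- rr_spec(fam, p = 3, constrained = NULL)
  ft <- fit_full(X, Y, spec)
  ls <- stats::lm(Y ~ X)
  expect_equal(ft$params$eta_bar1, unname(coef(ls)[1, ]), tolerance = 1e-8)
  expect_equal(
    unname(ft$params$beta2), unname(t(coef(ls)[-1, ])),
    tolerance = 1e-8
  )
  expect_true(ft$converged)
})

test_that("intercept-only multinomial MLE is the log frequency ratio", {
  fam <- rr_family("multinomial", q = 3)
  spec <- rr_spec(fam, p = 0)
  y <- rep(c(1L, 2L, 3L), times = c(20, 30, 50))
  ft <- fit_full(matrix(0, 100, 0), y, spec)
  expect_equal(ft$params$eta_bar1, log(c(20, 30, 50) / 50)[1:2],
    tolerance = 1e-6
  )
  # MLE log-likelihood dominates any other parameter value
  other <- rr_params(c(0.1, -0.2), matrix(0, 2, 0), matrix(0, 2, 0))
  expect_gte(ft$loglik, rr_loglik(other, matrix(0, 100, 0), y, spec))
})

test_that("full-rank estimates contract toward truth at the root-n rate", {
  sc <- workforce_scenario()
  xi0 <- pack_params(sc$true_params)
  errs <- vapply(c(500, 2000, 8000), function(n) {
    ds <- simulate_dataset(sc, n = n, seed = 100 + n)
    ft <- suppressWarnings(fit_full(ds$X, ds$Y, sc$spec))
    sqrt(sum((ft$xi - xi0)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # a 16-fold n increase should shrink the error by clearly more than half
  expect_lt(errs[3], 0.5 * errs[1])
})

test_that("reduced Gaussian fit matches the truncated-SVD closed form", {
  set.seed(5)
  for (rep in 1:3) {
    inst <- gaussian_instance(n = 200, p = 6, q = 4, d = 2)
    fr <- fit_reduced(inst$X, inst$Y, inst$spec)
    oracle <- gaussian_rrr(
      scale(inst$X, scale = FALSE), scale(inst$Y, scale = FALSE), 2
    )
    expect_lt(norm(fr$params$beta1 - oracle, "F"), 1e-6)
    expect_true(all(diff(fr$loglik_trace) >= -1e-10))
  }
})

test_that("vacuous rank bound reproduces the full-rank fit", {
  set.seed(6)
  inst <- gaussian_instance(n = 150, p = 5, q = 3, d = 3) # d = k1
  fr <- fit_reduced(inst$X, inst$Y, inst$spec)
  ff <- fit_full(inst$X, inst$Y, inst$spec)
  expect_lt(max(abs(fr$xi - ff$xi)), 1e-6)
})

test_that("reduced fit recovers a rank-1 multinomial coefficient block", {
  sc <- workforce_scenario()
  # recovery accuracy is a property of the estimator's distribution, so
  # assert it on the mean over replicates rather than on a single draw
  rels <- vapply(21:23, function(s) {
    ds <- simulate_dataset(sc, n = 8000, seed = s)
    fr <- fit_reduced(ds$X, ds$Y, sc$spec)
    expect_true(fr$converged)
    expect_true(all(diff(fr$loglik_trace) >= -1e-10))
    expect_equal(qr(fr$params$beta1)$rank, 1L)
    norm(fr$params$beta1 - sc$true_params$beta1, "F") /
      norm(sc$true_params$beta1, "F")
  }, numeric(1))
  expect_lt(mean(rels), 0.10)
})

test_that("log-likelihoods nest: full >= reduced >= intercept-only", {
  sc <- workforce_scenario()
  ds <- simulate_dataset(sc, n = 1500, seed = 30)
  ff <- fit_full(ds$X, ds$Y, sc$spec)
  fr <- fit_reduced(ds$X, ds$Y, sc$spec, init = list(fit = ff))
  spec0 <- rr_spec(sc$spec$family, p = 0)
  f0 <- fit_full(matrix(0, nrow(ds$X), 0), ds$Y, spec0)
  expect_gte(ff$loglik, fr$loglik - 1e-10)
  expect_gte(fr$loglik, f0$loglik - 1e-10)
})

test_that("the fitted beta1 is invariant to the factor gauge", {
  sc <- workforce_scenario()
  ds <- simulate_dataset(sc, n = 1200, seed = 40)
  fr <- fit_reduced(ds$X, ds$Y, sc$spec)
  M <- matrix(2.5, 1, 1)
  fr2 <- fit_reduced(ds$X, ds$Y, sc$spec,
    init = list(C = fr$params$C %*% M, B = solve(M) %*% fr$params$B, fit = fr)
  )
  expect_lt(
    max(abs(fr2$params$beta1 - fr$params$beta1)), 1e-6
  )
})

test_that("corner factorization reconstructs and pivots correctly", {
  # already in corner form
  C <- rbind(diag(2), c(0.5, -1))
  B <- matrix(c(1, 0, 2, 1, -1, 3), 2, 3)
  fc <- factorize_corner(C %*% B, 2)
  expect_equal(fc$C %*% fc$B, C %*% B, tolerance = 1e-12)
  expect_equal(fc$rows, c(1L, 2L))
  expect_equal(fc$C[fc$rows, ], diag(2))

  # zero first row forces pivoting
  beta1 <- rbind(c(0, 0, 0), c(1, 2, 3), c(2, 4, 6.5))
  fc2 <- factorize_corner(beta1, 2)
  expect_false(1L %in% fc2$rows)
  expect_equal(fc2$C %*% fc2$B, beta1, tolerance = 1e-10)
  expect_equal(fc2$C[fc2$perm, ][1:2, ], diag(2))

  # random rank-d reconstruction
  set.seed(8)
  for (rep in 1:10) {
    b <- matrix(stats::rnorm(12), 4, 3) %*% matrix(stats::rnorm(15), 3, 5)
    fc3 <- factorize_corner(b, 3)
    expect_lt(max(abs(fc3$C %*% fc3$B - b)), 1e-10)
  }
  expect_error(factorize_corner(matrix(1, 3, 3), 2), "rank")
})

test_that("gaussian_rrr is the exact rank-constrained least squares", {
  set.seed(9)
  n <- 60
  X <- matrix(stats::rnorm(n * 3), n, 3)
  B0 <- matrix(stats::rnorm(9), 3, 3)
  Y <- X %*% t(B0) + 0.3 * matrix(stats::rnorm(n * 3), n, 3)
  # no truncation returns OLS
  Bols <- t(solve(crossprod(X), crossprod(X, Y)))
  expect_equal(gaussian_rrr(X, Y, 3), Bols, tolerance = 1e-10)
  # Y = X: reduced-rank regression coincides with PCA of the identity fit
  Bpca <- gaussian_rrr(X, X, 1)
  v <- svd(X)$v[, 1]
  expect_equal(abs(sum(diag(Bpca))), 1, tolerance = 1e-8) # projector trace
  expect_equal(Bpca %*% v, v %*% t(v) %*% v, tolerance = 1e-8)
  # rank-1 solution beats random rank-1 competitors and local optimization
  B1 <- gaussian_rrr(X, Y, 1)
  sse <- function(Bm) sum((Y - X %*% t(Bm))^2)
  best <- sse(B1)
  for (rep in 1:25) {
    par0 <- stats::rnorm(6)
    o <- stats::optim(par0, function(p) {
      sse(matrix(p[1:3], 3, 1) %*% matrix(p[4:6], 1, 3))
    }, method = "BFGS", control = list(maxit = 500))
    expect_gte(o$value, best - 1e-6)
  }
})

test_that("degenerate designs and separation are reported, not hidden", {
  fam <- rr_family("multinomial", q = 3)
  spec <- rr_spec(fam, p = 2, constrained = 1:2, d = 1)
  X <- cbind(rep(1, 50), stats::rnorm(50))
  y <- rep(1:3, length.out = 50)
  expect_error(fit_full(X, y, spec), "constant")

  Xd <- cbind(stats::rnorm(60))
  yd <- rep(c(1L, 2L), each = 30)
  spec2 <- rr_spec(rr_family("multinomial", q = 3), p = 1, constrained = NULL)
  expect_error(fit_full(Xd, yd, spec2), "empty")

  # perfect separation: coefficient diverges and the fit says so
  xs <- rep(c(0, 1), each = 40)
  ys <- ifelse(xs == 1, 1L, 2L)
  spec3 <- rr_spec(rr_family("multinomial", q = 2), p = 1, constrained = NULL)
  Xs <- cbind(xs + c(stats::rnorm(80, sd = 1e-3)))
  expect_warning(
    fs <- fit_full(cbind(xs), ys, spec3),
    "diverged|converge"
  )
  expect_false(fs$converged)
})

test_that("rank bound above min(k1, r) is rejected", {
  fam <- rr_family("multinomial", q = 4)
  expect_error(rr_spec(fam, p = 6, constrained = 1:5, d = 4), "min")
})
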