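test_that("estimate_W matches the finite-difference Hessian of the loglik", {
  set.seed(10)
  sc <- workforce_scenario()
  spec <- rr_spec(sc$spec$family, p = 3, constrained = 1:2, d = 1)
  X <- cbind(stats::rbinom(400, 1, 0.4), stats::rbinom(400, 1, 0.3),
    stats::rnorm(400)
  )
  pars <- rr_params(
    c(-0.5, -0.8, -1), matrix(c(0.6, 0.3, 0.9, 0.4, 0.2, 0.6), 3, 2),
    matrix(c(0.2, -0.1, 0.3), 3, 1)
  )
  lawless <- rr_scenario(spec, pars,
    c(
      list(list(type = "binary", prob = 0.4), list(type = "binary", prob = 0.3)),
      list(list(type = "normal", mean = 0, sd = 1))
    ),
    n = 400, seed = 77
  )
  ds <- simulate_dataset(lawless)
  ft <- fit_full(ds$X, ds$Y, spec)
  W <- estimate_W(ds$X, ft$params, spec)
  # numeric Hessian of the mean log-likelihood at the optimum, inverted
  f <- function(xi) rr_loglik(unpack_params(xi, spec), ds$X, ds$Y, spec)
  Hn <- fd_grad(function(xi) fd_grad(f, xi, h = 1e-4), ft$xi, h = 1e-4)
  Hn <- (Hn + t(Hn)) / 2
  expect_equal(W, solve(-Hn), tolerance = 1e-3)
})

test_that("intercept-only W is the inverse family variance", {
  fam <- rr_family("multinomial", q = 4)
  spec <- rr_spec(fam, p = 0)
  pars <- rr_params(c(0, 0, 0), matrix(0, 3, 0), matrix(0, 3, 0))
  W <- estimate_W(matrix(0, 10, 0), pars, spec)
  expect_equal(W, solve(hess_psi(fam, c(0, 0, 0))), tolerance = 1e-10)
})

test_that("build_G is the differential of the factorization map", {
  fam <- rr_family("multinomial", q = 4)
  spec <- rr_spec(fam, p = 14, constrained = 1:12, d = 1)
  set.seed(11)
  C0 <- matrix(stats::rnorm(3), 3, 1)
  B0 <- matrix(stats::rnorm(12), 1, 12)
  G <- build_G(C0, B0, spec)
  expect_equal(dim(G), c(45L, 24L))
  for (rep in 1:5) {
    dC <- matrix(stats::rnorm(3), 3, 1)
    dB <- matrix(stats::rnorm(12), 1, 12)
    dtheta <- c(rep(0, 3), as.numeric(dC), as.numeric(dB), rep(0, 6))
    expect_equal(
      (G %*% dtheta)[3 + 1:36],
      as.numeric(dC %*% B0 + C0 %*% dB),
      tolerance = 1e-12
    )
  }
  expect_error(build_G(matrix(0, 3, 1), B0, spec), "rank")
})

test_that("oblique projection is idempotent, Sigma-self-adjoint, span-only", {
  set.seed(12)
  # square invertible G
  G <- matrix(stats::rnorm(16), 4, 4)
  S <- crossprod(matrix(stats::rnorm(40), 10, 4)) / 10 + diag(4)
  expect_equal(projection_oblique(G, S), diag(4), tolerance = 1e-8)
  # Euclidean case with orthonormal columns
  Q <- qr.Q(qr(matrix(stats::rnorm(10), 5, 2)))
  expect_equal(projection_oblique(Q, diag(5)), Q %*% t(Q), tolerance = 1e-10)
  # rank-deficient G gives the same projection as any same-span basis
  A <- matrix(stats::rnorm(18), 6, 3)
  Gdef <- A %*% cbind(diag(3), diag(3)) # rank 3, 6 columns
  S6 <- crossprod(matrix(stats::rnorm(120), 20, 6)) / 20 + diag(6)
  P1 <- projection_oblique(Gdef, S6)
  P2 <- projection_oblique(A, S6)
  expect_lt(max(abs(P1 - P2)), 1e-10)
  expect_error(projection_oblique(Gdef, -S6), "positive definite")
})

test_that("avar via pseudoinverse equals the full-rank corner-chart route", {
  fam <- rr_family("multinomial", q = 4)
  spec <- rr_spec(fam, p = 6, constrained = 1:5, d = 2)
  k1 <- 3
  d <- 2
  r <- 5
  set.seed(13)
  A0 <- matrix(stats::rnorm((k1 - d) * d), k1 - d, d)
  C0 <- rbind(diag(d), A0)
  B0 <- matrix(stats::rnorm(d * r), d, r)
  G <- build_G(C0, B0, spec)
  m <- count_parameters(spec) # = nrow(G)
  W <- crossprod(matrix(stats::rnorm(3 * m * m), 3 * m, m)) / (3 * m) + diag(m)
  av <- avar_reduced(W, G)$avar
  # corner chart: free coordinates (A, B); d vec(beta1) =
  # (B0' x I)(I_d x [0; I]) vecA + (I_r x C0) vecB  -- full column rank
  J <- rbind(matrix(0, d, k1 - d), diag(k1 - d))
  GA <- kronecker(t(B0), diag(k1)) %*% kronecker(diag(d), J)
  Gh <- cbind(
    G[, seq_len(k1), drop = FALSE],
    rbind(
      matrix(0, k1, (k1 - d) * d),
      GA,
      matrix(0, nrow(G) - k1 - k1 * r, (k1 - d) * d)
    ),
    G[, (k1 + k1 * d + 1):ncol(G), drop = FALSE]
  )
  expect_equal(qr(Gh)$rank, ncol(Gh)) # the chart gradient has full rank
  Winv <- solve(W)
  av_h <- Gh %*% solve(crossprod(Gh, Winv %*% Gh)) %*% t(Gh)
  expect_lt(max(abs(av - av_h)), 1e-8)
  # and the projection identity avar = Pi(W^{-1}) W
  Pi <- projection_oblique(G, Winv)
  expect_equal(av, Pi %*% W, tolerance = 1e-8)
})

test_that("avar is gauge-invariant and dominated by W", {
  fam <- rr_family("multinomial", q = 4)
  spec <- rr_spec(fam, p = 14, constrained = 1:12, d = 1)
  sc <- workforce_scenario()
  ds <- simulate_dataset(sc, n = 1500, seed = 55)
  fr <- fit_reduced(ds$X, ds$Y, spec)
  W <- estimate_W(ds$X, fr$params, spec)
  base <- avar_reduced(W, build_G(fr$params$C, fr$params$B, spec))$avar
  set.seed(14)
  for (rep in 1:5) {
    M <- matrix(stats::runif(1, 0.2, 3) * sample(c(-1, 1), 1), 1, 1)
    G2 <- build_G(fr$params$C %*% M, solve(M) %*% fr$params$B, spec)
    expect_lt(max(abs(avar_reduced(W, G2)$avar - base)), 1e-8)
  }
  ev <- eigen(W - base, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # rank(avar) equals rank(G): 24 raw factor coordinates minus the d^2 gauge
  G1 <- build_G(fr$params$C, fr$params$B, spec)
  expect_equal(qr(base)$rank, qr(G1)$rank)
  expect_equal(qr(base)$rank, 23L)
})

test_that("wald_table reports per-entry inference and handles edge cases", {
  sc <- workforce_scenario()
  ds <- simulate_dataset(sc, n = 2000, seed = 66)
  fr <- fit_reduced(ds$X, ds$Y, sc$spec)
  tab <- wald_table(fr)
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), 45L)
  expect_equal(sum(tab$term == "(Intercept)"), 3L)
  expect_setequal(
    unique(tab$response),
    c("log(p1/p4)", "log(p2/p4)", "log(p3/p4)")
  )
  # layout: each predictor appears once per contrast
  counts <- table(tab$term)
  expect_true(all(counts == 3L))
  # zero-variance coordinate: SE 0, degenerate CI at the estimate
  cov0 <- avar_reduced(
    estimate_W(ds$X, fr$params, sc$spec),
    build_G(fr$params$C, fr$params$B, sc$spec),
    n = fr$n
  )
  cov0$avar[4, ] <- 0
  cov0$avar[, 4] <- 0
  tab0 <- wald_table(fr, cov = cov0)
  expect_equal(tab0$std.error[4], 0)
  expect_equal(tab0$conf.low[4], tab0$estimate[4])
  expect_equal(tab0$conf.high[4], tab0$estimate[4])
  # refuses a non-converged fit
  frbad <- fr
  frbad$converged <- FALSE
  expect_error(wald_table(frbad), "converge")
})

test_that("wald z-test holds its size for a truly zero coefficient", {
  # small Gaussian model with beta1[ , 2] = 0 via B0[2] = 0
  fam <- rr_family("gaussian", q = 2, sigma = 1)
  spec <- rr_spec(fam, p = 3, constrained = 1:3, d = 1)
  C0 <- matrix(c(1, 0.8), 2, 1)
  B0 <- matrix(c(0.6, 0, 0.4), 1, 3)
  pars <- rr_params(c(0.3, -0.2), C0 %*% B0, matrix(0, 2, 0), C = C0, B = B0)
  law <- lapply(1:3, function(i) list(type = "normal", mean = 0, sd = 1))
  sc <- rr_scenario(spec, pars, law, n = 1000)
  zero_idx <- 2 + 2 + 1 # eta_bar1 (2), beta1[ ,1] (2), then beta1[1,2]
  set.seed(15)
  nrep <- 1000
  rej <- logical(nrep)
  for (b in seq_len(nrep)) {
    ds <- simulate_dataset(sc, n = 1000, seed = NULL)
    fr <- suppressWarnings(fit_reduced(ds$X, ds$Y, spec))
    tab <- wald_table(fr)
    rej[b] <- tab$p.value[zero_idx] < 0.05
  }
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("bootstrap covariance is deterministic and agrees with avar", {
  set.seed(16)
  fam <- rr_family("gaussian", q = 3, sigma = 1)
  spec <- rr_spec(fam, p = 4, constrained = 1:4, d = 1)
  C0 <- matrix(c(1, 0.6, -0.4), 3, 1)
  B0 <- matrix(c(0.8, -0.5, 0.6, 0.3), 1, 4)
  pars <- rr_params(c(0.2, 0, -0.1), C0 %*% B0, matrix(0, 3, 0),
    C = C0, B = B0
  )
  law <- lapply(1:4, function(i) list(type = "normal", mean = 0, sd = 1))
  sc <- rr_scenario(spec, pars, law, n = 1000)
  ds <- simulate_dataset(sc, n = 1000, seed = 17)
  fr <- fit_reduced(ds$X, ds$Y, spec)
  bc <- bootstrap_cov(ds$X, ds$Y, spec, n_boot = 400, seed = 18, fit = fr)
  bc2 <- bootstrap_cov(ds$X, ds$Y, spec, n_boot = 400, seed = 18, fit = fr)
  expect_identical(bc, bc2)
  av <- avar_reduced(
    estimate_W(ds$X, fr$params, spec),
    build_G(fr$params$C, fr$params$B, spec)
  )$avar
  expect_lt(norm(bc - av, "F") / norm(av, "F"), 0.25)
  expect_error(bootstrap_cov(ds$X, ds$Y, spec, n_boot = 0), "at least")
})

test_that("AIC path orders nested fits coherently", {
  sc <- workforce_scenario()
  ds <- simulate_dataset(sc, n = 2000, seed = 19)
  path <- aic_rank_path(ds$X, ds$Y, sc$spec, ranks = 1:3)
  expect_equal(nrow(path), 3L)
  expect_true(all(diff(path$loglik) >= -1e-6)) # loglik nondecreasing in d
  expect_equal(path$df, c(23, 35, 45)) # identified counts at d = 1, 2, 3
  expect_equal(sum(path$selected), 1L)
  single <- aic_rank_path(ds$X, ds$Y, sc$spec, ranks = 2)
  expect_equal(nrow(single), 1L)
  expect_true(single$selected)
})
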