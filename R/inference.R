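#' Plug-in asymptotic covariance of the unrestricted MLE
#'
#' Estimates \eqn{W = \{E[F(X)^\top \nabla^2\psi(F(X)\xi) F(X)]\}^{-1}},
#' the asymptotic covariance of \eqn{\sqrt{n}(\hat\xi_n - \xi_0)} in the
#' full-rank model, by replacing the expectation over the predictor
#' distribution with the empirical mean over the observed rows of `X` and
#' evaluating \eqn{\nabla^2\psi} at the supplied (fitted) parameters.
#'
#' @inheritParams rr_loglik
#' @return A symmetric positive definite matrix of dimension
#'   `k1*(p+1) + k2`.
#' @export
estimate_W <- function(X, params, spec) {
  Xr <- spec_reorder_x(X, spec)
  estimate_W_internal(Xr, params, spec)
}

# Xr already in internal (constrained-first) column order.
estimate_W_internal <- function(Xr, params, spec) {
  fam <- spec$family
  storage.mode(Xr) <- "double"
  eta <- eta_rows(params, Xr, spec)
  bad <- which(!in_domain_rows(fam, eta))
  if (length(bad) > 0L) {
    stop("natural parameter outside the domain H at row ", bad[1L], ".",
      call. = FALSE
    )
  }
  gr <- full_groups(Xr, fam)
  info <- gd_info(fam, gr$Wn, gr$Mlist, eta)
  ev <- eigen(info, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values)) {
    dir <- ev$vectors[, which.min(ev$values)]
    top <- order(abs(dir), decreasing = TRUE)[1:3]
    stop("information matrix is singular; null direction loads on ",
      "coordinates ", paste(top, collapse = ", "), ".",
      call. = FALSE
    )
  }
  W <- ev$vectors %*% (t(ev$vectors) / ev$values)
  (W + t(W)) / 2
}

#' Gradient of the factorization chart
#'
#' The map \eqn{\theta = (\bar\eta_1, C, B, \beta_2, \bar\eta_2) \mapsto
#' \xi = (\bar\eta_1, \mathrm{vec}(C B), \mathrm{vec}(\beta_2),
#' \bar\eta_2)} has block-diagonal gradient `G` with identity blocks on the
#' free coordinates and \eqn{[B_0^\top \otimes I_{k_1} \,|\, I_r \otimes
#' C_0]} on the `vec(beta1)` rows — the differential of
#' \eqn{\mathrm{vec}(CB)}. Any decomposition \eqn{\beta_1 = C_0 B_0} may be
#' used; the projection and asymptotic covariance built from `G` depend only
#' on its column span.
#'
#' @param C0 `k1 x d` factor.
#' @param B0 `d x r` factor with `rank(C0 %*% B0) == d`.
#' @param spec An [rr_spec()].
#' @return A `(k1 + k1*p + k2) x (k1 + k1*d + d*r + k1*(p-r) + k2)` matrix.
#' @export
build_G <- function(C0, B0, spec) {
  fam <- spec$family
  k1 <- fam$k1
  k2 <- fam$k2
  r <- spec$r
  d <- spec$d
  pu <- spec$p - r
  C0 <- as.matrix(C0)
  B0 <- as.matrix(B0)
  if (!all(dim(C0) == c(k1, d)) || !all(dim(B0) == c(d, r))) {
    stop("`C0` must be k1 x d and `B0` d x r.", call. = FALSE)
  }
  if (qr(C0 %*% B0)$rank < d) {
    stop("`C0 %*% B0` has rank below d.", call. = FALSE)
  }
  n_xi <- k1 + k1 * spec$p + k2
  n_th <- k1 + k1 * d + d * r + k1 * pu + k2
  G <- matrix(0, n_xi, n_th)
  G[seq_len(k1), seq_len(k1)] <- diag(k1)
  rw <- k1 + seq_len(k1 * r)
  cw <- k1 + seq_len(k1 * d)
  G[rw, cw] <- kronecker(t(B0), diag(k1))
  cw2 <- k1 + k1 * d + seq_len(d * r)
  G[rw, cw2] <- kronecker(diag(r), C0)
  if (pu > 0L) {
    G[k1 + k1 * r + seq_len(k1 * pu), k1 + k1 * d + d * r + seq_len(k1 * pu)] <-
      diag(k1 * pu)
  }
  if (k2 > 0L) {
    G[n_xi - k2 + seq_len(k2), n_th - k2 + seq_len(k2)] <- diag(k2)
  }
  G
}

#' Oblique projection onto the column span of G
#'
#' Computes \eqn{\Pi = G (G^\top \Sigma G)^{\dagger} G^\top \Sigma}, the
#' projection onto \eqn{\mathrm{span}(G)} that is orthogonal in the inner
#' product \eqn{\langle x, y\rangle_\Sigma = y^\top \Sigma x}. The
#' Moore–Penrose pseudoinverse makes the result well defined when `G` is
#' rank deficient (it depends on `G` only through its column span). The
#' result is idempotent and \eqn{\Sigma}-self-adjoint:
#' \eqn{\Sigma \Pi = \Pi^\top \Sigma}.
#'
#' @param G A nonzero matrix.
#' @param Sigma A symmetric positive definite matrix.
#' @return The projection matrix.
#' @export
projection_oblique <- function(G, Sigma) {
  G <- as.matrix(G)
  Sigma <- as.matrix(Sigma)
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma)))) {
    stop("`Sigma` must be symmetric.", call. = FALSE)
  }
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)
  if (min(ev$values) <= 0) {
    stop("`Sigma` must be positive definite.", call. = FALSE)
  }
  if (max(abs(G)) == 0) stop("`G` must be nonzero.", call. = FALSE)
  SG <- Sigma %*% G
  G %*% MASS::ginv(crossprod(G, SG)) %*% t(SG)
}

#' Asymptotic covariance of the rank-restricted MLE
#'
#' The restricted estimator satisfies
#' \eqn{\mathrm{avar}\{\sqrt{n}(\hat\xi^{res}_n - \xi_0)\} =
#' \Pi_{\xi_0}(W^{-1})\, W = G (G^\top W^{-1} G)^{\dagger} G^\top}: the
#' unrestricted covariance `W` compressed by the oblique projection onto
#' the tangent space of the rank manifold. The result is symmetric positive
#' semidefinite with rank equal to `rank(G)`, and `W - avar` is positive
#' semidefinite (the rank restriction never loses efficiency).
#'
#' @param W Symmetric positive definite matrix from [estimate_W()].
#' @param G Chart gradient from [build_G()].
#' @param n Optional sample size; when supplied, per-observation standard
#'   errors `sqrt(diag(avar)/n)` are stored.
#' @return An object of class `rr_avar`: list with `W`, `G`, `avar`, `se`
#'   (or `NULL`), and `n`.
#' @export
avar_reduced <- function(W, G, n = NULL) {
  W <- as.matrix(W)
  G <- as.matrix(G)
  if (nrow(G) != nrow(W)) {
    stop("`G` must have as many rows as `W`.", call. = FALSE)
  }
  Winv <- solve(W)
  A <- G %*% MASS::ginv(crossprod(G, Winv %*% G)) %*% t(G)
  A <- (A + t(A)) / 2
  structure(
    list(
      W = W, G = G, avar = A,
      se = if (!is.null(n)) sqrt(pmax(diag(A), 0) / n),
      n = n
    ),
    class = "rr_avar"
  )
}

#' @export
print.rr_avar <- function(x, ...) {
  cat("<rr_avar> ", nrow(x$avar), " x ", ncol(x$avar),
    " asymptotic covariance (rank ", qr(x$G)$rank, ")\n",
    sep = ""
  )
  invisible(x)
}

# Asymptotic covariance object for a fitted model: W from the plug-in
# information; for a restricted fit the projection through the stored
# factors, for a full-rank fit avar = W.
fit_avar <- function(fit) {
  W <- estimate_W_internal(fit$X, fit$params, fit$spec)
  if (fit$restricted) {
    avar_reduced(W, build_G(fit$params$C, fit$params$B, fit$spec), n = fit$n)
  } else {
    structure(
      list(
        W = W, G = diag(nrow(W)), avar = W,
        se = sqrt(pmax(diag(W), 0) / fit$n), n = fit$n
      ),
      class = "rr_avar"
    )
  }
}

# labels for the natural-parameter contrasts, e.g. log(p1/p4)
contrast_labels <- function(fam) {
  if (fam$name == "multinomial") {
    paste0("log(p", seq_len(fam$k1), "/p", fam$q, ")")
  } else {
    paste0("eta", seq_len(fam$k1))
  }
}

xi_labels <- function(spec) {
  fam <- spec$family
  resp <- contrast_labels(fam)
  ord <- c(spec$constrained, spec$unconstrained)
  terms <- c(
    rep("(Intercept)", fam$k1),
    rep(spec$x_names[ord], each = fam$k1),
    if (fam$k2 > 0L) paste0("dispersion", seq_len(fam$k2))
  )
  response <- c(
    rep(resp, spec$p + 1L),
    if (fam$k2 > 0L) rep("(free)", fam$k2)
  )
  list(term = terms, response = response)
}

#' Wald coefficient table
#'
#' Per-coordinate estimates, standard errors (`sqrt(diag(avar)/n)`, the
#' per-observation scale), z statistics, p-values and confidence intervals
#' for every entry of \eqn{\xi}, including all entries of the rank-restricted
#' product \eqn{\beta_1 = C B}. Coordinates with zero asymptotic variance
#' (directions fully determined by the restriction) get a zero standard
#' error and a degenerate interval at the estimate. No multiplicity
#' adjustment is applied; stars mark unadjusted 5%-level significance.
#'
#' @param fit A converged `rr_fit`.
#' @param cov Optional [avar_reduced()] result; computed from the fit when
#'   omitted.
#' @param level Confidence level.
#' @return A tibble with columns `term`, `response`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`, `signif`.
#' @export
wald_table <- function(fit, cov = NULL, level = 0.95) {
  stopifnot(inherits(fit, "rr_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; refusing to build a Wald table.",
      call. = FALSE
    )
  }
  if (is.null(cov)) cov <- fit_avar(fit)
  se <- sqrt(pmax(diag(cov$avar), 0) / fit$n)
  est <- fit$xi
  z <- ifelse(se > 0, est / se, NA_real_)
  pv <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  lab <- xi_labels(fit$spec)
  tibble::tibble(
    term = lab$term,
    response = lab$response,
    estimate = est,
    std.error = se,
    statistic = z,
    p.value = pv,
    conf.low = est - zc * se,
    conf.high = est + zc * se,
    signif = dplyr::if_else(!is.na(pv) & pv < 0.05, "*", "")
  )
}

#' Case-resampling bootstrap covariance
#'
#' Draws `n_boot` bootstrap samples of the cases \eqn{(x_i, y_i)} with
#' replacement (consistent with the joint-distribution framework), refits
#' the rank-restricted model on each, and returns the empirical covariance
#' of the resampled estimates on the \eqn{\sqrt{n}} scale, i.e.
#' `n * cov(xi_boot)`. Replicates are warm-started at the base fit.
#'
#' @inheritParams rr_loglik
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param fit Optional base `rr_fit` to warm-start from (refitted when
#'   omitted).
#' @return Covariance matrix of dimension `length(xi)`, with attribute
#'   `"n_fail"` counting discarded non-converged replicates.
#' @export
bootstrap_cov <- function(X, Y, spec, n_boot, seed = NULL, fit = NULL) {
  if (!is.numeric(n_boot) || n_boot < 100) {
    stop("`n_boot` must be at least 100.", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  if (!is.null(seed)) set.seed(seed)
  Xr <- spec_reorder_x(X, spec)
  Y <- if (is.matrix(Y) || is.data.frame(Y)) as.matrix(Y) else Y
  if (is.null(fit)) {
    fit <- if (spec$r > 0L) fit_reduced(X, Y, spec) else fit_full(X, Y, spec)
  }
  if (!isTRUE(fit$converged)) {
    stop("base fit did not converge.", call. = FALSE)
  }
  n <- nrow(Xr)
  spec_int <- spec
  spec_int$constrained <- seq_len(spec$r)
  spec_int$unconstrained <- spec$r + seq_len(spec$p - spec$r)
  spec_int$x_names <- spec$x_names[c(spec$constrained, spec$unconstrained)]
  draws <- matrix(NA_real_, n_boot, length(fit$xi))
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- Xr[idx, , drop = FALSE]
    Yb <- if (is.matrix(Y)) Y[idx, , drop = FALSE] else Y[idx]
    est <- tryCatch(
      suppressWarnings({
        fb <- if (spec$r > 0L) {
          fit_reduced(Xb, Yb, spec_int,
            init = list(C = fit$params$C, B = fit$params$B, fit = fit)
          )
        } else {
          fit_full(Xb, Yb, spec_int)
        }
        if (isTRUE(fb$converged)) fb$xi else NULL
      }),
      error = function(e) NULL
    )
    if (is.null(est)) n_fail <- n_fail + 1L else draws[b, ] <- est
  }
  if (n_fail > 0.05 * n_boot) {
    stop(n_fail, " of ", n_boot, " bootstrap replicates failed to converge.",
      call. = FALSE
    )
  }
  out <- n * stats::cov(draws[stats::complete.cases(draws), , drop = FALSE])
  attr(out, "n_fail") <- n_fail
  out
}

#' AIC path over candidate ranks
#'
#' Fits the rank-restricted model at each candidate rank and reports the
#' maximized total log-likelihood, the number of identified parameters
#' (the raw factor count minus the `d^2` redundancy of the factorization)
#' and AIC \eqn{= -2\ell + 2\,\mathrm{df}}; the minimizer is flagged.
#'
#' @inheritParams rr_loglik
#' @param ranks Integer vector of candidate ranks within
#'   `1..min(k1, r)`.
#' @return A tibble of class `rr_rank_path` with columns `rank`, `loglik`
#'   (total), `df`, `aic`, `converged`, `selected`.
#' @export
aic_rank_path <- function(X, Y, spec, ranks = seq_len(min(spec$family$k1, spec$r))) {
  ranks <- sort(unique(as.integer(ranks)))
  if (any(ranks < 1L | ranks > min(spec$family$k1, spec$r))) {
    stop("`ranks` must lie in 1..min(k1, r).", call. = FALSE)
  }
  full <- fit_full(X, Y, spec)
  rows <- purrr::map(ranks, function(d) {
    sp <- spec
    sp$d <- d
    ft <- tryCatch(
      suppressWarnings(fit_reduced(X, Y, sp, init = list(fit = full))),
      error = function(e) NULL
    )
    df <- count_parameters(sp, restricted = TRUE) - d^2
    if (is.null(ft)) {
      tibble::tibble(
        rank = d, loglik = NA_real_, df = df, aic = NA_real_,
        converged = FALSE
      )
    } else {
      tibble::tibble(
        rank = d, loglik = ft$loglik_total, df = df,
        aic = -2 * ft$loglik_total + 2 * df,
        converged = ft$converged
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- !is.na(out$aic) & out$aic == min(out$aic, na.rm = TRUE)
  class(out) <- c("rr_rank_path", class(out))
  out
}
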