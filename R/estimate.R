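#' Mean conditional log-likelihood
#'
#' Evaluates \eqn{L_n = n^{-1}\sum_i \{\eta_{x_i}^\top T(y_i) -
#' \psi(\eta_{x_i})\}}, the average conditional log-likelihood of the
#' multivariate GLM (constants absorbed in the carrier \eqn{h(y)} are
#' dropped).
#'
#' @param params An [rr_params()] object.
#' @param X Predictor matrix or data frame (`n x p`, original column order).
#' @param Y Responses: integer labels for the multinomial family, otherwise
#'   an `n x q` matrix.
#' @param spec An [rr_spec()].
#' @return Scalar mean log-likelihood.
#' @export
rr_loglik <- function(params, X, Y, spec) {
  fam <- spec$family
  Xr <- spec_reorder_x(X, spec)
  Tmat <- suff_stat(fam, Y)
  eta <- eta_rows(params, Xr, spec)
  bad <- which(!in_domain_rows(fam, eta))
  if (length(bad) > 0L) {
    stop("natural parameter outside the domain H at row ", bad[1L], ".",
      call. = FALSE
    )
  }
  gd_loglik(fam, eta, Tmat)
}

# eta for every row of the (already reordered) design: n x k.
eta_rows <- function(params, Xr, spec) {
  fam <- spec$family
  n <- nrow(Xr)
  beta <- cbind(params$beta1, params$beta2)
  eta1 <- matrix(params$eta_bar1, n, fam$k1, byrow = TRUE)
  if (ncol(beta) > 0L) eta1 <- eta1 + Xr %*% t(beta)
  if (fam$k2 > 0L) {
    cbind(eta1, matrix(params$eta_bar2, n, fam$k2, byrow = TRUE))
  } else {
    eta1
  }
}

check_design <- function(Xr, Y, spec) {
  fam <- spec$family
  n <- nrow(Xr)
  if (!is.numeric(Xr)) stop("predictors must be numeric.", call. = FALSE)
  ny <- if (is.matrix(Y) || is.data.frame(Y)) nrow(Y) else length(Y)
  if (ny != n) {
    stop("X has ", n, " rows but Y has ", ny, ".", call. = FALSE)
  }
  sds <- apply(Xr, 2L, stats::sd)
  const <- which(sds == 0)
  if (length(const) > 0L) {
    nm <- colnames(Xr)[const[1L]]
    stop("predictor ", if (is.null(nm)) const[1L] else sQuote(nm),
      " is constant; remove it (the intercept is always included).",
      call. = FALSE
    )
  }
  if (qr(cbind(1, Xr))$rank < ncol(Xr) + 1L) {
    stop("design matrix (with intercept) is rank deficient.", call. = FALSE)
  }
  if (fam$name == "multinomial") {
    lab <- if (is.matrix(Y) && ncol(Y) > 1L) {
      max.col(as.matrix(Y))
    } else {
      as.integer(drop(as.matrix(Y)))
    }
    counts <- tabulate(lab, nbins = fam$q)
    if (any(counts == 0L)) {
      stop("response category ", which(counts == 0L)[1L],
        " is empty; the MLE does not exist for its intercept.",
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

new_rr_fit <- function(theta, spec, Xr, Y, Tmat, sol, restricted,
                       C = NULL, B = NULL, outer_trace = NULL) {
  params <- unpack_params(theta, spec)
  if (!is.null(C)) {
    params$C <- C
    params$B <- B
  }
  n <- nrow(Xr)
  structure(
    list(
      params = params, xi = theta, spec = spec,
      loglik = sol$loglik, loglik_total = n * sol$loglik,
      loglik_trace = if (is.null(outer_trace)) sol$trace else outer_trace,
      converged = sol$converged, n_iter = sol$n_iter,
      message = sol$message, restricted = restricted,
      n = n, X = Xr, Y = Y, Tmat = Tmat
    ),
    class = "rr_fit"
  )
}

#' Full-rank maximum likelihood fit
#'
#' Fits the unrestricted multivariate GLM
#' \eqn{\eta_x = (\bar\eta_1 + \beta x,\ \bar\eta_2)} by Fisher scoring
#' (Newton steps on the expected information, with step-halving so the
#' log-likelihood never decreases). At convergence the score has sup-norm
#' at most `tol_score` and the expected information is positive definite.
#'
#' @inheritParams rr_loglik
#' @param tol_score Convergence tolerance on the sup-norm of the score.
#' @param max_iter Maximum scoring iterations.
#' @return An object of class `rr_fit`; see [tidy.rr_fit()], [glance.rr_fit()].
#' @export
fit_full <- function(X, Y, spec, tol_score = 1e-6, max_iter = 200L) {
  fam <- spec$family
  Xr <- spec_reorder_x(X, spec)
  storage.mode(Xr) <- "double"
  check_design(Xr, Y, spec)
  n <- nrow(Xr)
  if (n <= count_parameters(spec)) {
    stop("need n > ", count_parameters(spec), " observations to fit ",
      count_parameters(spec), " parameters.",
      call. = FALSE
    )
  }
  Tmat <- suff_stat(fam, Y)
  gr <- full_groups(Xr, fam)
  theta0 <- init_theta(fam, spec, Tmat)
  sol <- fs_solve(gr$Wn, gr$Mlist, Tmat, fam, theta0,
    tol_score = tol_score, max_iter = max_iter
  )
  if (sol$converged && fam$name %in% c("multinomial", "poisson") &&
    max(abs(sol$theta)) > 15) {
    # natural-parameter coefficients this large mean saturated fitted
    # probabilities: the likelihood is maximized at infinity (separation)
    sol$converged <- FALSE
    sol$diverged <- TRUE
    sol$message <- paste0(
      "estimates diverged (sup-norm ", format(max(abs(sol$theta)), digits = 3),
      "): the data appear separated and the MLE may not exist"
    )
  }
  if (!sol$converged) {
    warning("full-rank fit did not converge: ", sol$message, call. = FALSE)
  }
  new_rr_fit(sol$theta, spec, Xr, Y, Tmat, sol, restricted = FALSE)
}

init_theta <- function(fam, spec, Tmat) {
  theta0 <- numeric(count_parameters(spec))
  if (fam$k2 > 0L) {
    # Gaussian free-variance block: moment-matched starting value
    q <- fam$q
    v <- mean(apply(Tmat[, seq_len(q), drop = FALSE], 2L, stats::var))
    theta0[length(theta0)] <- -1 / (2 * max(v, 1e-3))
  }
  theta0
}

#' Rank-restricted maximum likelihood fit
#'
#' Fits the partial reduced-rank model, in which the coefficient block
#' \eqn{\beta_1} of the constrained predictors is restricted to rank at
#' most `d`, by alternating maximization over the factorization
#' \eqn{\beta_1 = C B} (`C` of dimension `k1 x d`, `B` of `d x r`):
#' with `B` fixed the model is a full-rank GLM in the reduced predictors
#' \eqn{\nu = B x_1} joined with \eqn{x_2}; with `C` fixed it is a GLM in
#' \eqn{x_1} whose coefficients carry the structure \eqn{C B}. Each half
#' step is solved by Fisher scoring with step-halving, so the log-likelihood
#' trace is nondecreasing. After every sweep the factors are renormalized to
#' the corner form of [factorize_corner()] to prevent drift along the
#' unidentified direction \eqn{(C, B) \mapsto (C M, M^{-1} B)}.
#'
#' Initialization takes the full-rank fit and truncates the SVD of its
#' \eqn{\hat\beta_1} block, a standard warm start for alternating schemes.
#'
#' @inheritParams rr_loglik
#' @param init Optional list with components `C` (`k1 x d`) and `B`
#'   (`d x r`) used as starting factors (a full-rank warm-start fit may be
#'   supplied as component `fit`).
#' @param tol Relative log-likelihood convergence tolerance of the outer
#'   alternation.
#' @param tol_xi Sup-norm tolerance on the change of the packed parameter
#'   vector between sweeps; both criteria must hold to stop (alternating
#'   schemes converge linearly, so the log-likelihood can stagnate while
#'   the factors are still moving).
#' @param max_outer Maximum number of outer alternation sweeps.
#' @return An object of class `rr_fit` with factors `C`, `B` stored in
#'   `$params` and `rank(beta1) <= d`.
#' @export
fit_reduced <- function(X, Y, spec, init = NULL, tol = 1e-9,
                        tol_xi = 1e-8, max_outer = 500L) {
  fam <- spec$family
  if (spec$r == 0L) stop("spec has no constrained predictors.", call. = FALSE)
  if (spec$d > min(fam$k1, spec$r)) {
    stop("rank d exceeds min(k1, r).", call. = FALSE)
  }
  Xr <- spec_reorder_x(X, spec)
  storage.mode(Xr) <- "double"
  check_design(Xr, Y, spec)
  Tmat <- suff_stat(fam, Y)
  n <- nrow(Xr)
  k1 <- fam$k1
  k2 <- fam$k2
  r <- spec$r
  pu <- spec$p - r
  d <- spec$d
  X1 <- Xr[, seq_len(r), drop = FALSE]
  X2 <- Xr[, r + seq_len(pu), drop = FALSE]

  # initialization: truncated SVD of the full-rank beta1-hat
  full <- if (!is.null(init$fit)) init$fit else fit_full(X, Y, spec)
  if (!is.null(init$C)) {
    C <- as.matrix(init$C)
    B <- as.matrix(init$B)
    stopifnot(nrow(C) == k1, ncol(C) == d, nrow(B) == d, ncol(B) == r)
    eta_bar1 <- full$params$eta_bar1
    beta2 <- full$params$beta2
    eta_bar2 <- full$params$eta_bar2
  } else {
    sv <- svd(full$params$beta1)
    C <- sv$u[, seq_len(d), drop = FALSE]
    B <- crossprod(C, full$params$beta1)
    eta_bar1 <- full$params$eta_bar1
    beta2 <- full$params$beta2
    eta_bar2 <- full$params$eta_bar2
  }

  Mtop_k1 <- rbind(diag(k1), matrix(0, k2, k1))
  Meta2 <- if (k2 > 0L) rbind(matrix(0, k1, k2), diag(k2)) else NULL

  ll_prev <- -Inf
  xi_prev <- rep(Inf, count_parameters(spec))
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  inner_ok <- TRUE
  for (it in seq_len(max_outer)) {
    iters <- it
    # (i) fix B: GLM in predictors (B x1, x2) with coefficients (C, beta2)
    Xa <- cbind(X1 %*% t(B), X2)
    gra <- full_groups(Xa, fam)
    th0 <- c(eta_bar1, as.numeric(C), as.numeric(beta2), eta_bar2)
    solA <- fs_solve(gra$Wn, gra$Mlist, Tmat, fam, th0,
      tol_score = 1e-8, max_iter = 100L
    )
    spl <- gd_split(solA$theta, gra$Mlist)
    eta_bar1 <- as.numeric(spl[[1L]])
    C <- matrix(unlist(spl[1L + seq_len(d)]), k1, d)
    beta2 <- matrix(
      if (pu > 0L) unlist(spl[1L + d + seq_len(pu)]) else numeric(0), k1, pu
    )
    if (k2 > 0L) eta_bar2 <- as.numeric(spl[[length(spl)]])

    # (ii) fix C: GLM in x1 with coefficient structure C B
    Wn <- cbind(1, X1, X2)
    MC <- rbind(C, matrix(0, k2, d))
    Mlist <- c(
      list(Mtop_k1), rep(list(MC), r), rep(list(Mtop_k1), pu)
    )
    if (k2 > 0L) {
      Wn <- cbind(Wn, 1)
      Mlist <- c(Mlist, list(Meta2))
    }
    th0 <- c(eta_bar1, as.numeric(B), as.numeric(beta2), eta_bar2)
    solB <- fs_solve(Wn, Mlist, Tmat, fam, th0,
      tol_score = 1e-8, max_iter = 100L
    )
    spl <- gd_split(solB$theta, Mlist)
    eta_bar1 <- as.numeric(spl[[1L]])
    B <- matrix(unlist(spl[1L + seq_len(r)]), d, r)
    beta2 <- matrix(
      if (pu > 0L) unlist(spl[1L + r + seq_len(pu)]) else numeric(0), k1, pu
    )
    if (k2 > 0L) eta_bar2 <- as.numeric(spl[[length(spl)]])
    inner_ok <- solA$converged && solB$converged

    ll <- solB$loglik
    trace <- c(trace, ll)
    xi_now <- c(eta_bar1, as.numeric(C %*% B), as.numeric(beta2), eta_bar2)
    if (is.finite(ll_prev) &&
      abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1e-10) &&
      max(abs(xi_now - xi_prev)) <= tol_xi) {
      converged <- inner_ok
      ll_prev <- ll
      break
    }
    ll_prev <- ll
    xi_prev <- xi_now

    # renormalize factors to corner form to prevent drift
    fc <- corner_factors(C %*% B, d)
    if (!is.null(fc)) {
      C <- fc$C
      B <- fc$B
    }
  }
  beta1 <- C %*% B
  params <- rr_params(eta_bar1, beta1, beta2, eta_bar2, C = C, B = B)
  theta <- pack_params(params)
  sol <- list(
    loglik = ll_prev, trace = trace, converged = converged,
    n_iter = iters,
    message = if (!converged) {
      paste0(
        "alternating maximization did not converge in ", iters,
        " sweeps",
        if (!inner_ok) " (an inner Fisher-scoring solve failed)"
      )
    }
  )
  if (!sol$converged) {
    warning("reduced-rank fit did not converge: ", sol$message, call. = FALSE)
  }
  new_rr_fit(theta, spec, Xr, Y, Tmat, sol,
    restricted = TRUE, C = C, B = B, outer_trace = trace
  )
}

# Tolerant internal corner factorization; returns NULL if beta1 is
# numerically rank-deficient below d (keep current factors in that case).
corner_factors <- function(beta1, d) {
  sv <- svd(beta1)$d
  if (length(sv) < d || sv[d] <= 1e-12 * max(sv[1L], 1)) {
    return(NULL)
  }
  fc <- factorize_corner(beta1, d)
  list(C = fc$C, B = fc$B)
}

#' Corner-form factorization of a rank-d matrix
#'
#' Writes a rank-`d` matrix `beta1` (`k1 x r`) as `C %*% B` where, after the
#' returned row permutation, `C` has the corner form
#' \eqn{[I_d; A]} — its leading `d` rows (the pivot rows) form the identity.
#' The pivot rows are chosen by a rank-revealing pivoted QR of `t(beta1)` so
#' that they are linearly independent; the factorization then reconstructs
#' `beta1` exactly (up to floating point).
#'
#' @param beta1 Numeric matrix of exact rank `d`.
#' @param d Target rank.
#' @return A list with `C` (`k1 x d`, rows in the original order, identity
#'   on the pivot rows), `B` (`d x r`, the pivot rows of `beta1`), `rows`
#'   (indices of the pivot rows) and `perm` (the permutation placing the
#'   pivot rows first, so `C[perm, ][1:d, ] == diag(d)`).
#' @export
factorize_corner <- function(beta1, d) {
  beta1 <- as.matrix(beta1)
  k1 <- nrow(beta1)
  d <- as.integer(d)
  if (d < 1L || d > min(dim(beta1))) {
    stop("`d` must lie in 1..min(dim(beta1)).", call. = FALSE)
  }
  sv <- svd(beta1)$d
  if (sv[d] <= max(dim(beta1)) * .Machine$double.eps * max(sv[1L], 1)) {
    stop("`beta1` has numerical rank below d = ", d, ".", call. = FALSE)
  }
  # prefer the leading d rows when they are independent (identity
  # permutation); otherwise pick pivot rows by rank-revealing QR
  lead <- svd(beta1[seq_len(d), , drop = FALSE])$d
  if (length(lead) == d && lead[d] > 1e-8 * max(sv[1L], 1)) {
    rows <- seq_len(d)
  } else {
    qrt <- qr(t(beta1), LAPACK = TRUE)
    rows <- sort(qrt$pivot[seq_len(d)])
  }
  B <- beta1[rows, , drop = FALSE]
  C <- t(solve(tcrossprod(B), tcrossprod(B, beta1)))
  C[rows, ] <- diag(d)
  list(C = C, B = B, rows = rows, perm = c(rows, setdiff(seq_len(k1), rows)))
}

#' Closed-form Gaussian reduced-rank regression
#'
#' The classical multivariate linear-model solution: the ordinary least
#' squares coefficient matrix
#' \eqn{\hat B_{ols} = (\sum_i Y_i X_i^\top)(\sum_i X_i X_i^\top)^{-1}}
#' followed by projection of its rows onto the leading `rank` left singular
#' vectors of the fitted-value matrix, i.e.
#' \eqn{\hat B_{rrr} = U_r U_r^\top \hat B_{ols}}. This is the exact
#' minimizer of \eqn{\sum_i \|Y_i - B X_i\|^2} over matrices of rank at most
#' `rank`, and serves as an independent oracle for the Gaussian
#' unit-variance restricted MLE (no intercept; center the data to compare
#' with an intercept model).
#'
#' @param X `n x p` predictor matrix.
#' @param Y `n x q` response matrix.
#' @param rank Rank bound, at most `min(p, q)`.
#' @return The `q x p` rank-truncated coefficient matrix.
#' @export
gaussian_rrr <- function(X, Y, rank) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(ncol(X), ncol(Y))) {
    stop("`rank` must lie in 1..min(p, q).", call. = FALSE)
  }
  Gm <- crossprod(X)
  if (rcond(Gm) < 1e-12) {
    stop("Gram matrix of X is (near-)singular.", call. = FALSE)
  }
  Bols_t <- solve(Gm, crossprod(X, Y)) # p x q
  Yhat <- X %*% Bols_t
  U <- svd(Yhat)$v[, seq_len(rank), drop = FALSE] # q x rank
  U %*% crossprod(U, t(Bols_t))
}
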