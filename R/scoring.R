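# Internal Fisher-scoring engine on a "grouped" linear natural-parameter
# design: eta_i = sum_g w[i, g] * (M[[g]] %*% theta_g), with w an n x G
# weight matrix and M[[g]] fixed k x m_g maps. Both the unrestricted model
# (M blocks are identities, w the predictors) and the two alternating
# subproblems of the rank-restricted fit (where one factor is frozen inside
# M) are instances, so score and expected-information assembly are shared
# and fully vectorized over observations.

gd_lengths <- function(Mlist) vapply(Mlist, ncol, integer(1))

gd_split <- function(theta, Mlist) {
  ml <- gd_lengths(Mlist)
  split(theta, rep(seq_along(Mlist), ml))
}

gd_eta <- function(Wn, Mlist, theta) {
  th <- gd_split(theta, Mlist)
  k <- nrow(Mlist[[1L]])
  V <- matrix(0, k, length(Mlist))
  for (g in seq_along(Mlist)) V[, g] <- Mlist[[g]] %*% th[[g]]
  Wn %*% t(V)
}

gd_loglik <- function(fam, eta, Tmat) {
  mean(rowSums(eta * Tmat) - psi_rows(fam, eta))
}

# Score of the mean log-likelihood: (1/n) sum_i D_i' (T_i - mu_i).
gd_score <- function(fam, Wn, Mlist, eta, Tmat) {
  R <- Tmat - mean_rows(fam, eta)
  S <- crossprod(R, Wn) # k x G
  out <- vector("list", length(Mlist))
  for (g in seq_along(Mlist)) out[[g]] <- crossprod(Mlist[[g]], S[, g])
  unlist(out, use.names = FALSE) / nrow(Wn)
}

# Expected information of the mean log-likelihood:
# (1/n) sum_i D_i' hess_psi(eta_i) D_i, assembled blockwise from
# G x G cross-moments of the weights against each Hessian entry.
gd_info <- function(fam, Wn, Mlist, eta) {
  n <- nrow(Wn)
  k <- ncol(eta)
  G <- length(Mlist)
  H <- hess_rows(fam, eta)
  Sarr <- array(0, c(G, G, k, k))
  for (s in seq_len(k)) {
    for (t in s:k) {
      S <- crossprod(Wn, Wn * H[, s, t])
      Sarr[, , s, t] <- S
      Sarr[, , t, s] <- S
    }
  }
  ml <- gd_lengths(Mlist)
  offs <- c(0L, cumsum(ml))
  m <- offs[G + 1L]
  info <- matrix(0, m, m)
  for (g in seq_len(G)) {
    rg <- offs[g] + seq_len(ml[g])
    for (h in g:G) {
      rh <- offs[h] + seq_len(ml[h])
      K <- matrix(Sarr[g, h, , ], k, k)
      blk <- crossprod(Mlist[[g]], K %*% Mlist[[h]])
      info[rg, rh] <- blk
      if (h > g) info[rh, rg] <- t(blk)
    }
  }
  info / n
}

# Maximize the mean log-likelihood over theta by Fisher scoring with
# step-halving (accepted steps never decrease the criterion). Convergence:
# sup-norm of the score <= tol_score, or relative log-likelihood change
# <= tol_loglik. Divergence of the iterates with still-increasing
# log-likelihood (separation) is reported, never silently truncated.
fs_solve <- function(Wn, Mlist, Tmat, fam, theta0,
                     tol_score = 1e-6, tol_loglik = 1e-12,
                     max_iter = 200L) {
  theta <- theta0
  eta <- gd_eta(Wn, Mlist, theta)
  if (!all(in_domain_rows(fam, eta))) {
    stop("initial parameters give natural parameters outside the domain H.",
      call. = FALSE
    )
  }
  ll <- gd_loglik(fam, eta, Tmat)
  trace <- ll
  converged <- FALSE
  diverged <- FALSE
  msg <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    score <- gd_score(fam, Wn, Mlist, eta, Tmat)
    if (max(abs(score)) <= tol_score) {
      converged <- TRUE
      break
    }
    info <- gd_info(fam, Wn, Mlist, eta)
    dir <- tryCatch(
      solve(info, score),
      error = function(e) {
        stop("expected information matrix is singular; ",
          "check the design for collinearity.",
          call. = FALSE
        )
      }
    )
    alpha <- 1
    accepted <- FALSE
    for (h in seq_len(40L)) {
      cand <- theta + alpha * dir
      eta_c <- gd_eta(Wn, Mlist, cand)
      if (all(in_domain_rows(fam, eta_c))) {
        ll_c <- gd_loglik(fam, eta_c, Tmat)
        if (is.finite(ll_c) && ll_c >= ll - 1e-12) {
          theta <- cand
          eta <- eta_c
          delta <- ll_c - ll
          ll <- ll_c
          trace <- c(trace, ll)
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      converged <- max(abs(score)) <= 1e-4
      msg <- if (converged) {
        NULL
      } else {
        "no ascent step found; criterion may be flat or ill-conditioned"
      }
      break
    }
    if (delta <= tol_loglik * (abs(ll) + 1e-10)) {
      converged <- max(abs(score)) <= sqrt(tol_score)
      if (converged) break
    }
    if (max(abs(theta)) > 1e6) {
      diverged <- TRUE
      msg <- paste0(
        "parameter estimates diverged (sup-norm ",
        format(max(abs(theta)), digits = 3),
        ") with increasing log-likelihood; ",
        "the data may be separated and the MLE may not exist"
      )
      break
    }
  }
  if (!converged && is.null(msg) && !diverged) {
    msg <- paste0("Fisher scoring did not converge in ", max_iter, " iterations")
  }
  list(
    theta = theta, loglik = ll, trace = trace, converged = converged,
    diverged = diverged, n_iter = iter, message = msg
  )
}

# Grouped design of the unrestricted model: intercept, one group per
# predictor column (each mapping through [I_k1; 0]), and the x-free block.
full_groups <- function(Xr, fam) {
  k1 <- fam$k1
  k2 <- fam$k2
  n <- nrow(Xr)
  Mtop <- rbind(diag(k1), matrix(0, k2, k1))
  Wn <- cbind(1, Xr)
  Mlist <- rep(list(Mtop), ncol(Xr) + 1L)
  if (k2 > 0L) {
    Wn <- cbind(Wn, 1)
    Mlist <- c(Mlist, list(rbind(matrix(0, k1, k2), diag(k2))))
  }
  list(Wn = Wn, Mlist = Mlist)
}
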