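#' Model specification for a partial reduced-rank multivariate GLM
#'
#' Describes the model \eqn{\eta_x = (\bar\eta_1 + \beta_1 x_1 + \beta_2 x_2,
#' \ \bar\eta_2)}: the natural-parameter block of dimension `k1` depends
#' linearly on the predictors through an intercept \eqn{\bar\eta_1}, a
#' rank-constrained coefficient matrix \eqn{\beta_1 \in R^{k_1 \times r}}
#' (rank at most `d`) for the constrained predictor block \eqn{x_1}, and an
#' unconstrained \eqn{\beta_2} for the remaining predictors \eqn{x_2}; the
#' `k2`-dimensional block \eqn{\bar\eta_2} is free of the predictors. The
#' intercept is never rank-constrained.
#'
#' Constrained predictors are identified by explicit column indices (not
#' assumed contiguous); internally the design is reordered so the constrained
#' block comes first, and all packed parameter vectors follow that order.
#'
#' @param family An [rr_family()] object.
#' @param p Total number of predictors.
#' @param constrained Integer indices (in `1..p`) of the rank-constrained
#'   predictors, or `NULL` for a full-rank model with no constrained block.
#' @param d Rank bound for `beta1`; must satisfy `0 < d <= min(k1, r)`.
#'   `d = min(k1, r)` makes the restriction vacuous and reproduces the
#'   full-rank model.
#' @param x_names Optional character vector of predictor names (length `p`).
#' @return An object of class `rr_spec`.
#' @examples
#' fam <- rr_family("multinomial", q = 4)
#' sp <- rr_spec(fam, p = 14, constrained = 1:12, d = 1)
#' count_parameters(sp) # 45
#' count_parameters(sp, restricted = TRUE) # 24
#' @export
rr_spec <- function(family, p, constrained = NULL, d = NULL, x_names = NULL) {
  stopifnot(inherits(family, "rr_family"))
  p <- as.integer(p)
  if (p < 0) stop("`p` must be nonnegative.", call. = FALSE)
  if (is.null(constrained) || length(constrained) == 0L) {
    constrained <- integer(0)
    d <- 0L
  } else {
    constrained <- sort(unique(as.integer(constrained)))
    if (any(constrained < 1L | constrained > p)) {
      stop("`constrained` indices must lie in 1..p.", call. = FALSE)
    }
    r <- length(constrained)
    if (is.null(d)) d <- min(family$k1, r)
    d <- as.integer(d)
    if (d < 1L || d > min(family$k1, r)) {
      stop("rank `d` must satisfy 0 < d <= min(k1, r) = ",
        min(family$k1, r), ".",
        call. = FALSE
      )
    }
  }
  if (is.null(x_names)) {
    x_names <- if (p > 0L) paste0("x", seq_len(p)) else character(0)
  }
  if (length(x_names) != p) stop("`x_names` must have length p.", call. = FALSE)
  structure(
    list(
      family = family, p = p,
      constrained = constrained,
      unconstrained = setdiff(seq_len(p), constrained),
      r = length(constrained), d = as.integer(d),
      x_names = x_names
    ),
    class = "rr_spec"
  )
}

#' @export
print.rr_spec <- function(x, ...) {
  cat("<rr_spec> family = ", x$family$name, ", p = ", x$p,
    ", r = ", x$r, " constrained, rank d = ", x$d, "\n",
    sep = ""
  )
  invisible(x)
}

# Column order used internally for X and for vec(beta): constrained block
# first, then unconstrained.
spec_order <- function(spec) c(spec$constrained, spec$unconstrained)

#' Parameter container for the partial reduced-rank model
#'
#' Bundles the intercept block `eta_bar1` (length `k1`), the constrained
#' coefficient matrix `beta1` (`k1 x r`), the unconstrained `beta2`
#' (`k1 x (p - r)`), the predictor-free block `eta_bar2` (length `k2`), and
#' optionally a factorization `beta1 = C %*% B` with `C` of dimension
#' `k1 x d` and `B` of dimension `d x r`.
#'
#' @param eta_bar1,eta_bar2 Numeric vectors.
#' @param beta1,beta2 Numeric matrices (use 0-column matrices for empty
#'   blocks).
#' @param C,B Optional factors with `beta1 = C %*% B`.
#' @return Object of class `rr_params`.
#' @export
rr_params <- function(eta_bar1, beta1, beta2, eta_bar2 = numeric(0),
                      C = NULL, B = NULL) {
  k1 <- length(eta_bar1)
  beta1 <- as.matrix(beta1)
  beta2 <- as.matrix(beta2)
  if (ncol(beta1) > 0L && nrow(beta1) != k1) {
    stop("`beta1` must have k1 rows.", call. = FALSE)
  }
  if (ncol(beta2) > 0L && nrow(beta2) != k1) {
    stop("`beta2` must have k1 rows.", call. = FALSE)
  }
  if (!is.null(C)) {
    stopifnot(!is.null(B))
    C <- as.matrix(C)
    B <- as.matrix(B)
    if (max(abs(beta1 - C %*% B)) > 1e-8 * max(1, max(abs(beta1)))) {
      stop("`C %*% B` does not reproduce `beta1`.", call. = FALSE)
    }
  }
  structure(
    list(
      eta_bar1 = as.numeric(eta_bar1), beta1 = beta1, beta2 = beta2,
      eta_bar2 = as.numeric(eta_bar2), C = C, B = B
    ),
    class = "rr_params"
  )
}

#' Pack and unpack parameter vectors
#'
#' The packed vector follows the convention
#' \eqn{\xi = (\bar\eta_1, \mathrm{vec}(\beta_1), \mathrm{vec}(\beta_2),
#' \bar\eta_2)} with column-stacking `vec`, for a total length of
#' `k1 + k1 * p + k2`. `pack_params()` and `unpack_params()` are mutual
#' inverses.
#'
#' @param params An [rr_params()] object.
#' @param xi Numeric vector of length `k1 + k1 * p + k2`.
#' @param spec An [rr_spec()] giving the dimensions.
#' @return `pack_params()` a numeric vector; `unpack_params()` an
#'   [rr_params()] object (without factors).
#' @export
pack_params <- function(params) {
  c(
    params$eta_bar1, as.numeric(params$beta1), as.numeric(params$beta2),
    params$eta_bar2
  )
}

#' @rdname pack_params
#' @export
unpack_params <- function(xi, spec) {
  k1 <- spec$family$k1
  k2 <- spec$family$k2
  r <- spec$r
  pu <- spec$p - r
  if (length(xi) != k1 + k1 * spec$p + k2) {
    stop("`xi` must have length k1 + k1*p + k2 = ", k1 + k1 * spec$p + k2, ".",
      call. = FALSE
    )
  }
  off <- k1
  beta1 <- matrix(xi[off + seq_len(k1 * r)], k1, r)
  off <- off + k1 * r
  beta2 <- matrix(xi[off + seq_len(k1 * pu)], k1, pu)
  off <- off + k1 * pu
  rr_params(
    eta_bar1 = xi[seq_len(k1)], beta1 = beta1, beta2 = beta2,
    eta_bar2 = xi[off + seq_len(k2)]
  )
}

#' Design operator F(x)
#'
#' Builds the `k x (k1*(p+1) + k2)` block matrix
#' \deqn{F(x) = \begin{pmatrix} (1, x^\top) \otimes I_{k_1} & 0 \\
#' 0 & I_{k_2} \end{pmatrix}}
#' so that `F(x) %*% pack_params(params)` equals the stacked natural
#' parameter \eqn{(\bar\eta_1 + \beta x, \ \bar\eta_2)}. `x` must be in the
#' internal predictor order (constrained block first); see [spec_reorder_x()].
#'
#' @param x Numeric predictor vector of length `p`, constrained block first.
#' @param spec An [rr_spec()].
#' @return A `k x (k1*(p+1) + k2)` matrix.
#' @export
build_F <- function(x, spec) {
  if (length(x) != spec$p) {
    stop("`x` must have length p = ", spec$p, ".", call. = FALSE)
  }
  k1 <- spec$family$k1
  k2 <- spec$family$k2
  top <- kronecker(matrix(c(1, x), nrow = 1L), diag(k1))
  if (k2 == 0L) {
    return(top)
  }
  rbind(
    cbind(top, matrix(0, k1, k2)),
    cbind(matrix(0, k2, ncol(top)), diag(k2))
  )
}

#' Reorder a predictor vector or matrix into the internal block order
#'
#' Puts the constrained columns first and the unconstrained ones after, the
#' order assumed by [build_F()], [pack_params()] and the fitting routines.
#'
#' @param x Vector of length `p` or matrix with `p` columns, in the original
#'   column order.
#' @param spec An [rr_spec()].
#' @return The reordered vector or matrix.
#' @export
spec_reorder_x <- function(x, spec) {
  ord <- spec_order(spec)
  if (is.matrix(x) || is.data.frame(x)) as.matrix(x)[, ord, drop = FALSE] else x[ord]
}

#' Natural parameter at a predictor value
#'
#' Evaluates \eqn{\eta_x = (\bar\eta_1 + \beta_1 x_1 + \beta_2 x_2,\
#' \bar\eta_2)} directly from the unpacked parameter blocks. Consistent with
#' `build_F(x, spec) %*% pack_params(params)` to machine precision.
#'
#' @inheritParams build_F
#' @param params An [rr_params()].
#' @return Numeric vector of length `k`.
#' @export
eta_of_x <- function(params, x, spec) {
  if (length(x) != spec$p) {
    stop("`x` must have length p = ", spec$p, ".", call. = FALSE)
  }
  x1 <- x[seq_len(spec$r)]
  x2 <- x[spec$r + seq_len(spec$p - spec$r)]
  e1 <- params$eta_bar1
  if (spec$r > 0L) e1 <- e1 + drop(params$beta1 %*% x1)
  if (spec$p - spec$r > 0L) e1 <- e1 + drop(params$beta2 %*% x2)
  c(e1, params$eta_bar2)
}

#' Count model parameters
#'
#' The unrestricted model has `k1 + k1*p + k2` parameters. The restricted
#' count follows the raw-factor convention — entries of
#' \eqn{\bar\eta_1, C, B, \beta_2, \bar\eta_2}:
#' `k1 + k1*d + d*r + k1*(p - r) + k2`. The factorization `beta1 = C %*% B`
#' is invariant to `(C, B) -> (C M, M^{-1} B)`, so the raw count exceeds the
#' number of identified parameters by `d^2`; [aic_rank_path()] subtracts that
#' redundancy when computing AIC.
#'
#' @param spec An [rr_spec()].
#' @param restricted Count the rank-restricted parametrization?
#' @return Integer count.
#' @export
count_parameters <- function(spec, restricted = FALSE) {
  k1 <- spec$family$k1
  k2 <- spec$family$k2
  if (!restricted) {
    return(k1 + k1 * spec$p + k2)
  }
  k1 + k1 * spec$d + spec$d * spec$r + k1 * (spec$p - spec$r) + k2
}
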