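#' Fit a partial reduced-rank multivariate GLM from a data frame
#'
#' Data-frame-first interface: picks the response and predictor columns out
#' of `data`, builds the model specification and dispatches to [fit_full()]
#' (when `rank` is `NULL`) or [fit_reduced()]. For the multinomial family
#' the response is a single column of integer labels `1..q`; for the other
#' families it is `q` numeric columns.
#'
#' @param data A data frame.
#' @param response Character: response column name(s).
#' @param constrained Character vector of rank-constrained predictor column
#'   names (may be empty for a fully unconstrained model).
#' @param rank Rank bound `d` for the constrained block, or `NULL` for the
#'   full-rank fit.
#' @param family Family name or an [rr_family()] object.
#' @param q Response dimension; inferred from the data when omitted
#'   (multinomial: the largest label).
#' @param sigma Known Gaussian standard deviation (optional).
#' @param ... Passed on to the fitting routine.
#' @return An `rr_fit`; use [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' sc <- workforce_scenario(n = 800, seed = 1)
#' d <- simulate_dataset(sc)$data
#' fit <- prrglm(d, "y",
#'   constrained = setdiff(names(d), c("y", "age30", "logedu1")), rank = 1
#' )
#' glance(fit)
#' @export
prrglm <- function(data, response, constrained = character(),
                   rank = NULL, family = "multinomial", q = NULL,
                   sigma = NULL, ...) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(response, constrained), names(data))
  if (length(missing_cols) > 0L) {
    stop("columns not in `data`: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!inherits(family, "rr_family")) {
    if (is.null(q)) {
      q <- if (family == "multinomial") {
        max(as.integer(data[[response[1L]]]))
      } else {
        length(response)
      }
    }
    family <- rr_family(family, q = q, sigma = sigma)
  }
  pred_names <- setdiff(names(data), response)
  X <- as.matrix(data[pred_names])
  Y <- if (family$name == "multinomial") {
    as.integer(data[[response[1L]]])
  } else {
    as.matrix(data[response])
  }
  spec <- rr_spec(family,
    p = length(pred_names),
    constrained = match(constrained, pred_names),
    d = rank, x_names = pred_names
  )
  if (is.null(rank) || spec$r == 0L) {
    fit_full(X, Y, spec, ...)
  } else {
    fit_reduced(X, Y, spec, ...)
  }
}

#' @export
print.rr_fit <- function(x, ...) {
  cat("<rr_fit> ", if (x$restricted) {
    paste0("rank-", x$spec$d, " restricted")
  } else {
    "full-rank"
  },
  " ", x$spec$family$name, " model\n",
  "  n = ", x$n, ", parameters = ",
  count_parameters(x$spec, restricted = x$restricted),
  if (x$restricted) paste0(" (", count_parameters(x$spec), " unrestricted)"),
  "\n  mean log-likelihood = ", format(x$loglik, digits = 7),
  ", ", if (x$converged) "converged" else "NOT converged",
  " in ", x$n_iter, " iterations\n",
  sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted partial reduced-rank GLM
#'
#' Returns the Wald coefficient table of [wald_table()] as a tibble, one
#' row per coordinate of \eqn{\xi} (every entry of \eqn{\beta_1 = CB}
#' included).
#'
#' @param x An `rr_fit`.
#' @param cov Optional [avar_reduced()] covariance.
#' @param level Confidence level.
#' @param ... Unused.
#' @return A tibble; see [wald_table()].
#' @method tidy rr_fit
#' @export
tidy.rr_fit <- function(x, cov = NULL, level = 0.95, ...) {
  wald_table(x, cov = cov, level = level)
}

#' Glance at a fitted partial reduced-rank GLM
#'
#' @param x An `rr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `logLik` (total), `df` (identified
#'   parameters), `AIC`, `rank`, `restricted`, `n_iter`, `converged`.
#' @method glance rr_fit
#' @export
glance.rr_fit <- function(x, ...) {
  df <- if (x$restricted) {
    count_parameters(x$spec, restricted = TRUE) - x$spec$d^2
  } else {
    count_parameters(x$spec)
  }
  tibble::tibble(
    n = x$n,
    logLik = x$loglik_total,
    df = df,
    AIC = -2 * x$loglik_total + 2 * df,
    rank = if (x$restricted) x$spec$d else min(x$spec$family$k1, max(x$spec$r, 1L)),
    restricted = x$restricted,
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Coefficient plot for a fitted model
#'
#' Dot-and-interval plot of the coefficient estimates with Wald confidence
#' intervals, faceted by response contrast. Intercepts and dispersion
#' coordinates are dropped.
#'
#' @param object An `rr_fit`.
#' @param level Confidence level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rr_fit
#' @export
autoplot.rr_fit <- function(object, level = 0.95, ...) {
  tab <- wald_table(object, level = level)
  tab <- dplyr::filter(
    tab,
    !(.data$term %in% "(Intercept)"), .data$response != "(free)"
  )
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = .data$estimate, y = .data$term,
      xmin = .data$conf.low, xmax = .data$conf.high
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~response) +
    ggplot2::labs(
      x = "coefficient (with Wald CI)", y = NULL,
      title = if (object$restricted) {
        paste0("Rank-", object$spec$d, " restricted fit")
      } else {
        "Full-rank fit"
      }
    )
}

#' Log-likelihood trace plot
#'
#' The mean log-likelihood after each (outer) iteration; nondecreasing by
#' construction of the step-halved ascent.
#'
#' @param fit An `rr_fit`.
#' @return A ggplot object.
#' @export
plot_loglik_trace <- function(fit) {
  df <- tibble::tibble(
    iteration = seq_along(fit$loglik_trace),
    loglik = fit$loglik_trace
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "mean log-likelihood")
}

#' AIC path plot
#'
#' @param object An [aic_rank_path()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rr_rank_path
#' @export
autoplot.rr_rank_path <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rank, .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red", `FALSE` = "black"), guide = "none"
    ) +
    ggplot2::labs(x = "rank d", y = "AIC")
}

#' @importFrom rlang .data
NULL
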