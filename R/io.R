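#' Read a predictor/response dataset from CSV
#'
#' Reads RFC-4180 CSVs with header rows: `path_x` holds the numeric
#' predictor table and `path_y` the response — a single column of integer
#' category labels `1..q` for the multinomial family, or a `q`-column
#' numeric table otherwise. Multinomial labels are expanded internally to
#' indicator sufficient statistics at fit time; a category absent from the
#' data triggers a warning.
#'
#' @param path_x,path_y CSV file paths.
#' @param family An [rr_family()].
#' @return A list with `X` (named numeric matrix) and `Y` (integer labels
#'   or numeric matrix).
#' @export
read_dataset <- function(path_x, path_y, family) {
  stopifnot(inherits(family, "rr_family"))
  # base read.csv: correctly-rounded double parsing, so a write/read
  # round-trip of readr::write_csv output is bitwise exact
  xdf <- utils::read.csv(path_x, check.names = FALSE)
  ydf <- utils::read.csv(path_y, check.names = FALSE)
  if (nrow(xdf) != nrow(ydf)) {
    stop("row-count mismatch: ", path_x, " has ", nrow(xdf), " rows but ",
      path_y, " has ", nrow(ydf), ".",
      call. = FALSE
    )
  }
  bad <- names(xdf)[!vapply(xdf, is.numeric, logical(1))]
  if (length(bad) > 0L) {
    stop("non-numeric predictor column ", sQuote(bad[1L]), ".", call. = FALSE)
  }
  X <- as.matrix(xdf)
  if (family$name == "multinomial") {
    if (ncol(ydf) != 1L) {
      stop("multinomial responses must be a single column of labels 1..",
        family$q, ".",
        call. = FALSE
      )
    }
    lab <- ydf[[1L]]
    if (!is.numeric(lab) || any(lab != round(lab)) ||
      any(lab < 1 | lab > family$q)) {
      bad_row <- which(!is.numeric(lab) | lab != round(lab) |
        lab < 1 | lab > family$q)[1L]
      stop("unknown category label at row ", bad_row,
        "; labels must be integers in 1..", family$q, ".",
        call. = FALSE
      )
    }
    lab <- as.integer(lab)
    counts <- tabulate(lab, nbins = family$q)
    if (any(counts == 0L)) {
      warning("response categories with no observations: ",
        paste(which(counts == 0L), collapse = ", "),
        call. = FALSE
      )
    }
    return(list(X = X, Y = lab))
  }
  if (ncol(ydf) != family$q) {
    stop("response table must have q = ", family$q, " columns.",
      call. = FALSE
    )
  }
  if (!all(vapply(ydf, is.numeric, logical(1)))) {
    stop("non-numeric response column.", call. = FALSE)
  }
  list(X = X, Y = as.matrix(ydf))
}

#' Write a simulated dataset to CSV
#'
#' Inverse of [read_dataset()]: the predictors to `path_x`, the responses
#' (labels or `q`-column table) to `path_y`.
#'
#' @param X Predictor matrix with column names.
#' @param Y Response labels or matrix.
#' @param path_x,path_y Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(X, Y, path_x, path_y) {
  readr::write_csv(tibble::as_tibble(X), path_x, progress = FALSE)
  ydf <- if (is.matrix(Y)) {
    if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
    tibble::as_tibble(Y)
  } else {
    tibble::tibble(y = Y)
  }
  readr::write_csv(ydf, path_y, progress = FALSE)
  invisible(c(path_x, path_y))
}

fmt3 <- function(x) formatC(x, digits = 3L, format = "f")

#' Write a coefficient report
#'
#' Writes the Wald table of a converged fit in two forms: a plain CSV at
#' `path`, and a compact text report alongside (extension `.txt`) with one
#' row per predictor, one column block per response contrast, standard
#' errors in parentheses under each estimate and a star for unadjusted
#' 5%-level significance — numbers formatted to 3 decimals. Re-running with
#' identical inputs produces identical bytes.
#'
#' @param fit A converged `rr_fit`.
#' @param path Output CSV path.
#' @param cov Optional [avar_reduced()] covariance.
#' @param level Confidence level for the table.
#' @return Invisibly, the Wald table tibble.
#' @export
write_report <- function(fit, path, cov = NULL, level = 0.95) {
  tab <- wald_table(fit, cov = cov, level = level)
  readr::write_csv(
    dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6))),
    path,
    progress = FALSE
  )
  wide <- tab |>
    dplyr::mutate(
      cell = paste0(fmt3(.data$estimate), .data$signif,
        " (", fmt3(.data$std.error), ")")
    ) |>
    dplyr::select("term", "response", "cell") |>
    tidyr::pivot_wider(names_from = "response", values_from = "cell")
  txt_path <- sub("\\.csv$", ".txt", path)
  if (identical(txt_path, path)) txt_path <- paste0(path, ".txt")
  con <- file(txt_path, open = "wb") # binary mode: byte-identical reruns
  on.exit(close(con))
  writeLines(c(
    paste0(
      "Partial reduced-rank GLM coefficient report (",
      if (fit$restricted) paste0("rank ", fit$spec$d) else "full rank",
      ", n = ", fit$n, ")"
    ),
    "Standard errors in parentheses; * marks 5%-level significance.",
    "",
    utils::capture.output(print(as.data.frame(wide), row.names = FALSE))
  ), con = con)
  invisible(tab)
}
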