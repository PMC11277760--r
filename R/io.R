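#' Read study, auxiliary and instrument columns from a CSV table
#'
#' Strict reader for the package's rectangular input format: comma-separated,
#' header required, `.` decimal. Missing `z_columns` default to the
#' corresponding `x_columns` (exogenous variables are their own instruments).
#' Rows containing a missing value in any used column are rejected with their
#' row numbers; non-numeric cells and absent columns raise typed parse errors.
#'
#' @param path CSV file path.
#' @param y_column name of the study-variable column.
#' @param x_columns character vector of auxiliary column names.
#' @param z_columns optional character vector of instrument column names, same
#'   length as `x_columns` (exact identification); `NULL` means `Z = X`.
#' @return List with `y` (numeric vector), `X`, `Z` (numeric matrices) and
#'   `n_rows`.
#' @export
read_table <- function(path, y_column = "y", x_columns, z_columns = NULL) {
  if (!file.exists(path))
    stop_ivcalib("ivcalib_parse_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(z_columns) && length(z_columns) != length(x_columns))
    stop_ivcalib("ivcalib_not_supported",
                 "z_columns must pair one instrument with each x column (exact identification)")
  used <- c(y_column, x_columns, z_columns)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols))
    stop_ivcalib("ivcalib_parse_error",
                 sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) stop_ivcalib("ivcalib_parse_error", "table has no data rows")
  for (cl in used) {
    v <- df[[cl]]
    if (is.character(v) || is.factor(v)) {
      suppress <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(suppress) & !is.na(v) & trimws(as.character(v)) != "" &
                     toupper(trimws(as.character(v))) != "NA")
      if (length(bad))
        stop_ivcalib("ivcalib_parse_error",
                     sprintf("non-numeric value in column '%s', row(s) %s",
                             cl, paste(utils::head(bad, 5), collapse = ", ")))
      df[[cl]] <- suppress
    }
    if (!is.numeric(df[[cl]]))
      stop_ivcalib("ivcalib_parse_error", sprintf("column '%s' is not numeric", cl))
  }
  na_rows <- which(rowSums(is.na(df[, used, drop = FALSE])) > 0)
  if (length(na_rows)) {
    na_cols <- used[colSums(is.na(df[na_rows, used, drop = FALSE])) > 0]
    stop_ivcalib("ivcalib_parse_error",
                 sprintf("missing value(s) in row(s) %s (column(s) %s)",
                         paste(utils::head(na_rows, 10), collapse = ", "),
                         paste(na_cols, collapse = ", ")))
  }
  X <- as.matrix(df[, x_columns, drop = FALSE])
  Z <- if (is.null(z_columns)) X else as.matrix(df[, z_columns, drop = FALSE])
  list(y = df[[y_column]], X = X, Z = Z, n_rows = nrow(df))
}

#' Build an estimation request
#'
#' Describes one estimate-from-data run. In `population_known` mode the table
#' is the whole universe: totals are computed from it, an SRSWOR sample of
#' size `n` is drawn with `seed`, and the reports include the true-total
#' errors. In `sample_with_totals` mode the table is the sample itself, the
#' auxiliary population totals must be supplied, and design weights come from
#' the stated population size `N`.
#'
#' @param table_path CSV path.
#' @param mode `"population_known"` or `"sample_with_totals"`.
#' @param y_column,x_columns,z_columns column-role assignment; `z_columns`
#'   pairs one instrument with each auxiliary (endogenous or not) and defaults
#'   to the auxiliaries themselves.
#' @param totals population totals `t_x` (required in `sample_with_totals`
#'   mode, one per x column).
#' @param n sample size (required in `population_known` mode).
#' @param N population size (required in `sample_with_totals` mode).
#' @param estimators subset of `c("HT", "GREG", "IVC", "MBIVC")`; MBIVC is
#'   only available in `population_known` mode, where the non-sample totals
#'   are computable.
#' @param seed integer seed for the sample draw.
#' @return An object of class `estimation_request`.
#' @export
estimation_request <- function(table_path,
                               mode = c("population_known", "sample_with_totals"),
                               y_column = "y", x_columns, z_columns = NULL,
                               totals = NULL, n = NULL, N = NULL,
                               estimators = c("HT", "GREG", "IVC"),
                               seed = 1L) {
  mode <- match.arg(mode)
  estimators <- match.arg(estimators, c("HT", "GREG", "IVC", "MBIVC"), several.ok = TRUE)
  if (!is.null(z_columns) && length(z_columns) != length(x_columns))
    stop_ivcalib("ivcalib_not_supported",
                 "z_columns must pair one instrument with each x column (exact identification)")
  if (mode == "sample_with_totals") {
    if (is.null(totals) || length(totals) != length(x_columns))
      stop_ivcalib("ivcalib_config_error",
                   "sample_with_totals mode requires one total per x column")
    if (is.null(N)) stop_ivcalib("ivcalib_config_error",
                                 "sample_with_totals mode requires the population size N")
    if ("MBIVC" %in% estimators)
      stop_ivcalib("ivcalib_config_error",
                   "MBIVC needs the non-sample auxiliary totals, available only in population_known mode")
  } else if (is.null(n)) {
    stop_ivcalib("ivcalib_config_error", "population_known mode requires the sample size n")
  }
  structure(list(table_path = table_path, mode = mode, y_column = y_column,
                 x_columns = x_columns, z_columns = z_columns,
                 totals = if (!is.null(totals)) as.numeric(totals),
                 n = if (!is.null(n)) as.integer(n),
                 N = if (!is.null(N)) as.integer(N),
                 estimators = estimators, seed = as.integer(seed)),
            class = "estimation_request")
}

#' Run an estimation request
#'
#' Executes the estimate-from-data path and returns one report record per
#' estimator: estimate, variance (where defined), slope, constraint gap, and
#' — when the true total is known — the error. Use [write_report_json()] to
#' serialize.
#'
#' @param request an [estimation_request()].
#' @param log optional function called with one message line per estimator
#'   (e.g. `message`); `NULL` disables logging.
#' @return List of class `estimation_report` with elements `mode`, `n`, `N`,
#'   `t_y` (when known), `seed`, and `results` (one record per estimator).
#' @export
run_estimate <- function(request, log = NULL) {
  stopifnot(inherits(request, "estimation_request"))
  tab <- read_table(request$table_path, request$y_column,
                    request$x_columns, request$z_columns)
  p <- ncol(tab$X)
  if (request$mode == "population_known") {
    N <- tab$n_rows
    if (request$n > N)
      stop_ivcalib("ivcalib_invalid_sample_size",
                   sprintf("n = %d exceeds the %d table rows", request$n, N))
    pop <- finite_population(tab$y, tab$X, tab$Z,
                             endogenous_idx = which(vapply(seq_len(p), function(j)
                               !isTRUE(all.equal(tab$Z[, j], tab$X[, j])), logical(1))))
    s <- draw_srswor(pop, request$n, seed = request$seed)
    idx <- s$indices
    y_s <- pop$y[idx]; X_s <- pop$X[idx, , drop = FALSE]; Z_s <- pop$Z[idx, , drop = FALSE]
    t_x <- pop$t_x; t_y <- pop$t_y
    t_xns <- t_x - colSums(X_s)
  } else {
    N <- request$N
    n <- tab$n_rows
    s <- survey_sample(seq_len(n), N = N, pi = n / N)
    y_s <- tab$y; X_s <- tab$X; Z_s <- tab$Z
    t_x <- request$totals; t_y <- NULL; t_xns <- NULL
  }
  results <- lapply(request$estimators, function(est) {
    rec <- switch(est,
      HT = {
        te <- ht_total(s, y_s)
        v <- if (s$n >= 2) ht_variance(s, y_s)
        list(estimator = "HT", estimate = te$estimate, variance = v,
             beta = NULL, constraint_gap = NULL)
      },
      GREG = {
        te <- greg_total(s, y_s, X_s, t_x)
        cw <- chisq_calibration_weights(s, X_s, t_x)
        list(estimator = "GREG", estimate = te$estimate, variance = NULL,
             beta = te$beta, constraint_gap = cw$constraint_gap)
      },
      IVC = {
        te <- ivc_total(s, y_s, X_s, Z_s, t_x)
        v <- if (s$n >= 2) ivc_asymptotic_variance(s, y_s, X_s, Z_s, t_x)
        cw <- ivc_weights(s, X_s, Z_s, t_x)
        list(estimator = "IVC", estimate = te$estimate, variance = v,
             beta = te$beta, constraint_gap = cw$constraint_gap)
      },
      MBIVC = {
        te <- mbivc_total(y_s, X_s, Z_s, t_xns)
        cw <- mbivc_weights(X_s, Z_s, t_xns)
        list(estimator = "MBIVC", estimate = te$estimate,
             variance = mbivc_mse(y_s, X_s, Z_s, t_xns),
             beta = te$beta, constraint_gap = cw$constraint_gap)
      })
    rec$n <- s$n; rec$N <- N
    if (!is.null(t_y)) rec$error <- rec$estimate - t_y
    if (!is.null(log))
      log(sprintf("[%s] estimate=%.6g variance=%s constraint_gap=%s",
                  rec$estimator, rec$estimate,
                  if (is.null(rec$variance)) "NA" else sprintf("%.6g", rec$variance),
                  if (is.null(rec$constraint_gap)) "NA" else sprintf("%.3g", rec$constraint_gap)))
    rec
  })
  structure(list(mode = request$mode, n = s$n, N = N, t_y = t_y,
                 seed = request$seed, results = results),
            class = "estimation_report")
}

#' @export
print.estimation_report <- function(x, ...) {
  cat(sprintf("Estimation report (%s mode, n = %d, N = %d)\n", x$mode, x$n, x$N))
  if (!is.null(x$t_y)) cat(sprintf("  true total t_y = %.6g\n", x$t_y))
  for (r in x$results)
    cat(sprintf("  %-6s estimate %.6g%s\n", r$estimator, r$estimate,
                if (!is.null(r$error)) sprintf("  (error %+.6g)", r$error) else ""))
  invisible(x)
}

#' Serialize an estimation report to JSON
#'
#' @param report an `estimation_report` from [run_estimate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "estimation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
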