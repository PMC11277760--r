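#' Construct a finite population
#'
#' Bundles the study variable, the auxiliary matrix \eqn{X}, the instrument
#' matrix \eqn{Z} and the known population totals into a single object that
#' serves as ground truth for sampling and simulation. Column \eqn{j} of
#' \eqn{Z} must equal column \eqn{j} of \eqn{X} for every exogenous variable:
#' only endogenous auxiliaries are replaced by an instrument, so \eqn{Z} keeps
#' the dimension of \eqn{X} (exact identification).
#'
#' @param y numeric vector of length N, the study variable.
#' @param X numeric N x p matrix of auxiliary variables.
#' @param Z numeric N x p matrix of instruments; defaults to `X`
#'   (all variables exogenous).
#' @param endogenous_idx integer vector of column indices (1-based) flagged
#'   endogenous; columns of `Z` outside this set must be identical to the
#'   corresponding columns of `X`.
#' @return An object of class `finite_population`: a list with elements
#'   `y`, `X`, `Z`, `t_y` (= `sum(y)`), `t_x` (= `colSums(X)`),
#'   `endogenous_idx`, `N`, `p`.
#' @examples
#' pop <- finite_population(y = 1:5, X = cbind(x1 = c(2, 4, 6, 8, 10)))
#' pop$t_y
#' @export
finite_population <- function(y, X, Z = X, endogenous_idx = integer(0)) {
  y <- as.numeric(y)
  X <- as_numeric_matrix(X, "X")
  Z <- as_numeric_matrix(Z, "Z")
  N <- length(y)
  p <- ncol(X)
  if (N < 1L || p < 1L)
    stop_ivcalib("ivcalib_config_error", "population must have N >= 1 units and p >= 1 auxiliary variables")
  if (nrow(X) != N || nrow(Z) != N || ncol(Z) != p)
    stop_ivcalib("ivcalib_config_error", "y, X and Z must have matching dimensions (exact identification: Z is N x p)")
  endogenous_idx <- sort(unique(as.integer(endogenous_idx)))
  if (length(endogenous_idx) && (min(endogenous_idx) < 1L || max(endogenous_idx) > p))
    stop_ivcalib("ivcalib_config_error", "endogenous_idx out of range")
  exo <- setdiff(seq_len(p), endogenous_idx)
  if (length(exo) && !isTRUE(all.equal(Z[, exo, drop = FALSE], X[, exo, drop = FALSE],
                                       check.attributes = FALSE)))
    stop_ivcalib("ivcalib_config_error",
                 "columns of Z for exogenous variables must equal the corresponding columns of X")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(p))
  structure(list(y = y, X = X, Z = Z,
                 t_y = sum(y), t_x = stats::setNames(colSums(X), colnames(X)),
                 endogenous_idx = endogenous_idx, N = N, p = p),
            class = "finite_population")
}

#' @export
print.finite_population <- function(x, ...) {
  cat(sprintf("Finite population: N = %d units, p = %d auxiliary variables\n", x$N, x$p))
  cat(sprintf("  endogenous columns: %s\n",
              if (length(x$endogenous_idx)) paste(x$endogenous_idx, collapse = ", ") else "none"))
  cat(sprintf("  t_y = %.6g\n", x$t_y))
  invisible(x)
}

#' Write / read a population table
#'
#' The on-disk form is a plain CSV with header `y, x1..xp, z1..zp` plus a JSON
#' sidecar holding the totals (`t_x`, `t_y`). Instrument columns equal to their
#' auxiliary column are still written, so the file round-trips exactly. On
#' reading, absent `z` columns default to the matching `x` columns.
#'
#' @param pop a `finite_population`.
#' @param path CSV path; the totals sidecar is written to `paste0(path, ".totals.json")`
#'   unless `totals_path` is given.
#' @param totals_path optional explicit sidecar path.
#' @return `write_population_csv` returns `path` invisibly;
#'   `read_population_csv` returns a `finite_population`.
#' @export
write_population_csv <- function(pop, path, totals_path = paste0(path, ".totals.json")) {
  stopifnot(inherits(pop, "finite_population"))
  df <- data.frame(y = pop$y, check.names = FALSE)
  Xd <- as.data.frame(pop$X); names(Xd) <- paste0("x", seq_len(pop$p))
  Zd <- as.data.frame(pop$Z); names(Zd) <- paste0("z", seq_len(pop$p))
  utils::write.csv(cbind(df, Xd, Zd), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(t_x = unname(pop$t_x), t_y = pop$t_y,
                            endogenous_idx = pop$endogenous_idx),
                       totals_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path, totals_path = paste0(path, ".totals.json")) {
  df <- utils::read.csv(path, check.names = FALSE)
  p <- sum(grepl("^x[0-9]+$", names(df)))
  zc <- paste0("z", seq_len(p))
  if (!all(zc %in% names(df))) zc <- NULL
  tab <- read_table(path, y_column = "y",
                    x_columns = paste0("x", seq_len(p)), z_columns = zc)
  endo <- integer(0)
  if (file.exists(totals_path)) {
    side <- jsonlite::read_json(totals_path, simplifyVector = TRUE)
    if (!is.null(side$endogenous_idx)) endo <- as.integer(side$endogenous_idx)
  }
  finite_population(tab$y, tab$X, tab$Z, endogenous_idx = endo)
}
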