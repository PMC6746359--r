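#' Assemble a validated observational dataset
#'
#' Container for unit-level observational data: one outcome, one binary
#' treatment indicator and a matrix of pre-treatment covariates per unit.
#' Validation enforces the data-level preconditions for ATE estimation under
#' strong ignorability: at least two units, a strictly binary treatment with
#' both arms non-empty (common support at the crudest level), and no missing
#' values.
#'
#' @param y numeric outcome vector (e.g. collision counts or differenced
#'   before/after counts).
#' @param d treatment indicator, coded 0/1.
#' @param X numeric matrix or data frame of pre-treatment covariates,
#'   one row per unit. May have zero columns.
#' @param column_names optional covariate names; defaults to `colnames(X)`.
#' @param outcome_name,treatment_name labels used when writing the dataset
#'   back to disk.
#'
#' @return An object of class `obs_dataset`: a list with elements `y`, `d`,
#'   `X` (numeric matrix with column names) and `n`.
#' @seealso [load_dataset()], [write_dataset()], [check_overlap()]
#' @export
observational_dataset <- function(y, d, X = NULL, column_names = NULL,
                                  outcome_name = "y", treatment_name = "d") {
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.null(column_names)) colnames(X) <- column_names
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- length(y)
  if (n < 2) .stopf("need at least 2 units, got %d", n)
  if (length(d) != n || nrow(X) != n) {
    .stopf("y, d and X must describe the same units (lengths %d, %d, %d)",
           n, length(d), nrow(X))
  }
  if (anyNA(y) || anyNA(d) || anyNA(X)) .stopf("missing values are not allowed in a validated dataset")
  d <- as.numeric(d)
  if (!all(d %in% c(0, 1))) .stopf("treatment indicator must contain only 0 and 1")
  if (sum(d) == 0 || sum(d) == n) {
    .stopf("common support violated: dataset needs at least one treated and one control unit")
  }
  structure(list(y = y, d = d, X = X, n = n,
                 outcome_name = outcome_name, treatment_name = treatment_name),
            class = "obs_dataset")
}

#' @export
print.obs_dataset <- function(x, ...) {
  cat(sprintf("Observational dataset: %d units (%d treated, %d control), %d covariate(s)\n",
              x$n, sum(x$d), x$n - sum(x$d), ncol(x$X)))
  if (ncol(x$X) > 0) cat("covariates:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Keep a subset of units
#'
#' @param data an [observational_dataset()].
#' @param idx integer or logical index of units to retain.
#' @return A new `obs_dataset` restricted to the selected units.
#' @export
subset_units <- function(data, idx) {
  stopifnot(inherits(data, "obs_dataset"))
  observational_dataset(data$y[idx], data$d[idx], data$X[idx, , drop = FALSE],
                        outcome_name = data$outcome_name,
                        treatment_name = data$treatment_name)
}

#' Load an observational dataset from a delimited file
#'
#' Reads a comma-separated table (header row required, `.` decimal) and
#' assembles a validated [observational_dataset()]. The treatment column must
#' either already be coded 0/1 or be mapped explicitly via `treatment_map`;
#' no silent coding inference is performed. Rows with missing outcome or
#' treatment are dropped with a warning; missing covariate values are an
#' error.
#'
#' @param path path to a CSV file.
#' @param outcome,treatment names of the outcome and treatment columns.
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param treatment_map optional list with elements `treated` and `control`
#'   giving the raw values mapped to 1 and 0.
#' @param quiet suppress the ingestion report message.
#'
#' @return An `obs_dataset`.
#' @export
load_dataset <- function(path, outcome = "y", treatment = "d",
                         covariates = NULL, treatment_map = NULL,
                         quiet = FALSE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(covariates)) covariates <- setdiff(names(tab), c(outcome, treatment))
  missing_cols <- setdiff(c(outcome, treatment, covariates), names(tab))
  if (length(missing_cols) > 0) {
    .stopf("schema error: column(s) %s not present in %s",
           paste(missing_cols, collapse = ", "), path)
  }
  keep <- !(is.na(tab[[outcome]]) | is.na(tab[[treatment]]))
  if (any(!keep)) {
    warning(sprintf("dropped %d row(s) with missing outcome or treatment", sum(!keep)),
            call. = FALSE)
    tab <- tab[keep, , drop = FALSE]
  }
  d_raw <- tab[[treatment]]
  if (!is.null(treatment_map)) {
    if (!all(c("treated", "control") %in% names(treatment_map))) {
      .stopf("treatment_map must name 'treated' and 'control' values")
    }
    unknown <- !(d_raw %in% c(treatment_map$treated, treatment_map$control))
    if (any(unknown)) {
      .stopf("coding error: treatment values %s not covered by treatment_map",
             paste(unique(d_raw[unknown]), collapse = ", "))
    }
    d <- as.numeric(d_raw %in% treatment_map$treated)
  } else {
    if (!all(d_raw %in% c(0, 1))) {
      .stopf("coding error: treatment column '%s' is not coded 0/1; supply treatment_map",
             treatment)
    }
    d <- as.numeric(d_raw)
  }
  Xdf <- tab[, covariates, drop = FALSE]
  non_num <- covariates[!vapply(Xdf, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    .stopf("covariate column(s) %s are not numeric; encode them (e.g. dummies) before loading",
           paste(non_num, collapse = ", "))
  }
  X <- as.matrix(Xdf)
  if (length(covariates) > 0 && anyNA(X)) {
    .stopf("missing covariate values in %s; impute or drop before loading", path)
  }
  out <- observational_dataset(tab[[outcome]], d, X,
                               outcome_name = outcome, treatment_name = treatment)
  if (!quiet) {
    message(sprintf("loaded %d units (%d treated) with %d covariate(s) from %s",
                    out$n, sum(out$d), ncol(out$X), path))
  }
  out
}

#' Write an observational dataset to CSV
#'
#' Mirrors the input dialect of [load_dataset()]: comma separated, header row,
#' `.` decimal.
#'
#' @param data an `obs_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "obs_dataset"))
  tab <- data.frame(data$y, data$d, check.names = FALSE)
  names(tab) <- c(data$outcome_name, data$treatment_name)
  if (ncol(data$X) > 0) tab <- cbind(tab, as.data.frame(data$X))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check common support of the estimated propensity score
#'
#' The common-support assumption requires 0 < Pr(D = 1 | X) < 1 over the
#' covariate distribution. This diagnostic retains units whose estimated
#' propensity lies within `bounds` and reports how many treated/control units
#' fall outside.
#'
#' @param data an `obs_dataset`.
#' @param ps vector of estimated propensity scores in (0, 1).
#' @param bounds length-2 numeric `(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return A list of class `overlap_check` with `retained` (integer indices),
#'   `n_dropped_treated`, `n_dropped_control` and `bounds`.
#' @export
check_overlap <- function(data, ps, bounds = c(0.05, 0.95)) {
  stopifnot(inherits(data, "obs_dataset"))
  .check_prob_vector(ps, n = data$n)
  if (length(bounds) != 2 || !is.numeric(bounds) ||
      bounds[1] < 0 || bounds[2] > 1 || bounds[1] >= bounds[2]) {
    .stopf("bounds must be numeric (lo, hi) with 0 <= lo < hi <= 1")
  }
  inside <- ps >= bounds[1] & ps <= bounds[2]
  if (!any(inside)) .stopf("empty support: all units fall outside bounds (%g, %g)",
                           bounds[1], bounds[2])
  structure(list(retained = which(inside),
                 n_dropped_treated = sum(!inside & data$d == 1),
                 n_dropped_control = sum(!inside & data$d == 0),
                 bounds = bounds),
            class = "overlap_check")
}

#' @export
print.overlap_check <- function(x, ...) {
  cat(sprintf("Overlap check on [%g, %g]: %d retained, dropped %d treated / %d control\n",
              x$bounds[1], x$bounds[2], length(x$retained),
              x$n_dropped_treated, x$n_dropped_control))
  invisible(x)
}
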