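#' Balanced country-year panel datasets
#'
#' A `panel_dataset` is a wide-format balanced panel: one row per
#' (country, year) combination and one numeric column per variable. Every
#' combination of country, year and variable must be present and finite,
#' and years must form the same contiguous run for every country. Rows are
#' kept in canonical order (country lexicographic, then year ascending) so
#' that every downstream fit is reproducible byte for byte regardless of
#' the input row order.
#'
#' @param df A data.frame with a character `country` column, an integer
#'   `year` column, and one numeric column per panel variable.
#' @return An object of class `panel_dataset`: the canonicalised
#'   data.frame with attributes `countries`, `years` and `variable_names`.
#' @examples
#' df <- expand.grid(country = c("AA", "BB"), year = 2000:2002,
#'                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
#' df$x <- seq_len(nrow(df))
#' ds <- panel_dataset(df)
#' variable_names(ds)
#' @export
panel_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("country", "year") %in% names(df)))
    stop("panel data must have 'country' and 'year' columns")
  df$country <- as.character(df$country)
  if (any(is.na(suppressWarnings(as.integer(df$year)))))
    stop("'year' column must be integer-valued")
  df$year <- as.integer(df$year)
  vars <- setdiff(names(df), c("country", "year"))
  if (anyDuplicated(vars))
    stop("variable names must be unique")
  for (v in vars) {
    if (!is.numeric(df[[v]]))
      stop(sprintf("column '%s' is not numeric", v))
    bad <- which(!is.finite(df[[v]]))
    if (length(bad))
      stop(sprintf("missing or non-finite value in column '%s', row %d (country %s, year %d)",
                   v, bad[1], df$country[bad[1]], df$year[bad[1]]))
  }
  key <- paste(df$country, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate (country, year) row: %s", sub("\r", ", ", d)))
  }
  countries <- sort(unique(df$country))
  years <- sort(unique(df$year))
  if (nrow(df) != length(countries) * length(years)) {
    have <- split(df$year, df$country)
    for (cc in countries) {
      miss <- setdiff(years, have[[cc]])
      if (length(miss))
        stop(sprintf("unbalanced panel: country %s is missing year %d", cc, miss[1]))
    }
    stop("unbalanced panel")
  }
  if (length(years) > 1 && !all(diff(years) == 1L))
    stop("years must be contiguous")
  df <- df[order(df$country, df$year), c("country", "year", vars), drop = FALSE]
  rownames(df) <- NULL
  structure(df, countries = countries, years = years,
            variable_names = vars, class = c("panel_dataset", "data.frame"))
}

#' @rdname panel_dataset
#' @param ds A `panel_dataset`.
#' @export
variable_names <- function(ds) attr(ds, "variable_names")

#' @rdname panel_dataset
#' @export
panel_countries <- function(ds) attr(ds, "countries")

#' @rdname panel_dataset
#' @export
panel_years <- function(ds) attr(ds, "years")

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("Balanced panel: %d countries x %d years x %d variables (%d values)\n",
              length(panel_countries(x)), length(panel_years(x)),
              length(variable_names(x)),
              length(panel_countries(x)) * length(panel_years(x)) * length(variable_names(x))))
  cat("Variables:", paste(variable_names(x), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a balanced panel from a wide-format CSV file
#'
#' Expects a comma-separated UTF-8 file with a mandatory header
#' `country,year,<var1>,...`; `country` is a string, `year` an integer and
#' all other columns real-valued. The input must describe a fully balanced
#' panel; unbalanced or duplicated rows are a hard error naming the
#' offending cell.
#'
#' @param path Path to the CSV file.
#' @return A [panel_dataset].
#' @seealso [write_panel_csv()]
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = NA, fileEncoding = "UTF-8")
  if (!all(c("country", "year") %in% names(df)))
    stop(sprintf("'%s': header must start with country,year", path))
  for (v in setdiff(names(df), "country")) {
    if (is.character(df[[v]])) {
      num <- suppressWarnings(as.numeric(df[[v]]))
      bad <- which(is.na(num) & !is.na(df[[v]]))
      if (length(bad))
        stop(sprintf("'%s': non-numeric cell '%s' in column '%s', data row %d",
                     path, df[[v]][bad[1]], v, bad[1]))
      df[[v]] <- num
    }
  }
  panel_dataset(df)
}

#' Write a balanced panel to a wide-format CSV file
#'
#' One row per (country, year) in canonical order, variables in
#' `variable_names(ds)` order. Numeric cells are written with 17
#' significant digits so that a read/write round trip is cell-exact.
#'
#' @param ds A [panel_dataset].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel_csv <- function(ds, path) {
  stopifnot(inherits(ds, "panel_dataset"))
  vars <- variable_names(ds)
  header <- paste(c("country", "year", vars), collapse = ",")
  cells <- lapply(vars, function(v) sprintf("%.17g", ds[[v]]))
  rows <- do.call(paste, c(list(ds$country, ds$year), cells, sep = ","))
  writeLines(c(header, rows), con = path, useBytes = TRUE)
  invisible(path)
}

#' Natural-log transform of selected panel variables
#'
#' Replaces each selected variable by its natural logarithm, leaving the
#' others untouched. The log rescaling is the standard pre-processing step
#' for macro panels whose dispersion grows with the level (income,
#' expenditure shares); it also places knots of downstream spline fits on
#' the log scale. Non-positive values are a hard error (no offset is
#' applied) because the transform is undefined there.
#'
#' @param ds A [panel_dataset].
#' @param vars Character vector of variable names to transform.
#' @return A new [panel_dataset] with the selected columns logged.
#' @export
log_transform <- function(ds, vars) {
  stopifnot(inherits(ds, "panel_dataset"))
  unknown <- setdiff(vars, variable_names(ds))
  if (length(unknown))
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")))
  out <- as.data.frame(ds)
  for (v in vars) {
    bad <- which(out[[v]] <= 0)
    if (length(bad))
      stop(sprintf("log_transform: non-positive value %g for (country %s, year %d, variable %s)",
                   out[[v]][bad[1]], out$country[bad[1]], out$year[bad[1]], v))
    out[[v]] <- log(out[[v]])
  }
  panel_dataset(out)
}

#' Design matrix for a regression on panel variables
#'
#' Extracts a response vector and predictor matrix from a balanced panel,
#' rows in canonical (country, year) order. The result is deterministic:
#' permuting the rows of the source CSV does not change it.
#'
#' @param ds A [panel_dataset].
#' @param response Name of the response variable.
#' @param predictors Character vector of predictor names (may be empty).
#' @return A `design_matrix`: list with `y` (length n), `X` (n x p matrix
#'   with column names), `row_index` (data.frame of country, year) and
#'   `column_names`.
#' @export
to_design <- function(ds, response, predictors = setdiff(variable_names(ds), response)) {
  stopifnot(inherits(ds, "panel_dataset"))
  all_vars <- variable_names(ds)
  unknown <- setdiff(c(response, predictors), all_vars)
  if (length(unknown))
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")))
  if (response %in% predictors)
    stop(sprintf("response '%s' may not appear among the predictors", response))
  X <- as.matrix(as.data.frame(ds)[, predictors, drop = FALSE])
  colnames(X) <- predictors
  design_matrix(y = ds[[response]], X = X,
                row_index = data.frame(country = ds$country, year = ds$year,
                                       stringsAsFactors = FALSE))
}

#' @rdname to_design
#' @param y Numeric response vector.
#' @param X Numeric predictor matrix with column names.
#' @param row_index Optional data.frame identifying rows.
#' @export
design_matrix <- function(y, X, row_index = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)")
  if (ncol(X) > 0 && is.null(colnames(X)))
    stop("X must have column names")
  if (any(!is.finite(y)) || (length(X) && any(!is.finite(X))))
    stop("design matrix entries must be finite")
  structure(list(y = as.numeric(y), X = X, row_index = row_index,
                 column_names = colnames(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: n = %d, p = %d (%s)\n", length(x$y), ncol(x$X),
              paste(x$column_names, collapse = ", ")))
  invisible(x)
}

#' Descriptive statistics of a panel's variables
#'
#' Per-variable mean, sample standard deviation (n - 1 denominator),
#' variance, coefficient of variation (100 * sd / mean), minimum, maximum
#' and range (max - min), in the layout conventional for panel studies.
#'
#' @param ds A [panel_dataset].
#' @return A data.frame with one row per variable.
#' @export
descriptive_stats <- function(ds) {
  stopifnot(inherits(ds, "panel_dataset"))
  vars <- variable_names(ds)
  rows <- lapply(vars, function(v) {
    x <- ds[[v]]
    s <- stats::sd(x)
    data.frame(variable = v, mean = mean(x), sd = s, variance = s^2,
               coef_var = 100 * s / mean(x), min = min(x), max = max(x),
               range = max(x) - min(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
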