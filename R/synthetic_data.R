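# Synthetic generators emulating the statistical structure the analysis
# assumes: a balanced 14-country x 23-year macro panel with prescribed
# per-variable moments, piecewise-linear ground-truth responses for
# parameter recovery, a closed-form toy surface, and calibration beds for
# the endogeneity and causality screens.
#
# All generators are pure functions of (spec, seed): the global RNG state
# is saved and restored around every draw.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic balanced panel
#'
#' `moments` prescribes the stationary marginal distribution of every
#' variable (mean, sd) and its observed support (min, max, to which draws
#' are clipped). Within each country every variable follows a stationary
#' Gaussian AR(1) with the given persistence; countries are independent.
#'
#' @param moments data.frame with columns `variable`, `mean`, `sd`, `min`,
#'   `max`.
#' @param n_countries,n_years Panel dimensions.
#' @param persistence AR(1) coefficient in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(moments, n_countries = 14, n_years = 23,
                       persistence = 0.85, seed = 1) {
  stopifnot(is.data.frame(moments),
            all(c("variable", "mean", "sd", "min", "max") %in% names(moments)),
            all(moments$sd >= 0), all(moments$min < moments$max),
            persistence >= 0, persistence < 1,
            n_countries >= 1, n_years >= 1)
  structure(list(moments = moments, n_countries = as.integer(n_countries),
                 n_years = as.integer(n_years), persistence = persistence,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Default panel specification: the European life-expectancy panel
#'
#' Moments of the seven study variables (life expectancy at birth and its
#' six socioeconomic covariates) as shipped in
#' `extdata/european_panel_moments.csv`, on a 14-country x 23-year
#' balanced panel. The HEALTH row of the published summary is internally
#' inconsistent; the shipped file records the decimal-consistent values
#' (see the file's comment) rather than silently reusing the misprint.
#'
#' @param seed Integer seed.
#' @return A [panel_spec].
#' @export
default_panel_spec <- function(seed = 1) {
  path <- system.file("extdata", "european_panel_moments.csv",
                      package = "marspanel", mustWork = TRUE)
  moments <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  panel_spec(moments, n_countries = 14, n_years = 23, seed = seed)
}

ar1_series <- function(n, mean, sd, phi) {
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) for (t in 2:n) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
  mean + x
}

#' Generate a synthetic balanced panel
#'
#' Per country and variable, draws a stationary Gaussian AR(1) series with
#' the spec's marginal mean and sd, then clips to the `[min, max]` support
#' (range fidelity is prioritised; the mild sd shrinkage from clipping is
#' absorbed by the tolerance of moment checks). Deterministic given the
#' spec's seed.
#'
#' @param spec A [panel_spec].
#' @return A [panel_dataset] of `n_countries * n_years * n_variables`
#'   values.
#' @export
gen_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    countries <- sprintf("C%02d", seq_len(spec$n_countries))
    years <- seq(2000L, length.out = spec$n_years)
    rows <- expand.grid(year = years, country = countries,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df <- data.frame(country = rows$country, year = rows$year,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(spec$moments))) {
      m <- spec$moments[i, ]
      vals <- unlist(lapply(countries, function(cc)
        ar1_series(spec$n_years, m$mean, m$sd, spec$persistence)))
      df[[m$variable]] <- pmin(pmax(vals, m$min), m$max)
    }
    panel_dataset(df)
  })
}

#' Ground-truth piecewise-linear response specification
#'
#' @param terms List of [basis_term] objects with coefficients set; every
#'   non-linear hinge knot must coincide with an observed value of its
#'   variable in the design the response is generated on.
#' @param intercept Intercept of the true signal.
#' @param noise_sd Gaussian noise standard deviation (0 = exact signal).
#' @param seed Integer seed for the noise.
#' @return An object of class `piecewise_spec`.
#' @export
piecewise_spec <- function(terms, intercept = 0, noise_sd = 0, seed = 1) {
  stopifnot(noise_sd >= 0,
            all(vapply(terms, inherits, TRUE, "basis_term")),
            all(vapply(terms, function(t) is.finite(t$coefficient), TRUE)))
  structure(list(terms = terms, intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "piecewise_spec")
}

#' Generate a piecewise-linear response on a design
#'
#' Evaluates the spec's hinge-product signal on the design rows and adds
#' Gaussian noise of the stated sd. With `noise_sd = 0` the output is the
#' exact signal, so a spline fit on it can be checked for exact knot and
#' coefficient recovery.
#'
#' @param D A design matrix.
#' @param spec A [piecewise_spec].
#' @return Numeric response vector of length `nrow(D$X)`.
#' @export
gen_piecewise_response <- function(D, spec) {
  stopifnot(inherits(spec, "piecewise_spec"))
  X <- D$X
  for (t in spec$terms) for (h in t$factors) {
    if (!h$var %in% colnames(X))
      stop(sprintf("unknown variable '%s' in piecewise spec", h$var))
    if (!h$linear && !h$knot %in% X[, h$var])
      stop(sprintf("knot %g of '%s' is not an observed value", h$knot, h$var))
  }
  y <- rep(spec$intercept, nrow(X))
  for (t in spec$terms) y <- y + t$coefficient * eval_term(t, X)
  if (spec$noise_sd > 0)
    y <- y + with_seed(spec$seed, stats::rnorm(length(y), 0, spec$noise_sd))
  y
}

#' Toy two-predictor surface on a uniform grid
#'
#' The benchmark surface `y = sin(1.5 pi x1) * cos(0.5 pi x2)` evaluated
#' exactly on a uniform `n x n` grid over the unit square — a smooth
#' nonlinear target a hinge-product model should approximate well at
#' moderate term budgets.
#'
#' @param n_per_axis Grid points per axis (>= 2).
#' @return A design matrix with predictors `x1`, `x2` and the exact
#'   response in `y`.
#' @export
gen_figure_surface <- function(n_per_axis) {
  stopifnot(n_per_axis >= 2)
  g <- seq(0, 1, length.out = n_per_axis)
  grid <- expand.grid(x1 = g, x2 = g, KEEP.OUT.ATTRS = FALSE)
  y <- sin(1.5 * pi * grid$x1) * cos(0.5 * pi * grid$x2)
  design_matrix(y, as.matrix(grid))
}

#' Calibration bed for the endogeneity screen
#'
#' A structural equation `y = 1 + x beta + u` with three endogenous
#' regressors `x_j = z_j + endogeneity * u + e_j`: each instrument `z_j`
#' is correlated with its regressor but not with the structural error, and
#' `endogeneity` scales how strongly the regressors load on the error.
#' At `endogeneity = 0` OLS is consistent and the Hausman test should
#' reject at its nominal rate.
#'
#' @param n Sample size (>= 30).
#' @param endogeneity Loading of the structural error in the regressors.
#' @param seed Integer seed.
#' @return List with `y`, `exog` (constant column), `endog` (n x 3),
#'   `instruments` (n x 3) and `beta_true`.
#' @export
gen_endogenous_system <- function(n, endogeneity, seed = 1) {
  stopifnot(n >= 30)
  with_seed(seed, {
    beta <- c(1, 0.5, -0.5)
    Z <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(NULL, paste0("z", 1:3)))
    u <- stats::rnorm(n)
    E <- matrix(stats::rnorm(n * 3, sd = 0.5), n, 3)
    X <- Z + endogeneity * u + E
    colnames(X) <- paste0("x", 1:3)
    y <- 1 + drop(X %*% beta) + u
    list(y = y, exog = matrix(1, n, 1, dimnames = list(NULL, "const")),
         endog = X, instruments = Z, beta_true = beta)
  })
}

#' Calibration bed for the panel causality screen
#'
#' Two panel series, each a stationary AR(1) within country (own-lag
#' coefficient `ar`); when `causal` is TRUE the cause's first lag enters
#' the effect's equation with coefficient `effect_size`, otherwise the two
#' series are independent.
#'
#' @param causal Whether the cause feeds the effect.
#' @param effect_size Lag-1 coefficient of the cause in the effect
#'   equation.
#' @param n_countries,n_years Panel dimensions.
#' @param ar Own-lag coefficient of both series.
#' @param seed Integer seed.
#' @return A [panel_dataset] with variables `cause` and `effect`.
#' @export
gen_granger_pair <- function(causal, effect_size = 0.8, n_countries = 14,
                             n_years = 23, ar = 0.5, seed = 1) {
  with_seed(seed, {
    countries <- sprintf("C%02d", seq_len(n_countries))
    years <- seq(2000L, length.out = n_years)
    one_country <- function() {
      cause <- ar1_series(n_years, 0, 1, ar)
      eff <- numeric(n_years)
      eff[1] <- stats::rnorm(1)
      if (n_years > 1) for (t in 2:n_years) {
        eff[t] <- ar * eff[t - 1] +
          (if (causal) effect_size * cause[t - 1] else 0) + stats::rnorm(1)
      }
      data.frame(cause = cause, effect = eff)
    }
    df <- do.call(rbind, lapply(countries, function(cc) {
      cbind(data.frame(country = cc, year = years, stringsAsFactors = FALSE),
            one_country())
    }))
    panel_dataset(df)
  })
}
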