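# Pre-spline screens: exactly-identified two-stage least squares, the
# Hausman endogeneity test, and the stacked (common-coefficient) panel
# Granger causality test.

regression_result <- function(coefficients, covariance, rss, n, names) {
  stopifnot(isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)),
            length(coefficients) == nrow(covariance))
  structure(list(coefficients = stats::setNames(coefficients, names),
                 covariance = covariance, rss = rss, n = n, names = names),
            class = "regression_result")
}

test_result <- function(statistic, df, p_value, n_obs, description) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 n_obs = n_obs, description = description),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.5f, df = (%s), p-value = %.6g, n = %d\n",
              x$description, x$statistic, paste(x$df, collapse = ", "),
              x$p_value, x$n_obs))
  invisible(x)
}

#' Ordinary least squares with classical covariance
#'
#' @param y Response vector.
#' @param X Regressor matrix (include a constant column if wanted).
#' @return A `regression_result` with coefficients, classical covariance
#'   `sigma^2 (X'X)^{-1}`, residual sum of squares and sample size.
#' @export
ols_regression <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  rss <- sum(res^2)
  sigma2 <- rss / (n - k)
  XtXinv <- chol2inv(chol(crossprod(X)))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  regression_result(fit$coefficients, sigma2 * XtXinv, rss, n, nm)
}

#' Two-stage least squares
#'
#' First stage projects the endogenous regressors on the full instrument
#' set (exogenous regressors plus excluded instruments); second stage is
#' OLS of `y` on the exogenous regressors and the projected endogenous
#' columns. The covariance is the classical IV estimate
#' `sigma^2 (Xhat' Xhat)^{-1}` with `sigma^2` from the structural
#' residuals (original regressors at the second-stage coefficients).
#'
#' @param y Response vector.
#' @param exog Matrix of included exogenous regressors (constant included
#'   here if wanted); may have zero columns.
#' @param endog Matrix of endogenous regressors.
#' @param instruments Matrix of excluded instruments; needs at least as
#'   many columns as `endog`.
#' @return A `regression_result` for `(exog, endog)` in that column order.
#' @export
tsls_fit <- function(y, exog, endog, instruments) {
  exog <- as.matrix(exog)
  endog <- as.matrix(endog)
  instruments <- as.matrix(instruments)
  n <- length(y)
  if (ncol(instruments) < ncol(endog))
    stop("tsls_fit: need at least as many instruments as endogenous regressors")
  Z <- cbind(exog, instruments)
  if (qr(Z)$rank < ncol(Z))
    stop("tsls_fit: instrument set is rank deficient")
  X <- cbind(exog, endog)
  Xhat <- cbind(exog, qr.fitted(qr(Z), endog))
  b <- qr.coef(qr(Xhat), y)
  res <- y - drop(X %*% b)             # structural residuals
  rss <- sum(res^2)
  k <- ncol(X)
  sigma2 <- rss / (n - k)
  cov <- sigma2 * chol2inv(chol(crossprod(Xhat)))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  regression_result(as.numeric(b), cov, rss, n, nm)
}

#' Hausman specification test
#'
#' Compares the instrumental-variable and OLS coefficient vectors on the
#' same specification: `H = d' [V_IV - V_OLS]^+ d` with `d = b_IV - b_OLS`.
#' Under the null that OLS is consistent (no endogeneity) H is
#' asymptotically chi-square with df equal to the number of instrumented
#' coefficients compared. The covariance difference is inverted by
#' pseudo-inverse after clipping negative eigenvalues at zero, so the
#' statistic is always non-negative.
#'
#' @param ols A `regression_result` from [ols_regression()].
#' @param iv A `regression_result` from [tsls_fit()] on the same
#'   specification.
#' @param which_coefs Names (or indices) of the coefficients to compare;
#'   defaults to all shared names.
#' @return A `test_result` with the chi-square statistic, df and p-value.
#' @export
hausman_test <- function(ols, iv, which_coefs = NULL) {
  if (is.null(which_coefs)) which_coefs <- intersect(iv$names, ols$names)
  if (is.character(which_coefs)) {
    io <- match(which_coefs, ols$names)
    ii <- match(which_coefs, iv$names)
    if (anyNA(io) || anyNA(ii))
      stop("hausman_test: coefficient names not present in both fits")
  } else {
    io <- ii <- as.integer(which_coefs)
  }
  d <- iv$coefficients[ii] - ols$coefficients[io]
  V <- iv$covariance[ii, ii, drop = FALSE] - ols$covariance[io, io, drop = FALSE]
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  pos <- lam > max(lam, 0) * 1e-12
  H <- if (any(pos)) {
    dz <- drop(crossprod(e$vectors[, pos, drop = FALSE], d))
    sum(dz^2 / lam[pos])
  } else 0
  df <- length(d)
  test_result(H, df, chi2_sf(H, df), ols$n,
              "Hausman test (H0: OLS estimates are consistent)")
}

#' Stacked panel Granger causality test
#'
#' The common-coefficient ("stacked") panel version: lags are built within
#' each country (never across borders), the first `lags` years of every
#' country are dropped, and a single pooled OLS of the effect on a
#' constant, its own lags and the cause's lags is fit with coefficients
#' common to all countries. The test is the F-statistic for joint nullity
#' of the cause's lag coefficients, with df `(L, n_obs - 2L - 1)`.
#'
#' With `difference = TRUE` both series are first-differenced within each
#' country before lagging — the standard stationarity device for trending
#' macro panels, costing one further year per country (a 14 x 23 panel at
#' 2 lags then yields 14 x 20 = 280 stacked observations).
#'
#' @param ds A [panel_dataset].
#' @param cause Name of the hypothesised causing variable.
#' @param effect Name of the affected variable.
#' @param lags Number of lags `L` (>= 1).
#' @param difference First-difference both series within country before
#'   building lags.
#' @return A `test_result`; `n_obs` is the number of stacked observations.
#' @export
granger_stacked <- function(ds, cause, effect, lags = 2, difference = FALSE) {
  stopifnot(inherits(ds, "panel_dataset"), lags >= 1)
  unknown <- setdiff(c(cause, effect), variable_names(ds))
  if (length(unknown))
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")))
  years <- panel_years(ds)
  if (length(years) <= lags + as.integer(difference))
    stop("granger_stacked: need more years per country than lags")
  blocks <- lapply(panel_countries(ds), function(cc) {
    sub <- ds[ds$country == cc, ]
    sub <- sub[order(sub$year), ]
    eff_s <- sub[[effect]]
    cau_s <- sub[[cause]]
    if (difference) {
      eff_s <- diff(eff_s)
      cau_s <- diff(cau_s)
    }
    t_idx <- (lags + 1):length(eff_s)
    lagmat <- do.call(cbind, lapply(seq_len(lags), function(l)
      eff_s[t_idx - l]))
    lagmat <- cbind(lagmat, do.call(cbind, lapply(seq_len(lags), function(l)
      cau_s[t_idx - l])))
    list(y = eff_s[t_idx], X = lagmat)
  })
  y <- unlist(lapply(blocks, `[[`, "y"))
  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  colnames(X) <- c(paste0("effect_lag", seq_len(lags)),
                   paste0("cause_lag", seq_len(lags)))
  n_obs <- length(y)
  df2 <- n_obs - (2 * lags + 1)
  if (df2 <= 0) stop("granger_stacked: not enough observations")
  full <- stats::lm.fit(cbind(const = 1, X), y)
  restr <- stats::lm.fit(cbind(const = 1, X[, seq_len(lags), drop = FALSE]), y)
  rss_f <- sum(full$residuals^2)
  rss_r <- sum(restr$residuals^2)
  Fstat <- ((rss_r - rss_f) / lags) / (rss_f / df2)
  test_result(Fstat, c(lags, df2), f_sf(Fstat, lags, df2), n_obs,
              sprintf("%s does not Granger cause %s", cause, effect))
}

#' Chi-square upper-tail probability
#'
#' @param x Non-negative quantile.
#' @param df Degrees of freedom (>= 1).
#' @return `P(X > x)` for `X ~ chi-square(df)`.
#' @export
chi2_sf <- function(x, df) {
  if (df < 1) stop("chi2_sf: df must be >= 1")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' F-distribution upper-tail probability
#'
#' @param x Non-negative quantile.
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return `P(X > x)` for `X ~ F(df1, df2)`.
#' @export
f_sf <- function(x, df1, df2) {
  if (df1 < 1 || df2 < 1) stop("f_sf: degrees of freedom must be >= 1")
  stats::pf(x, df1, df2, lower.tail = FALSE)
}
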