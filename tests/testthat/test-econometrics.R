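test_that("two-stage least squares reduces to OLS when self-instrumented", {
  set.seed(2)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("p", "q")))
  y <- 1 + X %*% c(2, -1) + rnorm(n)
  const <- matrix(1, n, 1, dimnames = list(NULL, "const"))
  ols <- ols_regression(y, cbind(const, X))
  iv <- tsls_fit(y, const, X, X)
  expect_equal(iv$coefficients, ols$coefficients, tolerance = 1e-10)
  expect_equal(iv$rss, ols$rss, tolerance = 1e-8)
})

test_that("just-identified IV equals the covariance-ratio closed form", {
  set.seed(3)
  n <- 200
  z <- rnorm(n)
  u <- rnorm(n)
  x <- z + 0.7 * u + rnorm(n, 0, 0.4)
  y <- 2 * x + u
  # with the constant partialled out the IV slope is the covariance ratio
  iv <- tsls_fit(y, matrix(1, n, 1, dimnames = list(NULL, "const")),
                 cbind(x = x), cbind(z = z))
  expect_equal(unname(iv$coefficients["x"]), cov(z, y) / cov(z, x),
               tolerance = 1e-10)
  expect_error(tsls_fit(y, matrix(numeric(0), n, 0), cbind(x, x + 0),
                        cbind(z)), "at least as many instruments")
})

test_that("structural coefficients are recovered by the IV fit", {
  reps <- 60
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    s <- gen_endogenous_system(322, endogeneity = 0.8, seed = 500 + r)
    iv <- tsls_fit(s$y, s$exog, s$endog, s$instruments)
    est[r, ] <- iv$coefficients[colnames(s$endog)]
  }
  truth <- gen_endogenous_system(40, 0.8, seed = 1)$beta_true
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se + 1e-8))
  # OLS is biased here; IV removes the bias
  ols_est <- vapply(1:reps, function(r) {
    s <- gen_endogenous_system(322, 0.8, seed = 500 + r)
    ols_regression(s$y, cbind(s$exog, s$endog))$coefficients["x1"]
  }, 0)
  expect_gt(abs(mean(ols_est) - truth[1]), 5 * sd(ols_est) / sqrt(reps))
})

test_that("Hausman statistic is zero on equal fits and matches the printed tail", {
  set.seed(4)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("p", "q")))
  y <- drop(X %*% c(1, 1)) + rnorm(n)
  const <- matrix(1, n, 1, dimnames = list(NULL, "const"))
  ols <- ols_regression(y, cbind(const, X))
  iv <- tsls_fit(y, const, X, X)   # identical estimates
  h <- hausman_test(ols, iv, which_coefs = c("p", "q"))
  expect_equal(h$statistic, 0, tolerance = 1e-8)
  expect_equal(h$p_value, 1, tolerance = 1e-6)
  # the published chi-square(3) tail at 34.787
  expect_equal(chi2_sf(34.787, 3), 1.35123e-7, tolerance = 1e-4)
})

test_that("Hausman statistic is never negative (clipping contract)", {
  for (r in 1:25) {
    s <- gen_endogenous_system(60, endogeneity = runif(1), seed = 900 + r)
    ols <- ols_regression(s$y, cbind(s$exog, s$endog))
    iv <- tsls_fit(s$y, s$exog, s$endog, s$instruments)
    h <- hausman_test(ols, iv, which_coefs = colnames(s$endog))
    expect_gte(h$statistic, 0)
    expect_true(h$p_value >= 0 && h$p_value <= 1)
  }
})

test_that("stacked causality test matches its sample-size and F conventions", {
  ds <- gen_granger_pair(causal = FALSE, seed = 10)
  g <- granger_stacked(ds, "cause", "effect", lags = 2)
  expect_equal(g$n_obs, 14 * 21)
  expect_equal(g$df, c(2, g$n_obs - 5))
  # first-differencing within country reproduces the published sample:
  # 14 countries x (23 - 1 - 2) = 280 observations, denominator df 275
  gd <- granger_stacked(ds, "cause", "effect", lags = 2, difference = TRUE)
  expect_equal(gd$n_obs, 280)
  expect_equal(gd$df, c(2, 275))

  # oracle identity: F equals the direct restricted-vs-full RSS computation
  direct_F <- function(ds, cause, effect, L) {
    rows <- do.call(rbind, lapply(panel_countries(ds), function(cc) {
      sub <- ds[ds$country == cc, ]
      sub <- sub[order(sub$year), ]
      idx <- (L + 1):nrow(sub)
      cbind(y = sub[[effect]][idx],
            el1 = sub[[effect]][idx - 1], el2 = sub[[effect]][idx - 2],
            cl1 = sub[[cause]][idx - 1], cl2 = sub[[cause]][idx - 2])
    }))
    full <- lm(y ~ el1 + el2 + cl1 + cl2, data = as.data.frame(rows))
    restr <- lm(y ~ el1 + el2, data = as.data.frame(rows))
    df2 <- nrow(rows) - 5
    ((sum(resid(restr)^2) - sum(resid(full)^2)) / L) /
      (sum(resid(full)^2) / df2)
  }
  expect_equal(g$statistic, direct_F(ds, "cause", "effect", 2),
               tolerance = 1e-10)
  expect_error(granger_stacked(ds, "cause", "nope", 2), "unknown variable")
  expect_error(granger_stacked(ds, "cause", "effect", 25), "more years")
})

test_that("causal signal is detected with high power", {
  rej <- vapply(1:100, function(r) {
    ds <- gen_granger_pair(causal = TRUE, effect_size = 0.8, seed = 600 + r)
    granger_stacked(ds, "cause", "effect", 2)$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.9)
})

test_that("distribution tails agree with their closed forms", {
  expect_equal(chi2_sf(0, 3), 1)
  expect_equal(f_sf(0, 2, 50), 1)
  # chi-square df=2: exp(-x/2)
  for (x in c(0.5, 2, 2 * log(20), 10)) {
    expect_equal(chi2_sf(x, 2), exp(-x / 2), tolerance = 1e-12)
  }
  expect_equal(chi2_sf(2 * log(20), 2), 0.05, tolerance = 1e-12)
  # chi-square df=3: 2(1 - Phi(sqrt(x))) + sqrt(2x/pi) exp(-x/2); the
  # normal tail is evaluated as an upper tail to avoid cancellation
  for (x in c(1, 5, 34.787)) {
    cf <- 2 * pnorm(sqrt(x), lower.tail = FALSE) +
      sqrt(2 * x / pi) * exp(-x / 2)
    expect_equal(chi2_sf(x, 3), cf, tolerance = 1e-12)
  }
  # F df1=2: (1 + 2x/df2)^(-df2/2)
  for (x in c(0.3, 1, 4.55385, 8.71157)) {
    expect_equal(f_sf(x, 2, 275), (1 + 2 * x / 275)^(-275 / 2),
                 tolerance = 1e-12)
  }
  expect_error(chi2_sf(1, 0), "df")
  expect_error(f_sf(1, 0, 10), "degrees of freedom")
})
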