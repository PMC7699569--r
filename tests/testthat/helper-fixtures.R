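# Fixtures built in code: tiny balanced panels, grid designs, and the
# sampling-theory standard errors used by generator moment checks.

tiny_panel_df <- function(n_countries = 2, n_years = 3,
                          vars = c("a", "b"), seed = 7) {
  set.seed(seed)
  df <- expand.grid(country = sprintf("C%d", seq_len(n_countries)),
                    year = 2000L + seq_len(n_years) - 1L,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in vars) df[[v]] <- round(runif(nrow(df), 1, 10), 3)
  df
}

grid_design <- function(step = 0.1, true_fun) {
  g <- seq(0, 1, by = step)
  X <- as.matrix(expand.grid(x1 = g, x2 = g, KEEP.OUT.ATTRS = FALSE))
  design_matrix(true_fun(X[, 1], X[, 2]), X)
}

# Standard error of the grand mean of n_countries independent stationary
# AR(1) series of length T with marginal sd sigma and coefficient phi.
ar1_mean_se <- function(sigma, phi, T, n_countries) {
  k <- seq_len(T - 1)
  var_cmean <- (sigma^2 / T^2) * (T + 2 * sum((T - k) * phi^k))
  sqrt(var_cmean / n_countries)
}

# Approximate standard error of the pooled sample sd under the same
# dependence: effective sample size deflated by the squared
# autocorrelations within country.
ar1_sd_se <- function(sigma, phi, T, n_countries) {
  k <- seq_len(T - 1)
  infl <- 1 + 2 * sum((1 - k / T) * phi^(2 * k))
  n_eff <- n_countries * T / infl
  sigma / sqrt(2 * n_eff)
}
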