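oracle_first_pair <- function(x, y) {
  best <- NULL
  for (t in sort(unique(x))) {
    B <- cbind(1, pmax(0, x - t), pmax(0, t - x))
    r <- sum(qr.resid(qr(B), y)^2)
    if (is.null(best) || r < best$rss - 1e-12) best <- list(knot = t, rss = r)
  }
  best
}

test_that("first forward pair matches exhaustive knot search (single predictor)", {
  for (s in 1:6) {
    set.seed(s)
    x <- runif(15)
    y <- sin(2 * pi * x) + 0.3 * x + rnorm(15, 0, 0.2)
    fp <- forward_pass(design_matrix(y, cbind(x1 = x)),
                       fit_config(max_terms = 3))
    ob <- oracle_first_pair(x, y)
    expect_equal(fp$terms[[1]]$factors[[1]]$knot, ob$knot)
    expect_equal(tail(fp$rss_trace, 1), ob$rss, tolerance = 1e-8)
  }
})

test_that("forward pass is monotone in RSS and handles degenerate input", {
  set.seed(21)
  X <- cbind(x1 = runif(40), x2 = runif(40))
  y <- 3 * pmax(0, X[, 1] - X[17, 1]) + rnorm(40, 0, 0.1)
  fp <- forward_pass(design_matrix(y, X), fit_config(max_terms = 11))
  expect_true(all(diff(fp$rss_trace) < 0))
  # constant response -> intercept only, no exception
  fp0 <- forward_pass(design_matrix(rep(2, 40), X), fit_config(max_terms = 11))
  expect_length(fp0$terms, 0)
  # all-constant predictors -> intercept only
  fpc <- forward_pass(design_matrix(y, cbind(c1 = rep(1, 40))),
                      fit_config(max_terms = 11))
  expect_length(fpc$terms, 0)
})

test_that("a single exact hinge is found with zero residual", {
  x <- c(0, 0.25, 0.5, 0.75, 1)
  y <- pmax(0, x - 0.5)
  fp <- forward_pass(design_matrix(y, cbind(x1 = x)),
                     fit_config(max_terms = 3))
  expect_equal(fp$terms[[1]]$factors[[1]]$knot, 0.5)
  expect_lt(tail(fp$rss_trace, 1), 1e-20)
})

test_that("noiseless piecewise targets are recovered exactly", {
  D <- grid_design(0.1, function(x1, x2)
    2 * pmax(0, x1 - 0.5) - 3 * pmax(0, 0.7 - x2))
  f <- mars_fit(D, fit_config(max_terms = 11))
  expect_lt(f$model$rss, 1e-12)
  knots <- sort(unlist(lapply(f$model$terms, function(t)
    vapply(t$factors, `[[`, 0, "knot"))))
  expect_equal(knots, c(0.5, 0.7))
  vars <- sort(unlist(lapply(f$model$terms, marspanel:::term_vars)))
  expect_equal(vars, c("x1", "x2"))
  coefs <- vapply(f$model$terms, `[[`, 0, "coefficient")
  expect_equal(sort(coefs), c(-3, 2), tolerance = 1e-8)
  expect_lt(max(abs(predict(f$model, D) - D$y)), 1e-6)

  # interaction target: exact fit, predictions match the truth
  D2 <- grid_design(0.1, function(x1, x2)
    2 * pmax(0, x1 - 0.5) * pmax(0, 0.7 - x2) + 0.5 * pmax(0, x2 - 0.3))
  f2 <- mars_fit(D2, fit_config(max_terms = 11))
  expect_lt(f2$model$rss, 1e-12)
  expect_lt(max(abs(predict(f2$model, D2) - D2$y)), 1e-6)
})

test_that("the smooth two-predictor benchmark surface is fit well", {
  D <- gen_figure_surface(21)
  f <- mars_fit(D, fit_config(max_terms = 21, max_degree = 2))
  expect_gte(f$model$rsq, 0.9)
})

test_that("backward pass returns the minimum-GCV subset of a nested trace", {
  set.seed(5)
  X <- cbind(x1 = runif(60), x2 = runif(60), x3 = runif(60))
  y <- X[, 1] + 0.5 * pmax(0, X[, 2] - X[30, 2]) + rnorm(60, 0, 0.3)
  D <- design_matrix(y, X)
  cfg <- fit_config(max_terms = 13)
  fp <- forward_pass(D, cfg)
  bp <- backward_pass(fp$terms, D, cfg)
  sizes <- vapply(bp$trace$subsets, function(s) length(s$keep), 0L)
  expect_equal(sizes, seq(length(fp$terms), 0))
  # each subset is nested inside the previous one
  for (i in seq_len(length(sizes) - 1)) {
    expect_true(all(bp$trace$subsets[[i + 1]]$keep %in%
                      bp$trace$subsets[[i]]$keep))
  }
  gcvs <- vapply(bp$trace$subsets, `[[`, 0, "gcv")
  expect_equal(bp$model$gcv, min(gcvs))
  expect_lte(bp$model$gcv, gcvs[1])  # never worse than the forward model

  # pure linear target oversupplied with terms: pruning keeps GCV minimal
  yl <- X[, 1]
  fl <- mars_fit(design_matrix(yl, X), cfg)
  gl <- vapply(fl$trace$subsets, `[[`, 0, "gcv")
  expect_equal(fl$model$gcv, min(gl))
})

test_that("fits are deterministic and training predictions reproduce rss", {
  set.seed(9)
  X <- cbind(a = runif(50), b = runif(50))
  y <- 2 * pmax(0, X[, 1] - 0.4) + rnorm(50, 0.2)
  D <- design_matrix(y, X)
  f1 <- mars_fit(D, fit_config(max_terms = 9))
  f2 <- mars_fit(D, fit_config(max_terms = 9))
  expect_identical(model_report(f1$model), model_report(f2$model))
  expect_identical(f1$model$rss, f2$model$rss)
  res <- y - predict(f1$model, D)
  expect_equal(sum(res^2), f1$model$rss, tolerance = 1e-10)
  # empty-term model predicts a constant
  m0 <- marspanel:::build_mars_model(list(), D, fit_config())
  expect_equal(predict(m0, D), rep(mean(y), 50))
  expect_error(predict(f1$model, cbind(zz = 1:5)), "missing variable")
})

test_that("GRSq never exceeds RSq for penalised non-trivial models", {
  for (s in 1:8) {
    set.seed(100 + s)
    X <- cbind(x1 = runif(45), x2 = runif(45))
    y <- pmax(0, X[, 1] - 0.5) - X[, 2] + rnorm(45, 0, 0.25)
    f <- mars_fit(design_matrix(y, X), fit_config(max_terms = 9))
    if (length(f$model$terms) >= 1) {
      expect_lte(f$model$grsq, f$model$rsq)
    }
  }
})

test_that("a predictor the response ignores ends unused", {
  set.seed(33)
  n <- 250
  X <- cbind(s1 = runif(n), s2 = runif(n), noise = runif(n))
  y <- 2 * pmax(0, X[, 1] - 0.5) + X[, 2] + rnorm(n, 0, 0.2)
  f <- mars_fit(design_matrix(y, X), fit_config(max_terms = 11))
  imp <- variable_importance(f$trace, f$model)
  expect_false(imp$used[imp$var == "noise"])
  expect_true(is.na(imp$gcv_score[imp$var == "noise"]))
})

test_that("importance ranks a dominant predictor first and normalises to 100", {
  set.seed(71)
  X <- cbind(big = runif(100), small = runif(100))
  y <- 5 * pmax(0, X[, 1] - 0.5) + 0.4 * pmax(0, X[, 2] - 0.5) +
    rnorm(100, 0, 0.05)
  f <- mars_fit(design_matrix(y, X), fit_config(max_terms = 11))
  imp <- variable_importance(f$trace, f$model)
  expect_equal(imp$var[1], "big")
  expect_equal(max(imp$gcv_score, na.rm = TRUE), 100)
  expect_equal(max(imp$rss_score, na.rm = TRUE), 100)
  expect_gte(imp$gcv_score[imp$var == "big"],
             imp$gcv_score[imp$var == "small"])
  expect_gte(imp$rss_score[imp$var == "big"],
             imp$rss_score[imp$var == "small"])

  # single-variable model scores 100/100 by construction
  y1 <- 2 * pmax(0, X[, 1] - 0.5) + rnorm(100, 0, 0.05)
  f1 <- mars_fit(design_matrix(y1, cbind(only = X[, 1])),
                 fit_config(max_terms = 7))
  i1 <- variable_importance(f1$trace, f1$model)
  expect_equal(i1$gcv_score[i1$var == "only"], 100)
  expect_equal(i1$rss_score[i1$var == "only"], 100)
})

test_that("residual diagnostics rank by absolute residual without excluding", {
  set.seed(55)
  X <- cbind(x1 = runif(40))
  y <- pmax(0, X[, 1] - 0.5) + rnorm(40, 0, 0.1)
  y[17] <- y[17] + 3   # gross outlier
  D <- design_matrix(y, X)
  m <- marspanel:::build_mars_model(list(), D, fit_config())
  rd <- residual_diagnostics(m, D)
  expect_equal(nrow(rd), 40)            # nothing dropped
  expect_equal(rd$row[1], 17)           # the planted outlier ranks first
  expect_true(all(diff(rd$abs_residual) <= 0))
})
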