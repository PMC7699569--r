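#' Hinge basis factors
#'
#' The building block of an adaptive regression spline model is the hinge
#' (one-sided linear spline): `max(0, x - t)` for direction `"+"` or
#' `max(0, t - x)` for direction `"-"`, with the knot `t` placed at an
#' observed value of the predictor. A hinge whose knot sits at the observed
#' minimum of its variable (direction `"+"`) is equivalent on the training
#' range to a bare linear entry of that variable; such factors carry
#' `linear = TRUE` and are evaluated and reported as the untransformed
#' variable.
#'
#' @param var Predictor name.
#' @param knot Knot location `t`.
#' @param direction `"+"` for `max(0, x - t)`, `"-"` for `max(0, t - x)`.
#' @param linear If `TRUE` the factor enters as the bare variable.
#' @return An object of class `hinge`.
#' @export
hinge <- function(var, knot, direction = c("+", "-"), linear = FALSE) {
  direction <- match.arg(direction)
  structure(list(var = var, knot = as.numeric(knot), direction = direction,
                 linear = isTRUE(linear)),
            class = "hinge")
}

#' Evaluate a hinge factor
#'
#' @param h A [hinge].
#' @param x Numeric vector of predictor values.
#' @return `max(0, x - knot)`, `max(0, knot - x)`, or `x` itself when the
#'   factor is linear.
#' @export
hinge_eval <- function(h, x) {
  if (h$linear) return(as.numeric(x))
  if (h$direction == "+") pmax(0, x - h$knot) else pmax(0, h$knot - x)
}

#' A product-of-hinges basis term
#'
#' @param factors List of [hinge] factors (degree = number of factors).
#'   No predictor may appear twice within one term.
#' @param coefficient Fitted coefficient (NA until fitted).
#' @return An object of class `basis_term`.
#' @export
basis_term <- function(factors, coefficient = NA_real_) {
  stopifnot(length(factors) >= 1, all(vapply(factors, inherits, TRUE, "hinge")))
  vars <- vapply(factors, `[[`, "", "var")
  if (anyDuplicated(vars))
    stop("a predictor may not appear twice within one basis term")
  structure(list(factors = factors, coefficient = as.numeric(coefficient)),
            class = "basis_term")
}

term_vars <- function(term) vapply(term$factors, `[[`, "", "var")
term_degree <- function(term) length(term$factors)

eval_term <- function(term, X) {
  out <- rep(1, nrow(X))
  for (h in term$factors) {
    if (!h$var %in% colnames(X))
      stop(sprintf("variable '%s' not found in design", h$var))
    out <- out * hinge_eval(h, X[, h$var])
  }
  out
}

#' Candidate knots for a predictor
#'
#' Knots are placed at the distinct observed values of the predictor,
#' sorted ascending. For large samples an optional cap thins the set to
#' evenly spaced order statistics of the distinct values.
#'
#' @param D A design matrix (see [to_design()]).
#' @param var Predictor name.
#' @param max_knots Cap on the number of candidates (default unlimited).
#' @return Sorted numeric vector of candidate knots.
#' @export
candidate_knots <- function(D, var, max_knots = Inf) {
  if (!var %in% colnames(D$X))
    stop(sprintf("unknown predictor '%s'", var))
  k <- sort(unique(D$X[, var]))
  if (is.finite(max_knots) && length(k) > max_knots)
    k <- k[unique(round(seq(1, length(k), length.out = max_knots)))]
  k
}

#' Basis matrix of a term list
#'
#' First column is the all-ones intercept; column `m + 1` is the row-wise
#' product of the hinge evaluations of term `m`.
#'
#' @param terms List of [basis_term] objects (possibly empty).
#' @param D A design matrix, or a numeric matrix with column names.
#' @return An `n x (1 + M)` numeric matrix.
#' @export
basis_matrix <- function(terms, D) {
  X <- if (inherits(D, "design_matrix")) D$X else as.matrix(D)
  n <- nrow(X)
  B <- matrix(1, n, 1 + length(terms))
  for (m in seq_along(terms)) B[, m + 1] <- eval_term(terms[[m]], X)
  B
}

#' Ordinary least squares on a basis matrix
#'
#' Minimises the residual sum of squares by pivoted QR; a rank-deficient
#' basis is resolved by the minimum-norm solution (Moore-Penrose
#' pseudo-inverse), so duplicated columns leave the fit unchanged.
#'
#' @param B Numeric matrix (n x k).
#' @param y Numeric response of length n.
#' @return List with `coefficients`, `rss` and `rank`.
#' @export
ols_fit <- function(B, y) {
  B <- as.matrix(B)
  if (nrow(B) != length(y))
    stop("ols_fit: nrow(B) must equal length(y)")
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    coef <- drop(MASS::ginv(B) %*% y)
  } else {
    coef <- as.numeric(qr.coef(qrB, y))
  }
  res <- y - drop(B %*% coef)
  list(coefficients = coef, rss = sum(res^2), rank = qrB$rank)
}

#' MARS fitting configuration
#'
#' @param max_terms Forward-pass term budget, counting the intercept.
#' @param max_degree Cap on the number of hinge factors per term.
#' @param penalty Per-knot complexity penalty `d` of the generalized
#'   cross-validation criterion.
#' @param gcv_convention How effective parameters are counted:
#'   `"knot_penalty"` charges `M + d (M - 1) / 2` for a model with `M`
#'   terms (each of the `(M - 1) / 2` reflected hinge pairs contributes one
#'   knot); `"eq4"` charges `(M - 1 + 1) + d (M - 1)`, i.e. one penalty
#'   unit per non-intercept term.
#' @param forbid_self_interaction Disallow a predictor from appearing twice
#'   within one product term.
#' @param max_knots Optional cap on candidate knots per predictor.
#' @param rss_tol Relative residual-sum-of-squares improvement below which
#'   the forward pass stops.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(max_terms = 21, max_degree = 3, penalty = 3,
                       gcv_convention = c("knot_penalty", "eq4"),
                       forbid_self_interaction = TRUE,
                       max_knots = Inf, rss_tol = 1e-10) {
  gcv_convention <- match.arg(gcv_convention)
  stopifnot(max_terms >= 1, max_degree >= 1, penalty >= 0, rss_tol >= 0)
  structure(list(max_terms = as.integer(max_terms),
                 max_degree = as.integer(max_degree),
                 penalty = penalty, gcv_convention = gcv_convention,
                 forbid_self_interaction = isTRUE(forbid_self_interaction),
                 max_knots = max_knots, rss_tol = rss_tol),
            class = "fit_config")
}

#' Effective number of parameters of a spline model
#'
#' The complexity charge entering the generalized cross-validation
#' denominator. Under the `"knot_penalty"` convention a model with `M`
#' terms (intercept included) is charged `M + d (M - 1) / 2`: one unit per
#' coefficient plus `d` per knot, where the `(M - 1) / 2` reflected hinge
#' pairs of the forward pass each contribute one knot. The `"eq4"`
#' convention charges `(lambda + 1) + d lambda` with `lambda = M - 1`
#' non-intercept terms.
#'
#' @param n_terms Total number of terms `M`, intercept included.
#' @param config A [fit_config].
#' @return Effective parameter count (real).
#' @export
effective_params <- function(n_terms, config = fit_config()) {
  stopifnot(n_terms >= 1)
  M <- n_terms
  if (config$gcv_convention == "knot_penalty") {
    M + config$penalty * (M - 1) / 2
  } else {
    lambda <- M - 1
    (lambda + 1) + config$penalty * lambda
  }
}

#' Generalized cross-validation criterion
#'
#' `GCV = (RSS / N) / (1 - C / N)^2` where `C` is the effective parameter
#' count: the per-observation residual error inflated by a complexity
#' penalty. The pruning pass minimises this quantity.
#'
#' @param rss Residual sum of squares.
#' @param n Number of training observations.
#' @param eff Effective number of parameters (must be < n).
#' @return The GCV value.
#' @export
gcv <- function(rss, n, eff) {
  if (eff >= n)
    stop("gcv: effective parameters must be smaller than the sample size")
  (rss / n) / (1 - eff / n)^2
}

#' Goodness-of-fit measures of a fitted spline model
#'
#' `RSq = 1 - RSS / TSS` and the generalized coefficient of determination
#' `GRSq = 1 - GCV / GCV_null`, where the null GCV is that of the
#' intercept-only model (RSS = TSS, one effective parameter) on the same
#' data. GRSq discounts RSq for model complexity and is at most RSq for
#' any penalised model with at least one hinge term.
#'
#' @param model A fitted [mars_fit()] model.
#' @param y The training response.
#' @return List with `rsq` and `grsq`.
#' @export
fit_measures <- function(model, y) {
  tss <- sum((y - mean(y))^2)
  if (tss <= 0)
    stop("fit_measures: response has zero total sum of squares")
  n <- model$n_train
  gcv_null <- gcv(tss, n, 1)
  list(rsq = 1 - model$rss / tss, grsq = 1 - model$gcv / gcv_null)
}
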