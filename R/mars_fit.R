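# Forward pair addition and GCV backward pruning.
#
# The forward pass scores every candidate (parent term, predictor, knot)
# through bordered normal equations -- cross-products of the current basis
# are updated with the two reflected hinge columns, so one candidate costs
# O(n) plus a small dense solve.  Accepted steps are refit by pivoted QR,
# which both restores full numerical accuracy for the recorded RSS and
# exposes exactly-collinear pair members (dropped deterministically).

# Solve the normal system G b = g; fall back to the pseudo-inverse when the
# system is singular (minimum-norm least squares).
solve_normal <- function(G, g) {
  b <- tryCatch(solve(G, g), error = function(e) NULL)
  if (is.null(b) || any(!is.finite(b))) b <- drop(MASS::ginv(G) %*% g)
  b
}

#' Forward pass: greedy reflected-pair addition
#'
#' Starting from the intercept-only model, each step searches over every
#' parent term (the intercept included), every predictor not already in
#' the parent, and every candidate knot, and adds the reflected hinge pair
#' `parent * max(0, x - t)`, `parent * max(0, t - x)` that minimises the
#' post-addition residual sum of squares. The search stops at the term
#' budget or when no addition improves RSS beyond a relative tolerance.
#' Ties are broken deterministically: lower parent degree, then parent
#' creation order, then predictor column order, then smaller knot.
#'
#' @param D A design matrix (see [to_design()]).
#' @param config A [fit_config].
#' @return List with `terms` (list of [basis_term], coefficients unset) and
#'   `rss_trace` (RSS after each accepted step, starting from the
#'   intercept-only model's RSS).
#' @export
forward_pass <- function(D, config = fit_config()) {
  y <- D$y
  X <- D$X
  n <- length(y)
  if (n < 2) stop("forward_pass: need at least two observations")
  p <- ncol(X)
  if (p < 1) stop("forward_pass: need at least one predictor")
  preds <- colnames(X)
  knots <- lapply(preds, function(v) candidate_knots(D, v, config$max_knots))
  names(knots) <- preds
  xmin <- apply(X, 2, min)

  terms <- list()
  B <- matrix(1, n, 1)
  yty <- sum(y^2)
  rss_cur <- ols_fit(B, y)$rss           # intercept-only RSS = TSS
  rss_trace <- rss_cur
  scale_rss <- max(rss_cur, .Machine$double.eps)

  make_pair_terms <- function(parent_factors, var, t) {
    lin <- (t == xmin[[var]])
    plus <- hinge(var, t, "+", linear = lin)
    minus <- hinge(var, t, "-")
    list(basis_term(c(parent_factors, list(plus))),
         basis_term(c(parent_factors, list(minus))))
  }

  while (1 + length(terms) + 2 <= config$max_terms) {
    if (rss_cur <= config$rss_tol * scale_rss) break
    G <- crossprod(B)
    g <- drop(crossprod(B, y))
    M <- ncol(B)
    # parent ordering: intercept (degree 0) first, then creation order;
    # terms are created in non-decreasing search preference already, but we
    # sort explicitly by (degree, index) to honour the tie-break contract
    pdeg <- c(0L, vapply(terms, term_degree, 0L))
    parent_order <- order(pdeg, seq_len(M))
    best <- NULL
    for (pi in parent_order) {
      deg <- pdeg[pi]
      if (deg + 1 > config$max_degree) next
      pvars <- if (pi == 1) character(0) else term_vars(terms[[pi - 1]])
      pcol <- B[, pi]
      for (j in seq_len(p)) {
        v <- preds[j]
        if (config$forbid_self_interaction && v %in% pvars) next
        x <- X[, j]
        tk <- knots[[v]]
        K <- length(tk)
        Dif <- outer(x, tk, "-")
        U <- pcol * pmax(Dif, 0)
        V <- pcol * pmax(-Dif, 0)
        BtU <- crossprod(B, U)
        BtV <- crossprod(B, V)
        Uy <- drop(crossprod(U, y))
        Vy <- drop(crossprod(V, y))
        UU <- colSums(U * U)
        VV <- colSums(V * V)
        UV <- colSums(U * V)
        for (k in seq_len(K)) {
          Ga <- rbind(cbind(G, BtU[, k], BtV[, k]),
                      c(BtU[, k], UU[k], UV[k]),
                      c(BtV[, k], UV[k], VV[k]))
          ga <- c(g, Uy[k], Vy[k])
          b <- solve_normal(Ga, ga)
          rss_raw <- yty - sum(ga * b)
          # an overshoot far below zero flags a blown-up near-singular
          # solve, not a genuinely better candidate
          if (!is.finite(rss_raw) || rss_raw < -1e-6 * yty) next
          rss_k <- max(rss_raw, 0)
          if (is.null(best) || rss_k < best$rss) {
            best <- list(rss = rss_k, parent = pi, var = v, knot = tk[k])
          }
        }
      }
    }
    if (is.null(best)) break
    if ((rss_cur - best$rss) <= config$rss_tol * max(rss_cur, scale_rss * 1e-6))
      break
    parent_factors <- if (best$parent == 1) list() else
      terms[[best$parent - 1]]$factors
    pair <- make_pair_terms(parent_factors, best$var, best$knot)
    # drop pair members whose basis column is identically zero (knot at an
    # extreme observed value) and aliased members (exact collinearity)
    new_terms <- terms
    added <- integer(0)
    for (tm in pair) {
      col <- eval_term(tm, X)
      if (all(col == 0)) next
      new_terms <- c(new_terms, list(tm))
      added <- c(added, length(new_terms))
    }
    if (!length(added)) break
    Bnew <- basis_matrix(new_terms, X)
    qrB <- qr(Bnew)
    if (qrB$rank < ncol(Bnew)) {
      aliased <- rep(FALSE, ncol(Bnew))
      aliased[qrB$pivot[-seq_len(qrB$rank)]] <- TRUE
      # only newly added terms may be dropped; an aliased old term would
      # indicate an earlier bookkeeping bug
      drop_new <- intersect(which(aliased) - 1L, added)
      if (length(drop_new)) {
        new_terms <- new_terms[-drop_new]
        if (length(new_terms) == length(terms)) break
        Bnew <- basis_matrix(new_terms, X)
      }
    }
    fit <- ols_fit(Bnew, y)
    if ((rss_cur - fit$rss) <= config$rss_tol * max(rss_cur, scale_rss * 1e-6))
      break
    terms <- new_terms
    B <- Bnew
    rss_cur <- fit$rss
    rss_trace <- c(rss_trace, rss_cur)
  }
  list(terms = terms, rss_trace = rss_trace)
}

#' Backward pass: GCV-driven pruning
#'
#' Starting from the forward-pass term set, iteratively deletes the single
#' term whose removal yields the lowest GCV, recording every visited
#' subset down to the intercept-only model, and returns the subset with
#' the global minimum GCV over the whole trace, refit by ordinary least
#' squares.
#'
#' @param terms Term list from [forward_pass()].
#' @param D The training design matrix.
#' @param config A [fit_config].
#' @return List with `model` (a `mars_model`) and `trace` (a
#'   `prune_trace`: `subsets` of (kept term indices, rss, gcv), the term
#'   definitions, and `best_index`).
#' @export
backward_pass <- function(terms, D, config = fit_config()) {
  y <- D$y
  n <- length(y)
  Bfull <- basis_matrix(terms, D$X)
  subset_stats <- function(keep) {
    f <- ols_fit(Bfull[, c(1L, keep + 1L), drop = FALSE], y)
    list(keep = keep, rss = f$rss,
         gcv = gcv(f$rss, n, effective_params(1 + length(keep), config)))
  }
  keep <- seq_along(terms)
  trace <- list(subset_stats(keep))
  while (length(keep) > 0) {
    cand <- lapply(seq_along(keep), function(i) subset_stats(keep[-i]))
    gcvs <- vapply(cand, `[[`, 0, "gcv")
    pick <- which.min(gcvs)          # first index on ties: deterministic
    trace[[length(trace) + 1L]] <- cand[[pick]]
    keep <- cand[[pick]]$keep
  }
  gcvs <- vapply(trace, `[[`, 0, "gcv")
  # intercept-only GCV (last trace entry) sets the natural scale; among
  # subsets tied with the minimum, prefer the most parsimonious
  tie_tol <- 1e-9 * trace[[length(trace)]]$gcv
  best_index <- max(which(gcvs <= min(gcvs) + tie_tol))
  best <- trace[[best_index]]
  ptrace <- structure(list(subsets = trace, best_index = best_index,
                           terms = terms),
                      class = "prune_trace")
  model <- build_mars_model(terms[best$keep], D, config)
  list(model = model, trace = ptrace)
}

build_mars_model <- function(terms, D, config) {
  y <- D$y
  n <- length(y)
  B <- basis_matrix(terms, D$X)
  f <- ols_fit(B, y)
  coefs <- f$coefficients
  terms <- lapply(seq_along(terms), function(m) {
    t <- terms[[m]]; t$coefficient <- coefs[m + 1]; t
  })
  g <- gcv(f$rss, n, effective_params(1 + length(terms), config))
  model <- structure(list(intercept = coefs[1], terms = terms, n_train = n,
                          rss = f$rss, gcv = g, rsq = NA_real_,
                          grsq = NA_real_, config = config,
                          predictors = colnames(D$X)),
                     class = "mars_model")
  fm <- fit_measures(model, y)
  model$rsq <- fm$rsq
  model$grsq <- fm$grsq
  model
}

#' Fit a multivariate adaptive regression splines model
#'
#' Runs the greedy forward pair-addition pass followed by the GCV backward
#' pruning pass and returns the pruned model together with the full
#' pruning trace. Fully deterministic given the design and configuration.
#'
#' @param D A design matrix (see [to_design()] / [design_matrix()]).
#' @param config A [fit_config].
#' @return List with `model` (class `mars_model`) and `trace` (class
#'   `prune_trace`).
#' @examples
#' set.seed(1)
#' x <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("x1", "x2")))
#' y <- 2 * pmax(0, x[, 1] - x[50, 1])
#' D <- design_matrix(y, x)
#' fit <- mars_fit(D, fit_config(max_terms = 7))
#' fit$model$rss
#' @export
mars_fit <- function(D, config = fit_config()) {
  fp <- forward_pass(D, config)
  bp <- backward_pass(fp$terms, D, config)
  bp$forward <- fp
  bp
}

#' Predict from a fitted spline model
#'
#' @param object A `mars_model`.
#' @param newdata A design matrix, numeric matrix with named columns, or
#'   data.frame containing every predictor the model uses.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.mars_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "design_matrix")) newdata$X else
    as.matrix(as.data.frame(newdata))
  used <- unique(unlist(lapply(object$terms, term_vars)))
  missing_vars <- setdiff(used, colnames(X))
  if (length(missing_vars))
    stop(sprintf("predict: missing variable(s): %s",
                 paste(missing_vars, collapse = ", ")))
  out <- rep(object$intercept, nrow(X))
  for (t in object$terms) out <- out + t$coefficient * eval_term(t, X)
  out
}

#' @export
print.mars_model <- function(x, ...) {
  cat(model_report(x), sep = "\n")
  invisible(x)
}

#' Subset-based variable importance
#'
#' Importance of each predictor as read off the backward-pruning trace:
#' `n_subsets` counts the visited subsets in which at least one term uses
#' the variable; the GCV score accumulates, over the deletion steps of the
#' trace, the GCV increase incurred when a term using the variable is
#' removed (credited to every variable in the deleted term), floored at
#' zero and rescaled so the top used variable scores 100; the RSS score is
#' built the same way from RSS increases. Predictors absent from the final
#' model are flagged unused and carry no scores.
#'
#' @param trace A `prune_trace` from [backward_pass()].
#' @param model The pruned `mars_model`.
#' @return A data.frame with columns `var`, `n_subsets`, `gcv_score`,
#'   `rss_score`, `used`, sorted by decreasing importance (unused
#'   predictors last).
#' @export
variable_importance <- function(trace, model) {
  stopifnot(inherits(trace, "prune_trace"))
  preds <- model$predictors
  terms <- trace$terms
  tvars <- lapply(terms, term_vars)
  subs <- trace$subsets
  nsub <- gacc <- racc <- stats::setNames(numeric(length(preds)), preds)
  for (s in subs) {
    in_sub <- unique(unlist(tvars[s$keep]))
    nsub[in_sub] <- nsub[in_sub] + 1
  }
  for (i in seq_len(length(subs) - 1)) {
    removed <- setdiff(subs[[i]]$keep, subs[[i + 1]]$keep)
    dg <- subs[[i + 1]]$gcv - subs[[i]]$gcv
    dr <- subs[[i + 1]]$rss - subs[[i]]$rss
    for (m in removed) {
      gacc[tvars[[m]]] <- gacc[tvars[[m]]] + dg
      racc[tvars[[m]]] <- racc[tvars[[m]]] + dr
    }
  }
  used_vars <- unique(unlist(lapply(model$terms, term_vars)))
  used <- preds %in% used_vars
  gacc <- pmax(gacc, 0)
  racc <- pmax(racc, 0)
  gs <- rs <- rep(NA_real_, length(preds))
  if (any(used)) {
    gmax <- max(gacc[used])
    rmax <- max(racc[used])
    gs[used] <- if (gmax > 0) 100 * gacc[used] / gmax else 100
    rs[used] <- if (rmax > 0) 100 * racc[used] / rmax else 100
  }
  out <- data.frame(var = preds, n_subsets = ifelse(used, nsub[preds], NA),
                    gcv_score = gs, rss_score = rs, used = used,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$used, -ifelse(is.na(out$n_subsets), -1, out$n_subsets),
                   -ifelse(is.na(out$gcv_score), -1, out$gcv_score)), ]
  rownames(out) <- NULL
  out
}

#' Ranked residual diagnostics
#'
#' Training-set residuals ranked by absolute size, for eyeballing
#' candidate outliers. No automatic exclusion is performed: observations
#' are reported, never removed.
#'
#' @param model A `mars_model`.
#' @param D The training design matrix.
#' @return data.frame with `row` (position in the design), `residual` and
#'   `abs_residual`, sorted by decreasing `abs_residual`; when the design
#'   carries a (country, year) row index it is included.
#' @export
residual_diagnostics <- function(model, D) {
  res <- D$y - predict(model, D)
  out <- data.frame(row = seq_along(res), residual = res,
                    abs_residual = abs(res))
  if (!is.null(D$row_index)) out <- cbind(out, D$row_index)
  out <- out[order(-out$abs_residual), ]
  rownames(out) <- NULL
  out
}
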