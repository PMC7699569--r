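# Text rendering of fitted models: the `max(VAR-KNOT)` term grammar, the
# summary block, and a full-precision plain-text serialization.

format_hinge <- function(h, digits = 5) {
  if (h$linear) return(h$var)
  k <- sprintf(paste0("%.", digits, "f"), h$knot)
  if (h$direction == "+") sprintf("max(%s-%s)", h$var, k)
  else sprintf("max(%s-%s)", k, h$var)
}

#' Render a basis term in the `max(var-knot)` grammar
#'
#' Factors are separated by a single space; a positive hinge renders as
#' `max(VAR-KNOT)`, a negative one as `max(KNOT-VAR)`, and a linear factor
#' as the bare variable name. Knots are printed to 5 decimals.
#'
#' @param term A [basis_term].
#' @param digits Decimals for knot values.
#' @return A single string.
#' @export
format_term <- function(term, digits = 5) {
  paste(vapply(term$factors, format_hinge, "", digits = digits),
        collapse = " ")
}

#' Parse a basis term from the `max(var-knot)` grammar
#'
#' Inverse of [format_term()] up to knot rounding: `max(VAR-KNOT)` yields a
#' positive hinge, `max(KNOT-VAR)` a negative one, and a bare name a
#' linear factor.
#'
#' @param text Term string, factors separated by whitespace.
#' @return A [basis_term] (coefficient unset).
#' @export
parse_term <- function(text) {
  toks <- regmatches(text, gregexpr("max\\([^)]*\\)|[A-Za-z_.][A-Za-z0-9_.]*",
                                    text))[[1]]
  if (!length(toks)) stop(sprintf("cannot parse term '%s'", text))
  factors <- lapply(toks, function(tk) {
    if (!grepl("^max\\(", tk)) return(hinge(tk, 0, "+", linear = TRUE))
    body <- sub("^max\\(", "", sub("\\)$", "", tk))
    m <- regmatches(body, regexec("^([A-Za-z_.][A-Za-z0-9_.]*)-(.+)$", body))[[1]]
    if (length(m) == 3 && !is.na(suppressWarnings(as.numeric(m[3]))))
      return(hinge(m[2], as.numeric(m[3]), "+"))
    m <- regmatches(body, regexec("^(.+?)-([A-Za-z_.][A-Za-z0-9_.]*)$", body))[[1]]
    if (length(m) == 3 && !is.na(suppressWarnings(as.numeric(m[2]))))
      return(hinge(m[3], as.numeric(m[2]), "-"))
    stop(sprintf("cannot parse hinge factor '%s'", tk))
  })
  basis_term(factors)
}

#' Plain-text report of a fitted spline model
#'
#' Lists the intercept and every basis term in the `max(var-knot)` grammar
#' with its coefficient, followed by the model's main features (GCV, RSS,
#' GRSq, RSq, selected-of-candidate term counts) and, when an importance
#' table is supplied, the predictor importance ordering.
#'
#' @param model A `mars_model`.
#' @param importance Optional table from [variable_importance()].
#' @param forward_terms Number of candidate terms the forward pass built,
#'   intercept included (defaults to the fitted count when unknown).
#' @return Character vector of report lines.
#' @export
model_report <- function(model, importance = NULL, forward_terms = NULL) {
  lines <- c("Corresponding Equations of the Model",
             sprintf("Intercept\t-\t%.5f", model$intercept))
  for (m in seq_along(model$terms)) {
    t <- model$terms[[m]]
    lines <- c(lines, sprintf("BF%d\t%s\t%.5f", m, format_term(t),
                              t$coefficient))
  }
  n_sel <- 1 + length(model$terms)
  n_cand <- if (is.null(forward_terms)) n_sel else forward_terms
  lines <- c(lines,
             "Main Features of the Model",
             sprintf("GCV:\t%.8f", model$gcv),
             sprintf("RSS:\t%.5f", model$rss),
             sprintf("GRSq:\t%.7f", model$grsq),
             sprintf("RSq:\t%.7f", model$rsq),
             sprintf("Terms (BFs):\tSelected %d of %d (including the intercept term)",
                     n_sel, n_cand))
  if (!is.null(importance)) {
    n_used <- sum(importance$used)
    order_txt <- paste(importance$var[importance$used], collapse = ", ")
    unused <- importance$var[!importance$used]
    lines <- c(lines,
               sprintf("Predictors:\tSelected %d of %d", n_used,
                       nrow(importance)),
               sprintf("Predictors importance (in order):\t%s%s", order_txt,
                       if (length(unused))
                         sprintf(" (unused: %s)", paste(unused, collapse = ", "))
                       else ""))
  }
  lines
}

#' Render an importance table as text
#'
#' One row per predictor with the subset count and the GCV/RSS scores
#' scaled to 100; unused predictors print as dashes.
#'
#' @param importance Table from [variable_importance()].
#' @return Character vector of lines.
#' @export
importance_report <- function(importance) {
  rows <- vapply(seq_len(nrow(importance)), function(i) {
    r <- importance[i, ]
    if (r$used)
      sprintf("%s\t%d\t%.1f\t%.1f", r$var, as.integer(r$n_subsets),
              r$gcv_score, r$rss_score)
    else sprintf("%s\t-\t-\t-", r$var)
  }, "")
  c("Variable\tNumber of Subsets\tGCV\tRSS", rows)
}

#' Serialize / restore a fitted spline model
#'
#' Plain structured text, one factor per line
#' (`var,direction,knot,linear`), values at 17 significant digits so the
#' restored model predicts identically.
#'
#' @param model A `mars_model`.
#' @param path Output (input) file path.
#' @return `write_mars_model` invisibly returns `path`; `read_mars_model`
#'   returns the restored `mars_model`.
#' @export
write_mars_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c("marspanel-model 1",
             sprintf("n_train %d", model$n_train),
             sprintf("intercept %s", num(model$intercept)),
             sprintf("rss %s", num(model$rss)),
             sprintf("gcv %s", num(model$gcv)),
             sprintf("rsq %s", num(model$rsq)),
             sprintf("grsq %s", num(model$grsq)),
             sprintf("penalty %s", num(model$config$penalty)),
             sprintf("gcv_convention %s", model$config$gcv_convention),
             sprintf("predictors %s", paste(model$predictors, collapse = ",")))
  for (t in model$terms) {
    lines <- c(lines, sprintf("term %s", num(t$coefficient)))
    for (h in t$factors)
      lines <- c(lines, sprintf("factor %s,%s,%s,%d", h$var, h$direction,
                                num(h$knot), as.integer(h$linear)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mars_model
#' @export
read_mars_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "marspanel-model"))
    stop(sprintf("'%s' is not a serialized model file", path))
  field <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    sub(paste0("^", key, " "), "", ln)
  }
  terms <- list()
  cur_factors <- NULL
  cur_coef <- NA_real_
  flush <- function() {
    if (!is.null(cur_factors))
      terms[[length(terms) + 1L]] <<- basis_term(cur_factors, cur_coef)
  }
  for (ln in lines) {
    if (startsWith(ln, "term ")) {
      flush()
      cur_coef <- as.numeric(sub("^term ", "", ln))
      cur_factors <- list()
    } else if (startsWith(ln, "factor ")) {
      p <- strsplit(sub("^factor ", "", ln), ",", fixed = TRUE)[[1]]
      cur_factors[[length(cur_factors) + 1L]] <-
        hinge(p[1], as.numeric(p[3]), p[2], linear = p[4] == "1")
    }
  }
  flush()
  structure(list(intercept = as.numeric(field("intercept")), terms = terms,
                 n_train = as.integer(field("n_train")),
                 rss = as.numeric(field("rss")),
                 gcv = as.numeric(field("gcv")),
                 rsq = as.numeric(field("rsq")),
                 grsq = as.numeric(field("grsq")),
                 config = fit_config(penalty = as.numeric(field("penalty")),
                                     gcv_convention = field("gcv_convention")),
                 predictors = strsplit(field("predictors"), ",")[[1]]),
            class = "mars_model")
}
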