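model_term <- function(kind, factors) {
  label <- switch(kind,
                  main = factors,
                  quadratic = paste0(factors, "^2"),
                  interaction = paste(factors, collapse = ":"))
  list(kind = kind, factors = factors, label = label)
}

#' Build the candidate term list for stepwise model selection
#'
#' Candidates are ordered deterministically: all main effects (in factor
#' order), then pure quadratic effects of numeric factors, then pairwise
#' interactions. Quadratic terms are never built for two-level categorical
#' factors (they would be constant), with a notice when quadratics were
#' requested and such factors are present.
#'
#' @param factors A `dsd_factors`.
#' @param include_quadratic Include pure quadratic terms (default `TRUE`).
#' @param include_interactions Include all pairwise interactions (default
#'   `FALSE`; screening designs rest on an effect-sparsity argument).
#' @return A list of model terms of class `model_terms`.
#' @examples
#' length(build_candidates(default_factors(5)))  # 5 main + 5 quadratic
#' @export
build_candidates <- function(factors, include_quadratic = TRUE,
                             include_interactions = FALSE) {
  factors <- as_dsd_factors(factors)
  if (nrow(factors) == 0L) stop("at least one factor is required")
  terms <- lapply(factors$name, function(f) model_term("main", f))
  if (include_quadratic) {
    num <- factors$name[factors$kind == "numeric"]
    skipped <- setdiff(factors$name, num)
    if (length(skipped))
      message("skipping quadratic terms for categorical2 factor(s): ",
              paste(skipped, collapse = ", "))
    terms <- c(terms, lapply(num, function(f) model_term("quadratic", f)))
  }
  if (include_interactions && nrow(factors) >= 2L) {
    pairs <- utils::combn(factors$name, 2L, simplify = FALSE)
    terms <- c(terms, lapply(pairs, function(p) model_term("interaction", p)))
  }
  structure(terms, class = "model_terms")
}

# evaluate term columns at a matrix of coded settings (columns = factors)
term_columns <- function(terms, X) {
  if (length(terms) == 0L)
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0L))
  cols <- vapply(terms, function(tm) {
    switch(tm$kind,
           main = X[, tm$factors[1L]],
           quadratic = X[, tm$factors[1L]]^2,
           interaction = X[, tm$factors[1L]] * X[, tm$factors[2L]])
  }, numeric(nrow(X)))
  cols <- matrix(cols, nrow = nrow(X))
  colnames(cols) <- vapply(terms, `[[`, character(1L), "label")
  cols
}

# two-sided t-test p-values of all non-intercept coefficients of an OLS fit
partial_pvalues <- function(M, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, M), y)
  k <- fit$rank
  df <- length(y) - k
  if (df < 1L || any(is.na(fit$coefficients)))
    return(rep(NA_real_, ncol(M)))
  R <- qr.R(fit$qr)[seq_len(k), seq_len(k), drop = FALSE]
  XtXi <- chol2inv(R)
  sigma2 <- sum(fit$residuals^2) / df
  se <- sqrt(diag(XtXi) * sigma2)
  tval <- fit$coefficients / se
  p <- 2 * stats::pt(-abs(tval), df)
  p[-1L]
}

#' Stepwise multiple linear regression for DoE evaluation
#'
#' Selects a multiple linear regression model by iterated
#' inclusion/exclusion on partial p-values: in every cycle the candidate
#' with the smallest partial p-value (two-sided t-test of its coefficient
#' when added to the current model) enters if it is below `p_enter`; then
#' the included term with the largest p-value leaves if it is above
#' `p_exit`. The procedure starts from the intercept-only model, with ties
#' broken by candidate order, and stops when a full cycle changes nothing.
#' The intercept is always retained. A term never enters when it would
#' leave fewer than 2 residual degrees of freedom, and candidates that are
#' collinear with the current model are skipped with a notice.
#'
#' @param design A `dsd_design` (or coded matrix with factor columns).
#' @param y Numeric response vector, one value per run.
#' @param candidates A `model_terms` list, e.g. from [build_candidates()].
#' @param p_enter Entry threshold on the partial p-value (default 0.05).
#' @param p_exit Exit threshold (default 0.10).
#' @param max_cycles Safety bound on enter/exit cycles (default 50).
#' @return An object of class `doe_fit`: intercept, selected `terms`,
#'   `coefficients`, per-term `p_values`, raw `residuals`,
#'   `sigma_residues` (raw-residual sd, denominator n - 1), `fitted`, and
#'   a selection `trace`.
#' @export
stepwise_select <- function(design, y, candidates, p_enter = 0.05,
                            p_exit = 0.10, max_cycles = 50L) {
  X <- as.matrix(design)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n)
    stop("response has ", n, " values but the design has ", nrow(X), " runs")
  if (!inherits(candidates, "model_terms"))
    candidates <- structure(candidates, class = "model_terms")
  C <- term_columns(candidates, X)
  labels <- colnames(C)
  selected <- integer(0)
  trace <- list()
  cycle <- 0L
  y_scale <- max(sum((y - mean(y))^2), 1e-12)
  current_rss <- function(sel)
    sum(stats::lm.fit(cbind(1, C[, sel, drop = FALSE]), y)$residuals^2)
  repeat {
    cycle <- cycle + 1L
    if (cycle > max_cycles)
      stop("stepwise selection did not converge within ", max_cycles,
           " cycles")
    changed <- FALSE
    # a numerically perfect fit makes further partial p-values meaningless
    if (current_rss(selected) <= 1e-12 * y_scale) break
    # entry step: candidate with the smallest partial p-value below p_enter
    avail <- setdiff(seq_along(candidates), selected)
    if (length(avail) && n - (length(selected) + 2L) >= 2L) {
      entry_p <- rep(NA_real_, length(avail))
      for (k in seq_along(avail)) {
        j <- avail[k]
        M <- C[, c(selected, j), drop = FALSE]
        if (qr(cbind(1, M))$rank < ncol(M) + 1L) {
          message("candidate '", labels[j],
                  "' is collinear with the current model; skipped")
          next
        }
        pv <- partial_pvalues(M, y)
        entry_p[k] <- pv[length(pv)]
      }
      if (any(!is.na(entry_p)) && min(entry_p, na.rm = TRUE) < p_enter) {
        k <- which.min(entry_p)  # ties: first in candidate order
        selected <- c(selected, avail[k])
        trace[[length(trace) + 1L]] <-
          data.frame(cycle = cycle, action = "enter",
                     term = labels[avail[k]], p_value = entry_p[k])
        changed <- TRUE
      }
    }
    # exit step: included term with the largest p-value above p_exit
    if (length(selected)) {
      pv <- partial_pvalues(C[, selected, drop = FALSE], y)
      if (any(is.na(pv)))
        stop("selected model became rank deficient; candidates: ",
             paste(labels[selected], collapse = ", "))
      if (max(pv) > p_exit) {
        k <- which.max(pv)
        trace[[length(trace) + 1L]] <-
          data.frame(cycle = cycle, action = "exit",
                     term = labels[selected[k]], p_value = pv[k])
        selected <- selected[-k]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  Msel <- C[, selected, drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Msel), y)
  coefs <- fit$coefficients
  pv <- if (length(selected)) partial_pvalues(Msel, y) else numeric(0)
  res <- as.numeric(fit$residuals)
  structure(list(
    intercept = unname(coefs[1L]),
    terms = candidates[selected],
    coefficients = if (length(selected))
      stats::setNames(as.numeric(coefs[-1L]), labels[selected])
    else stats::setNames(numeric(0), character(0)),
    p_values = if (length(selected))
      stats::setNames(pv, labels[selected]) else numeric(0),
    residuals = res,
    fitted = as.numeric(fit$fitted.values),
    sigma_residues = stats::sd(res),
    n = n,
    factors = if (inherits(design, "dsd_design")) design_factors(design),
    trace = if (length(trace)) do.call(rbind, trace)
            else data.frame(cycle = integer(0), action = character(0),
                            term = character(0), p_value = numeric(0))
  ), class = "doe_fit")
}

#' Refit a fixed term set by ordinary least squares
#'
#' Fits the given terms (plus intercept) without any selection; used to
#' verify that the final stepwise model is independent of its selection
#' path, and to build user-specified models for worst-case prediction.
#'
#' @inheritParams stepwise_select
#' @param terms A `model_terms` list to fit as-is.
#' @return A `doe_fit` with an empty trace.
#' @export
fit_terms <- function(design, y, terms) {
  if (!inherits(terms, "model_terms"))
    terms <- structure(terms, class = "model_terms")
  stepwise_select(design, y, terms, p_enter = Inf, p_exit = Inf,
                  max_cycles = length(terms) + 2L)
}

#' @export
print.doe_fit <- function(x, ...) {
  cat(sprintf("DoE model fit: intercept %.5g, %d selected term(s), n = %d\n",
              x$intercept, length(x$terms), x$n))
  if (length(x$terms)) {
    df <- data.frame(term = names(x$coefficients),
                     coefficient = unname(x$coefficients),
                     p_value = unname(x$p_values))
    print(df, row.names = FALSE)
  }
  cat(sprintf("Residual sd (raw, n-1): %.5g\n", x$sigma_residues))
  invisible(x)
}

#' Predict from a fitted DoE model
#'
#' @param object A `doe_fit`.
#' @param newdata Matrix or data frame of coded factor settings with named
#'   columns covering every factor used by the model.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.doe_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X)))
    stop("newdata must have named factor columns")
  used <- unique(unlist(lapply(object$terms, `[[`, "factors")))
  missing <- setdiff(used, colnames(X))
  if (length(missing))
    stop("newdata is missing factor column(s): ",
         paste(missing, collapse = ", "))
  if (length(object$terms) == 0L)
    return(rep(object$intercept, nrow(X)))
  cols <- term_columns(object$terms, X)
  drop(object$intercept + cols %*% object$coefficients)
}

#' Ratio of model residual sd to set-point sd
#'
#' A diagnostic for the validity of the a priori noise assumption: values
#' well above 1 mean the DoE's unmodelled variance is much larger than the
#' set-point estimate it was planned with, and the a priori power was
#' over-optimistic. Computed from raw residuals with denominator
#' `sqrt(n - 1)` by default; `method = "ols"` uses the usual
#' `n - q - 1` denominator instead.
#'
#' @param model A `doe_fit`.
#' @param sp An `sp_sample` of set-point replicates.
#' @param method `"raw"` (default, denominator n - 1) or `"ols"`.
#' @return Dimensionless ratio `sigma_residues / sigma_SP`.
#' @export
residual_sd_ratio <- function(model, sp, method = c("raw", "ols")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "doe_fit"))
  if (!inherits(sp, "sp_sample")) sp <- set_point_sample(sp)
  num <- if (method == "raw") model$sigma_residues
  else {
    df <- model$n - length(model$terms) - 1L
    if (df < 1L) stop("no residual degrees of freedom for method 'ols'")
    sqrt(sum(model$residuals^2) / df)
  }
  num / sp$sd
}
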