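#' Specific clearance of a unit operation
#'
#' The specific clearance of an impurity across one unit operation is the
#' ratio of its specific concentration (mass of impurity per mass of
#' product) in the load over that in the pool:
#' `SC = c_load / c_pool`. Values above 1 mean the step clears the
#' impurity.
#'
#' @param c_load Specific concentration before the unit operation (>= 0).
#' @param c_pool Specific concentration after the unit operation (> 0).
#' @return Dimensionless clearance ratio.
#' @examples
#' specific_clearance(2, 1)  # 2
#' @export
specific_clearance <- function(c_load, c_pool) {
  if (any(!is.finite(c_load)) || any(!is.finite(c_pool)))
    stop("specific concentrations must be finite")
  if (any(c_load < 0))
    stop("c_load must be >= 0")
  if (any(c_pool <= 0))
    stop("c_pool must be > 0")
  c_load / c_pool
}

#' Intermediate-stage threshold from a drug-substance specification
#'
#' The acceptance threshold at an intermediate unit operation is obtained
#' by back-calculating the drug-substance upper specification limit through
#' the mean specific clearance factors of all downstream unit operations:
#' `threshold = USL * prod(SC_u)` for u from the studied step to drug
#' substance.
#'
#' @param usl_ds Drug-substance upper specification limit, in CQA units.
#' @param clearances Numeric vector of specific clearance factors, one per
#'   downstream unit operation; all > 0.
#' @return Threshold in the intermediate stage's CQA units.
#' @examples
#' threshold_from_usl(0.1, c(3, 3))  # 0.9
#' @export
threshold_from_usl <- function(usl_ds, clearances) {
  if (!is.numeric(usl_ds) || length(usl_ds) != 1L || !is.finite(usl_ds))
    stop("usl_ds must be a single finite number")
  if (is.null(clearances) || length(clearances) == 0L)
    stop("a drug-substance USL requires at least one clearance factor")
  if (any(!is.finite(clearances)) || any(clearances <= 0))
    stop("all clearance factors must be finite and > 0")
  usl_ds * prod(clearances)
}

#' Define a CQA with its threshold information
#'
#' A critical quality attribute is specified either through the
#' drug-substance USL plus the chain of downstream specific clearance
#' factors (from which the intermediate threshold is derived), or through a
#' directly supplied intermediate threshold. `direction` states on which
#' side of the threshold quality is acceptable: `"upper"` (default; the
#' response must stay below the threshold) or `"lower"`.
#'
#' @param name CQA name.
#' @param usl_ds Drug-substance upper specification limit; mutually
#'   exclusive with `threshold_direct`.
#' @param threshold_direct Intermediate-stage threshold, given directly.
#' @param clearances Specific clearance factors (used only with `usl_ds`).
#' @param direction `"upper"` or `"lower"`.
#' @return An object of class `cqa_spec`.
#' @export
cqa_spec <- function(name, usl_ds = NULL, threshold_direct = NULL,
                     clearances = NULL, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  if (is.null(usl_ds) == is.null(threshold_direct))
    stop("supply exactly one of usl_ds / threshold_direct for CQA '",
         name, "'")
  if (!is.null(usl_ds)) {
    threshold <- threshold_from_usl(usl_ds, clearances)
  } else {
    if (!is.numeric(threshold_direct) || length(threshold_direct) != 1L ||
        !is.finite(threshold_direct))
      stop("threshold_direct must be a single finite number")
    threshold <- threshold_direct
  }
  structure(list(name = as.character(name), usl_ds = usl_ds,
                 threshold_direct = threshold_direct,
                 clearances = clearances, direction = direction,
                 threshold = threshold),
            class = "cqa_spec")
}

#' @export
print.cqa_spec <- function(x, ...) {
  cat(sprintf("CQA '%s': threshold %.6g (%s limit)%s\n", x$name, x$threshold,
              x$direction,
              if (!is.null(x$usl_ds))
                sprintf(", from USL %.6g x %d clearance factor(s)",
                        x$usl_ds, length(x$clearances)) else ""))
  invisible(x)
}

cqa_threshold <- function(cqa) {
  if (inherits(cqa, "cqa_spec")) return(cqa$threshold)
  if (is.numeric(cqa) && length(cqa) == 1L && is.finite(cqa)) return(cqa)
  stop("cqa must be a cqa_spec or a single numeric threshold")
}

cqa_direction <- function(cqa, default = "upper") {
  if (inherits(cqa, "cqa_spec")) cqa$direction else default
}

new_critical_gap <- function(value, basis, location = NULL) {
  structure(list(value = value, basis = basis, location = location),
            class = "critical_gap")
}

#' @export
print.critical_gap <- function(x, ...) {
  cat(sprintf("Critical gap: %.6g (basis: %s)\n", x$value, x$basis))
  invisible(x)
}

cg_value <- function(cg) {
  if (inherits(cg, "critical_gap")) cg$value
  else if (is.numeric(cg) && length(cg) == 1L) as.numeric(cg)
  else stop("cg must be a critical_gap or a single number")
}

#' Critical gap at set-point conditions
#'
#' The critical gap is the signed distance from the mean set-point response
#' to the intermediate-stage threshold: `threshold - y_sp` for an upper
#' limit, `y_sp - threshold` for a lower one. A non-positive gap means the
#' process already violates (or sits on) the threshold at set point; this
#' is raised as an error rather than silently clamped, because the whole
#' criticality assessment presumes a gap left to protect.
#'
#' @param threshold Intermediate threshold (or a `cqa_spec`, from which the
#'   threshold and direction are taken).
#' @param y_sp_mean Mean response at set-point conditions.
#' @param direction `"upper"` or `"lower"`; ignored when `threshold` is a
#'   `cqa_spec`.
#' @return A `critical_gap` object with `basis = "set_point"`.
#' @export
critical_gap_setpoint <- function(threshold, y_sp_mean,
                                  direction = c("upper", "lower")) {
  if (inherits(threshold, "cqa_spec")) {
    direction <- threshold$direction
    threshold <- threshold$threshold
  } else {
    direction <- match.arg(direction)
  }
  if (!is.finite(threshold) || !is.finite(y_sp_mean))
    stop("threshold and y_sp_mean must be finite")
  value <- if (direction == "upper") threshold - y_sp_mean
           else y_sp_mean - threshold
  if (value <= 0)
    stop("set-point response is already beyond (or on) the threshold: ",
         sprintf("gap = %.6g <= 0; the criticality assessment presumes ",
                 value),
         "a positive gap")
  new_critical_gap(value, "set_point")
}

#' Worst-case model prediction over the NOR box
#'
#' Finds the extreme prediction of a fitted DoE model over the normal
#' operating range box (the Cartesian product of all factors' NOR
#' intervals): the maximum for an upper limit, the minimum for a lower one.
#' For additive models (main + pure quadratic terms) every coordinate is
#' optimised in closed form; with interaction terms the optimum is located
#' by vertex enumeration refined by exact coordinate ascent. Factors absent
#' from the model are reported at their set point.
#'
#' @param model A `doe_fit` (see [stepwise_select()]).
#' @param factors A `dsd_factors` giving the NOR box.
#' @param direction `"upper"` (maximise) or `"lower"` (minimise).
#' @return A list with `value` (the extreme prediction) and `location`
#'   (named coded coordinates attaining it).
#' @export
worst_case_prediction <- function(model, factors,
                                  direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  factors <- as_dsd_factors(factors)
  stopifnot(inherits(model, "doe_fit"))
  used <- unique(unlist(lapply(model$terms, `[[`, "factors")))
  unknown <- setdiff(used, factors$name)
  if (length(unknown))
    stop("model uses factor(s) absent from the specification: ",
         paste(unknown, collapse = ", "))
  sign <- if (direction == "upper") 1 else -1

  p <- nrow(factors)
  lo <- factors$nor_low; hi <- factors$nor_high
  names(lo) <- names(hi) <- factors$name
  loc <- factors$set_point
  names(loc) <- factors$name
  if (length(model$terms) == 0L)
    return(list(value = model$intercept, location = loc))

  # quadratic-form representation: f(x) = b0 + b'x + x'diag(a)x + interactions
  a <- b <- stats::setNames(numeric(p), factors$name)
  inter <- list()
  for (i in seq_along(model$terms)) {
    tm <- model$terms[[i]]
    cf <- model$coefficients[[tm$label]]
    if (tm$kind == "main") b[tm$factors] <- b[tm$factors] + cf
    else if (tm$kind == "quadratic") a[tm$factors] <- a[tm$factors] + cf
    else inter[[length(inter) + 1L]] <- list(f = tm$factors, cf = cf)
  }
  active <- factors$name[abs(a) > 0 | abs(b) > 0 |
                           factors$name %in% unlist(lapply(inter, `[[`, "f"))]

  eval_f <- function(x) {
    v <- model$intercept + sum(b * x) + sum(a * x^2)
    for (it in inter) v <- v + it$cf * x[it$f[1L]] * x[it$f[2L]]
    unname(v)
  }
  # exact 1-D optimum of a*t^2 + b*t over [l, u] (maximising sign * f)
  opt1d <- function(ai, bi, l, u) {
    cand <- c(l, u)
    if (ai != 0) {
      s <- -bi / (2 * ai)
      if (s > l && s < u) cand <- c(cand, s)
    }
    cand[which.max(sign * (ai * cand^2 + bi * cand))]
  }

  if (length(inter) == 0L) {
    # additive model: separable closed form
    for (f in active) loc[f] <- opt1d(a[f], b[f], lo[f], hi[f])
    return(list(value = eval_f(loc), location = loc))
  }

  # interactions present: vertex enumeration + coordinate-ascent polish
  if (length(active) > 12L)
    stop("worst-case search supports at most 12 active factors")
  grid <- as.matrix(expand.grid(lapply(active, function(f) c(lo[f], hi[f]))))
  colnames(grid) <- active
  starts <- rbind(grid, matrix((lo[active] + hi[active]) / 2, nrow = 1,
                               dimnames = list(NULL, active)))
  best <- NULL; best_v <- -Inf
  for (s in seq_len(nrow(starts))) {
    x <- loc
    x[active] <- starts[s, active]
    repeat {
      changed <- FALSE
      for (f in active) {
        # effective linear coefficient of x_f given the other coordinates
        beff <- b[f]
        for (it in inter) {
          if (it$f[1L] == f) beff <- beff + it$cf * x[it$f[2L]]
          if (it$f[2L] == f) beff <- beff + it$cf * x[it$f[1L]]
        }
        xn <- opt1d(a[f], beff, lo[f], hi[f])
        if (abs(xn - x[f]) > 1e-12) { x[f] <- xn; changed <- TRUE }
      }
      if (!changed) break
    }
    v <- eval_f(x)
    if (sign * v > sign * best_v || is.null(best)) { best <- x; best_v <- v }
  }
  list(value = best_v, location = best)
}

#' Critical gap from the worst-case prediction in the NOR
#'
#' The retrospective-power assessment uses the gap between the threshold
#' and the worst-case prediction of the selected model over the NOR box
#' (rather than the set-point mean): `CG = threshold - max_NOR(yhat)` for
#' an upper limit. Tightening the NOR of a factor that is in the model
#' moves the worst-case prediction away from the threshold and therefore
#' enlarges this gap.
#'
#' @inheritParams critical_gap_setpoint
#' @param model A `doe_fit`.
#' @param factors A `dsd_factors` giving the NOR box.
#' @return A `critical_gap` with `basis = "worst_case"` and the attaining
#'   `location`.
#' @export
critical_gap_worstcase <- function(threshold, model, factors,
                                   direction = c("upper", "lower")) {
  if (inherits(threshold, "cqa_spec")) {
    direction <- threshold$direction
    threshold <- threshold$threshold
  } else {
    direction <- match.arg(direction)
  }
  wc <- worst_case_prediction(model, factors, direction)
  value <- if (direction == "upper") threshold - wc$value
           else wc$value - threshold
  if (value <= 0)
    stop("worst-case model prediction within the NOR is already beyond ",
         sprintf("(or on) the threshold: gap = %.6g <= 0", value))
  new_critical_gap(value, "worst_case", location = wc$location)
}

#' Critical effect size of a process parameter
#'
#' The critical effect of parameter i under weight w is the regression
#' coefficient just large enough for the parameter, moved to its farthest
#' NOR bound, to consume its weighted share of the critical gap:
#' `beta_crit = w * CG / max(nor_high - sp, sp - nor_low)`. Dividing by the
#' longest set-point-to-bound distance is the risk-conservative choice and
#' handles asymmetric NORs.
#'
#' @param w Weight in \[0, 1\]: the fraction of the critical gap attributed
#'   to this parameter.
#' @param cg A `critical_gap` (or positive number).
#' @param factor A single-row `dsd_factors` (or a row index into one).
#' @return Critical coefficient magnitude, in CQA units per coded unit.
#' @examples
#' f <- factor_specs("x", nor_low = -0.5, nor_high = 1.1)
#' critical_effect(0.5, 2, f)  # 0.5 * 2 / 1.1
#' @export
critical_effect <- function(w, cg, factor) {
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("w must lie in [0, 1]")
  cg <- cg_value(cg)
  if (cg <= 0) stop("critical gap must be > 0")
  factor <- as_dsd_factors(factor)
  if (nrow(factor) != 1L) stop("supply exactly one factor")
  d <- max(factor$nor_high - factor$set_point,
           factor$set_point - factor$nor_low)
  if (d <= 0)
    stop("degenerate NOR: both half-widths of factor '", factor$name,
         "' are zero")
  w * cg / d
}

# vector of signed critical effects for a set of factors, one weight each;
# the sign pushes predictions toward the threshold (+ for upper limits)
beta_crit_vector <- function(weights, cg, factors, direction = "upper") {
  factors <- as_dsd_factors(factors)
  stopifnot(length(weights) == nrow(factors))
  d <- pmax(factors$nor_high - factors$set_point,
            factors$set_point - factors$nor_low)
  if (any(d <= 0)) stop("degenerate NOR for factor(s): ",
                        paste(factors$name[d <= 0], collapse = ", "))
  s <- if (direction == "upper") 1 else -1
  stats::setNames(s * weights * cg_value(cg) / d, factors$name)
}
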