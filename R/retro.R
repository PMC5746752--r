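#' Configuration for the retrospective-power permutation test
#'
#' @param alpha Significance level for declaring an injected critical
#'   effect detected (default 0.05); must lie in (0, 0.5).
#' @param n_iterations Permutation count (default 1000): per weight
#'   combination under the `"per_combination"` strategy, or in total under
#'   `"sampled"` (each iteration draws a combination uniformly). At least
#'   100.
#' @param step_count Weight-grid steps per non-significant parameter
#'   (default 100, i.e. C = p * 100 combinations).
#' @param rng_seed Integer seed; the whole permutation loop is driven by a
#'   single seeded generator, so results are bit-reproducible.
#' @param combination_strategy `"per_combination"` (default) or
#'   `"sampled"`.
#' @return A list of class `retro_config`.
#' @export
retro_config <- function(alpha = 0.05, n_iterations = 1000L,
                         step_count = 100L, rng_seed = 1L,
                         combination_strategy = c("per_combination",
                                                  "sampled")) {
  combination_strategy <- match.arg(combination_strategy)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5)
    stop("alpha must lie in (0, 0.5)")
  if (!is.numeric(n_iterations) || n_iterations < 100L)
    stop("n_iterations must be at least 100")
  if (!is.numeric(step_count) || step_count < 1L)
    stop("step_count must be >= 1")
  structure(list(alpha = alpha, n_iterations = as.integer(n_iterations),
                 step_count = as.integer(step_count),
                 rng_seed = as.integer(rng_seed),
                 combination_strategy = combination_strategy),
            class = "retro_config")
}

# run a block with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Randomly permute model residuals
#'
#' Draws one uniformly random permutation (without replacement) of the
#' residual vector, preserving its multiset of values. Uses R's global
#' random number generator; seed it (or use [retro_config()]'s
#' `rng_seed`) for reproducibility.
#'
#' @param residuals Numeric vector of model residuals.
#' @return Permuted residual vector of the same length.
#' @export
permute_residuals <- function(residuals) {
  if (length(residuals) < 2L) return(residuals)
  residuals[sample.int(length(residuals))]
}

#' Synthesize a response under the critical-effect alternative
#'
#' Builds `y* = beta0 + X_s beta_s + Z beta_crit + R*`: the selected
#' model's deterministic part, plus the injected critical effects on the
#' non-significant parameters, plus a permuted copy of the model
#' residuals. This is the alternative-hypothesis response the permutation
#' test refits.
#'
#' @param intercept Model intercept `beta0`.
#' @param beta_s Coefficients of the selected (significant) terms; may be
#'   empty.
#' @param X_s `n x s` matrix of selected-term columns; may have 0 columns.
#' @param beta_crit Injected critical-effect coefficients, one per
#'   non-significant parameter.
#' @param Z `n x p_ns` matrix of non-significant parameters' main-effect
#'   columns.
#' @param permuted_residuals Permuted residual vector, length `n`.
#' @return Numeric response vector `y*` of length `n`.
#' @export
synthesize_alternative <- function(intercept, beta_s, X_s, beta_crit, Z,
                                   permuted_residuals) {
  X_s <- as.matrix(X_s); Z <- as.matrix(Z)
  n <- length(permuted_residuals)
  if (nrow(X_s) != n || nrow(Z) != n)
    stop("X_s, Z and permuted_residuals must agree on the run count")
  if (ncol(X_s) != length(beta_s))
    stop("beta_s has length ", length(beta_s), " but X_s has ",
         ncol(X_s), " columns")
  if (ncol(Z) != length(beta_crit))
    stop("beta_crit has length ", length(beta_crit), " but Z has ",
         ncol(Z), " columns")
  drop(intercept + X_s %*% beta_s + Z %*% beta_crit) + permuted_residuals
}

#' Test significance of injected critical effects
#'
#' Fits one ordinary least-squares model of `y*` on the intercept, the
#' selected terms `X_s` and all non-significant parameters `Z`, and
#' reports for each `Z` column whether its two-sided coefficient t-test
#' p-value is below `alpha`.
#'
#' @param y_star Synthesized response vector.
#' @param X_s Selected-term columns (may have 0 columns).
#' @param Z Non-significant parameters' main-effect columns.
#' @param alpha Significance level (default 0.05).
#' @return Named logical vector (one element per `Z` column) with the
#'   p-values attached as attribute `"p_values"`.
#' @export
assess_significance <- function(y_star, X_s, Z, alpha = 0.05) {
  X_s <- as.matrix(X_s); Z <- as.matrix(Z)
  M <- cbind(`(Intercept)` = 1, X_s, Z)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1L):ncol(M)]]
    stop("design for the permutation refit is rank deficient; offending ",
         "column(s): ", paste(bad, collapse = ", "))
  }
  n <- length(y_star)
  df <- n - ncol(M)
  if (df < 1L) stop("no residual degrees of freedom in the permutation refit")
  pv <- partial_pvalues(cbind(X_s, Z), y_star)
  zp <- pv[ncol(X_s) + seq_len(ncol(Z))]
  names(zp) <- colnames(Z)
  structure(stats::setNames(zp < alpha, colnames(Z)), p_values = zp)
}

# Vectorized permutation batch: for a fixed mean vector mu and model matrix
# M (with intercept), permute `residuals` B times, refit by OLS, and return
# a (#z_cols x B) logical matrix of |t| > t_crit for the given columns.
perm_sig_batch <- function(mu, residuals, M, z_cols, B, alpha) {
  n <- length(mu)
  idx <- apply(matrix(stats::runif(n * B), n, B), 2L, order)
  Y <- mu + matrix(residuals[idx], n, B)
  XtXi <- chol2inv(chol(crossprod(M)))
  coefs <- XtXi %*% crossprod(M, Y)
  rss <- colSums((Y - M %*% coefs)^2)
  df <- n - ncol(M)
  sigma2 <- rss / df
  d <- diag(XtXi)[z_cols]
  tcrit <- stats::qt(1 - alpha / 2, df)
  abs(coefs[z_cols, , drop = FALSE]) > tcrit * sqrt(outer(d, sigma2))
}

#' Retrospective power of non-significant parameters
#'
#' The permutation test at the heart of the criticality assessment. After
#' stepwise selection, every parameter left out of the model is tested for
#' the *alternative* that it carries a critical effect: for each
#' effect-weight combination, critical effects are derived from the
#' worst-case critical gap, injected on the non-significant parameters'
#' design columns on top of the fitted model, the model residuals are
#' randomly permuted, and the augmented model is refit. The fraction of
#' refits in which a parameter's injected coefficient comes out
#' significant, over all permutations and weight combinations, is its
#' retrospective power — the chance a critical effect of that parameter
#' would have been detected by this experiment, had it been present.
#'
#' Factors count as significant when any selected model term involves them
#' (main, quadratic or interaction); only fully uninvolved factors enter
#' the non-significant set `Z`.
#'
#' @param design A `dsd_design`.
#' @param response Numeric response vector (one value per run); used only
#'   through the fitted model, echoed for provenance.
#' @param factors A `dsd_factors`; defaults to the design's. Supply a
#'   modified copy to study tightened NORs.
#' @param cqa A `cqa_spec` (or a single numeric upper threshold).
#' @param model The `doe_fit` selected on this design/response.
#' @param config A `retro_config`.
#' @return An object of class `retro_power`: `per_parameter_power` (named,
#'   one entry per non-significant factor), `per_combination` data frame
#'   of per-combination significance fractions, `cg_used`, the factor and
#'   config echo. If no non-significant parameters remain, all elements
#'   are empty and a message is emitted.
#' @export
retrospective_power <- function(design, response, factors = NULL, cqa,
                                model, config = retro_config()) {
  stopifnot(inherits(model, "doe_fit"), inherits(config, "retro_config"))
  if (is.null(factors)) factors <- design_factors(design)
  factors <- as_dsd_factors(factors)
  X <- as.matrix(design)[, factors$name, drop = FALSE]
  n <- nrow(X)
  if (length(model$residuals) != n)
    stop("model was not fitted on this design (run counts differ)")
  direction <- cqa_direction(cqa)
  sig <- unique(unlist(lapply(model$terms, `[[`, "factors")))
  nonsig <- setdiff(factors$name, sig)
  if (length(nonsig) == 0L) {
    message("all parameters are involved in the selected model; ",
            "nothing to assess retrospectively")
    return(structure(list(per_parameter_power = stats::setNames(numeric(0),
                                                                character(0)),
                          per_combination = NULL, cg_used = NULL,
                          significant_factors = sig, factors = factors,
                          config = config),
                     class = "retro_power"))
  }
  cg <- critical_gap_worstcase(cqa, model, factors, direction)
  fns <- factors[match(nonsig, factors$name), , drop = FALSE]
  Xs <- term_columns(model$terms, X)
  Z <- X[, nonsig, drop = FALSE]
  M <- cbind(`(Intercept)` = 1, Xs, Z)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1L):ncol(M)]]
    stop("permutation refit design is rank deficient; offending ",
         "column(s): ", paste(bad, collapse = ", "))
  }
  z_cols <- ncol(M) - length(nonsig) + seq_along(nonsig)
  mu_base <- model$fitted
  W <- weight_grid(length(nonsig), config$step_count)
  C <- nrow(W)
  strategy <- config$combination_strategy

  with_seed(config$rng_seed, {
    iters <- if (strategy == "per_combination") {
      rep(config$n_iterations, C)
    } else {
      tabulate(sample.int(C, config$n_iterations, replace = TRUE), C)
    }
    frac <- matrix(NA_real_, C, length(nonsig),
                   dimnames = list(NULL, nonsig))
    counts <- stats::setNames(numeric(length(nonsig)), nonsig)
    for (c_idx in seq_len(C)) {
      if (iters[c_idx] == 0L) next
      bc <- beta_crit_vector(W[c_idx, ], cg, fns, direction)
      mu <- mu_base + drop(Z %*% bc)
      sig_mat <- perm_sig_batch(mu, model$residuals, M, z_cols,
                                iters[c_idx], config$alpha)
      frac[c_idx, ] <- rowMeans(sig_mat)
      counts <- counts + rowSums(sig_mat)
    }
  })
  per_param <- counts / sum(iters)
  per_comb <- data.frame(combination = seq_len(C),
                         parameter = nonsig[attr(W, "param")],
                         a = attr(W, "a"),
                         n_iterations = iters)
  per_comb <- cbind(per_comb, as.data.frame(frac))
  structure(list(per_parameter_power = per_param,
                 per_combination = per_comb,
                 cg_used = cg,
                 significant_factors = sig,
                 factors = factors,
                 config = config),
            class = "retro_power")
}

#' @export
print.retro_power <- function(x, ...) {
  if (length(x$per_parameter_power) == 0L) {
    cat("Retrospective power: no non-significant parameters to assess\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Retrospective power (CG = %.5g, worst-case basis; alpha = %.3g, %s, %d iterations)\n",
    x$cg_used$value, x$config$alpha, x$config$combination_strategy,
    x$config$n_iterations))
  df <- data.frame(parameter = names(x$per_parameter_power),
                   power = unname(x$per_parameter_power))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Scan retrospective power under NOR tightening
#'
#' Re-runs the retrospective power assessment after symmetrically
#' shrinking one factor's NOR about its set point by each given fraction,
#' re-deriving the worst-case critical gap each time (so tightening a
#' factor that is in the model enlarges the gap and lifts every
#' non-significant parameter's power, while tightening a non-significant
#' factor steepens only its own critical effect). The same RNG seed is
#' used for every fraction, so a shrink of 0 reproduces the baseline
#' bit-for-bit and curves are comparable across fractions.
#'
#' @inheritParams retrospective_power
#' @param target_factor Name of the factor whose NOR is tightened.
#' @param shrink_fractions Numeric vector of shrink fractions in `[0, 1)`.
#' @return An object of class `nor_scan`: `summary` data frame (one row
#'   per fraction, one power column per non-significant parameter) and the
#'   full `results` list of `retro_power` objects.
#' @export
nor_scan <- function(design, response, factors = NULL, cqa, model,
                     config = retro_config(), target_factor,
                     shrink_fractions = c(0, 0.25, 0.5)) {
  if (is.null(factors)) factors <- design_factors(design)
  factors <- as_dsd_factors(factors)
  if (!target_factor %in% factors$name)
    stop("unknown target factor: ", target_factor)
  if (any(shrink_fractions < 0 | shrink_fractions >= 1))
    stop("shrink fractions must lie in [0, 1)")
  results <- lapply(shrink_fractions, function(f) {
    retrospective_power(design, response,
                        shrink_nor(factors, target_factor, f),
                        cqa, model, config)
  })
  powers <- do.call(rbind, lapply(results, function(r)
    as.data.frame(as.list(r$per_parameter_power), check.names = FALSE)))
  summary <- cbind(data.frame(shrink_fraction = shrink_fractions,
                              cg = vapply(results, function(r)
                                r$cg_used$value, numeric(1L))),
                   powers)
  structure(list(target_factor = target_factor, summary = summary,
                 results = results),
            class = "nor_scan")
}

#' @export
print.nor_scan <- function(x, ...) {
  cat(sprintf("NOR tightening scan of '%s':\n", x$target_factor))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.nor_scan <- function(x, ...) {
  params <- setdiff(names(x$summary), c("shrink_fraction", "cg"))
  graphics::matplot(x$summary$shrink_fraction,
                    as.matrix(x$summary[params]), type = "b", pch = 16,
                    lty = 1, xlab = "NOR shrink fraction",
                    ylab = "retrospective power", ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = params, col = seq_along(params),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
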