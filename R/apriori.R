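#' Randomized effect-weight combinations
#'
#' With several parameters, infinitely many effect combinations can jointly
#' consume the critical gap. The weight grid enumerates, for each parameter
#' i in turn, the vectors `w_i = a`, `w_j = (1 - a) / (p - 1)` for
#' `a = 1/step_count, 2/step_count, ..., 1`, giving `C = p * step_count`
#' combinations that all sum to 1. Order is parameter-major with `a`
#' ascending. For `p = 1` the grid degenerates to `step_count` copies of
#' `w = 1`, so the mean power equals the plain fixed-effect power.
#'
#' @param p Number of parameters sharing the gap (>= 1).
#' @param step_count Number of grid steps per parameter (default 100).
#' @return A `C x p` matrix of class `weight_grid` with columns `w1..wp`
#'   and attributes `param` (the indexed parameter of each row) and `a`.
#' @export
weight_grid <- function(p, step_count = 100L) {
  if (p < 1L) stop("p must be >= 1")
  if (step_count < 1L) stop("step_count must be >= 1")
  a <- seq_len(step_count) / step_count
  if (p == 1L) {
    W <- matrix(1, nrow = step_count, ncol = 1L)
    param <- rep(1L, step_count)
    aa <- rep(1, step_count)
  } else {
    W <- matrix(0, nrow = p * step_count, ncol = p)
    param <- rep(seq_len(p), each = step_count)
    aa <- rep(a, times = p)
    for (i in seq_len(p)) {
      rows <- (i - 1L) * step_count + seq_len(step_count)
      W[rows, ] <- (1 - a) / (p - 1)
      W[rows, i] <- a
    }
  }
  structure(W, param = param, a = aa, class = c("weight_grid", "matrix"))
}

#' Expected residual sum of squares from the set-point variance
#'
#' Before the experiments, the only available noise estimate is the
#' set-point response sd; the expected residual sum of squares of an
#' n-run DoE model is taken as `(n - 1) * sigma_sp^2`.
#'
#' @param n DoE run count (>= 2).
#' @param sigma_sp Set-point response standard deviation (> 0).
#' @return Expected residual sum of squares.
#' @export
expected_ss_res <- function(n, sigma_sp) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L)
    stop("n must be a single integer >= 2")
  if (!is.numeric(sigma_sp) || length(sigma_sp) != 1L || sigma_sp <= 0)
    stop("sigma_sp must be > 0")
  (n - 1) * sigma_sp^2
}

#' A priori power for one effect-weight combination
#'
#' Given the main-effect design matrix and a vector of critical effects,
#' simulates the noiseless response `y = X beta_crit`, forms its total sum
#' of squares about the mean, and converts the signal-to-noise ratio into
#' noncentral-F power for the overall regression test with `u = p`
#' numerator and `nu = n - p - 1` denominator degrees of freedom:
#' `f2 = R2 / (1 - R2)`, `lambda = f2 * nu`,
#' `power = 1 - F_nc(F_crit | u, nu, lambda)` with
#' `F_crit = F^{-1}(1 - alpha | u, nu)`.
#'
#' Two conventions for `R2` are offered. The default, `"noiseless"`, is
#' `R2 = 1 - ss_res / SStot` with `SStot` the noiseless signal sum of
#' squares; when the expected noise exceeds the critical signal this goes
#' negative and `lambda` is clamped to 0 (power = alpha), with the result
#' flagged. The `"conventional"` alternative uses
#' `R2 = SStot / (SStot + ss_res)`, i.e. signal over signal-plus-noise,
#' which is never negative and corresponds exactly to the noncentral-F
#' distribution of the overall F statistic at noise variance
#' `ss_res / nu`. The noiseless convention is the more conservative of the
#' two (its lambda is smaller by exactly nu whenever positive).
#'
#' A confidence interval accounts for the uncertainty of the noncentrality:
#' `lambda_upp = lambda * chi2^{-1}(1 - ci_alpha | nu) / nu` and
#' `lambda_low = lambda * chi2^{-1}(ci_alpha | nu) / nu`, each converted to
#' power.
#'
#' @param X Main-effect design matrix (`n x p`, coded units).
#' @param beta_crit Critical-effect vector of length `p`.
#' @param ss_res Expected residual sum of squares, see [expected_ss_res()].
#' @param alpha Significance level of the F test (default 0.05).
#' @param r2 `"noiseless"` (default) or `"conventional"`, see Details.
#' @param ci_alpha Percentile level for the lambda confidence interval;
#'   defaults to `alpha`.
#' @return A list with `power`, `ci` (lower, upper), `lambda`, `r_squared`
#'   and `flagged` (`TRUE` when noise exceeded the critical signal and
#'   lambda was clamped).
#' @export
apriori_power_combination <- function(X, beta_crit, ss_res, alpha = 0.05,
                                      r2 = c("noiseless", "conventional"),
                                      ci_alpha = alpha) {
  r2 <- match.arg(r2)
  X <- as.matrix(X)
  n <- nrow(X); u <- ncol(X)
  if (length(beta_crit) != u)
    stop("beta_crit has length ", length(beta_crit), "; expected ", u)
  nu <- n - u - 1L
  if (nu < 1L)
    stop("no denominator degrees of freedom: need n > p + 1")
  if (ss_res < 0) stop("ss_res must be >= 0")
  ytilde <- drop(X %*% beta_crit)
  ss_tot <- sum((ytilde - mean(ytilde))^2)
  flagged <- FALSE
  if (ss_tot <= 0) {
    if (any(beta_crit != 0))
      stop("degenerate design: nonzero critical effects produced a ",
           "constant simulated response")
    lambda <- 0
    r_squared <- 0
    flagged <- TRUE
  } else if (ss_res == 0) {
    lambda <- Inf
    r_squared <- 1
  } else {
    r_squared <- switch(r2,
                        noiseless = 1 - ss_res / ss_tot,
                        conventional = ss_tot / (ss_tot + ss_res))
    f2 <- switch(r2,
                 noiseless = (ss_tot - ss_res) / ss_res,
                 conventional = ss_tot / ss_res)
    lambda <- f2 * nu
    if (lambda < 0) { # noise exceeds critical signal
      lambda <- 0
      flagged <- TRUE
    }
  }
  f_crit <- stats::qf(1 - alpha, u, nu)
  pow <- function(l) {
    if (is.infinite(l)) 1 else 1 - stats::pf(f_crit, u, nu, ncp = l)
  }
  l_upp <- lambda * stats::qchisq(1 - ci_alpha, nu) / nu
  l_low <- lambda * stats::qchisq(ci_alpha, nu) / nu
  list(power = pow(lambda), ci = c(lower = pow(l_low), upper = pow(l_upp)),
       lambda = lambda, r_squared = r_squared, flagged = flagged)
}

#' A priori power of a design to detect critical effects
#'
#' Iterates the effect-weight grid: for every combination, critical effects
#' are derived from the set-point critical gap and each factor's NOR via
#' the critical-effect formula, converted to noncentral-F power of the
#' overall regression test, and averaged arithmetically. This is the
#' pre-experiment probability that the design detects *some* combination
#' of effects jointly large enough to push the response across the
#' threshold within the NOR, under the planning assumption that the DoE
#' residual noise equals the set-point noise.
#'
#' @param design A `dsd_design` (main-effect columns are used).
#' @param cg A `critical_gap` with basis `set_point` (or a positive
#'   number).
#' @param factors A `dsd_factors`; defaults to the design's own.
#' @param sigma_sp Set-point response sd.
#' @param alpha Significance level (default 0.05).
#' @param step_count Weight-grid steps per parameter (default 100).
#' @param r2,ci_alpha Passed to [apriori_power_combination()].
#' @param direction `"upper"` or `"lower"` criticality direction.
#' @return An object of class `apriori_power`: `mean_power`,
#'   `per_combination` data frame (indexed parameter, weight `a`, power,
#'   CI, flag), and an echo of the inputs.
#' @export
apriori_power <- function(design, cg, factors = NULL, sigma_sp,
                          alpha = 0.05, step_count = 100L,
                          r2 = c("noiseless", "conventional"),
                          ci_alpha = alpha,
                          direction = c("upper", "lower")) {
  r2 <- match.arg(r2)
  direction <- match.arg(direction)
  if (is.null(factors)) factors <- design_factors(design)
  factors <- as_dsd_factors(factors)
  X <- as.matrix(design)[, factors$name, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  ss_res <- expected_ss_res(n, sigma_sp)
  W <- weight_grid(p, step_count)
  res <- vector("list", nrow(W))
  for (c_idx in seq_len(nrow(W))) {
    bc <- beta_crit_vector(W[c_idx, ], cg, factors, direction)
    res[[c_idx]] <- apriori_power_combination(X, bc, ss_res, alpha,
                                              r2 = r2, ci_alpha = ci_alpha)
  }
  per <- data.frame(
    combination = seq_len(nrow(W)),
    parameter = factors$name[attr(W, "param")],
    a = attr(W, "a"),
    power = vapply(res, `[[`, numeric(1L), "power"),
    ci_lower = vapply(res, function(r) r$ci[["lower"]], numeric(1L)),
    ci_upper = vapply(res, function(r) r$ci[["upper"]], numeric(1L)),
    lambda = vapply(res, `[[`, numeric(1L), "lambda"),
    flagged = vapply(res, `[[`, logical(1L), "flagged"))
  structure(list(mean_power = mean(per$power),
                 per_combination = per,
                 inputs = list(n = n, p = p, alpha = alpha,
                               sigma_sp = sigma_sp, cg = cg_value(cg),
                               step_count = step_count, r2 = r2,
                               direction = direction)),
            class = "apriori_power")
}

#' @export
print.apriori_power <- function(x, ...) {
  with(x$inputs, cat(sprintf(
    "A priori power: %.4f (n = %d, p = %d, alpha = %.3g, sigma_SP = %.4g, CG = %.4g)\n",
    x$mean_power, n, p, alpha, sigma_sp, cg)))
  if (any(x$per_combination$flagged))
    cat(sprintf("  %d/%d combinations flagged: expected noise exceeds critical signal\n",
                sum(x$per_combination$flagged), nrow(x$per_combination)))
  invisible(x)
}
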