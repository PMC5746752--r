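#' Define DoE factor specifications
#'
#' A factor specification records, for every process parameter studied in a
#' screening design, its name, whether it is numeric or a two-level
#' categorical, its set point, and its normal operating range (NOR). All
#' values are in coded units: the screening range of the design is mapped to
#' \[-1, +1\], and the NOR is expressed on the same scale (it may exceed the
#' screening range, e.g. a NOR of \[-1.1, 1.1\]).
#'
#' @param name Character vector of factor names (unique, non-empty).
#' @param kind `"numeric"` or `"categorical2"`, recycled. Two-level
#'   categorical factors are coded -1/+1 and treated numerically downstream;
#'   quadratic terms are never built for them.
#' @param set_point Coded set point, recycled; must lie inside the NOR.
#'   Defaults to 0 (the design center).
#' @param nor_low,nor_high Coded NOR bounds, recycled.
#' @return A data frame of class `dsd_factors` with one row per factor and
#'   columns `name`, `kind`, `set_point`, `nor_low`, `nor_high`.
#' @examples
#' factor_specs(c("pH", "load"), nor_low = c(-0.55, -0.51), nor_high = c(0.55, 1.1))
#' @export
factor_specs <- function(name, kind = "numeric", set_point = 0,
                         nor_low = -1, nor_high = 1) {
  name <- as.character(name)
  if (length(name) == 0L || anyNA(name) || any(!nzchar(name)))
    stop("factor names must be non-empty character strings")
  if (anyDuplicated(name))
    stop("factor names must be unique")
  p <- length(name)
  kind <- rep_len(match.arg(kind, c("numeric", "categorical2"), several.ok = TRUE),
                  p)
  set_point <- rep_len(as.numeric(set_point), p)
  nor_low <- rep_len(as.numeric(nor_low), p)
  nor_high <- rep_len(as.numeric(nor_high), p)
  if (any(!is.finite(c(set_point, nor_low, nor_high))))
    stop("set_point and NOR bounds must be finite")
  if (any(nor_low >= nor_high))
    stop("nor_low must be strictly below nor_high for every factor")
  if (any(set_point < nor_low | set_point > nor_high))
    stop("set_point must lie inside [nor_low, nor_high]")
  out <- data.frame(name = name, kind = kind, set_point = set_point,
                    nor_low = nor_low, nor_high = nor_high,
                    stringsAsFactors = FALSE)
  class(out) <- c("dsd_factors", "data.frame")
  out
}

#' @rdname factor_specs
#' @param m Number of factors for a default specification (`X1` ... `Xm`,
#'   numeric, set point 0, NOR \[-1, 1\]).
#' @export
default_factors <- function(m) {
  factor_specs(paste0("X", seq_len(m)))
}

as_dsd_factors <- function(x) {
  if (inherits(x, "dsd_factors")) return(x)
  if (is.data.frame(x)) {
    req <- c("name", "set_point", "nor_low", "nor_high")
    if (!all(req %in% names(x)))
      stop("factor data frame needs columns: ", paste(req, collapse = ", "))
    return(factor_specs(x$name,
                        kind = if ("kind" %in% names(x)) x$kind else "numeric",
                        set_point = x$set_point,
                        nor_low = x$nor_low, nor_high = x$nor_high))
  }
  stop("cannot interpret object of class '", class(x)[1L], "' as factor specs")
}

#' Shrink a factor's NOR symmetrically about its set point
#'
#' Both NOR half-widths (set point to lower bound, set point to upper bound)
#' are multiplied by `1 - fraction`, so a fraction of 0.5 halves the range
#' about the set point. Used by [nor_scan()] to study tightened control
#' strategies.
#'
#' @param factors A `dsd_factors` object.
#' @param name Name of the factor to shrink.
#' @param fraction Shrink fraction in `[0, 1)`.
#' @return The modified `dsd_factors` object.
#' @export
shrink_nor <- function(factors, name, fraction) {
  factors <- as_dsd_factors(factors)
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction < 0 || fraction >= 1)
    stop("shrink fraction must be a single number in [0, 1)")
  i <- match(name, factors$name)
  if (is.na(i)) stop("unknown factor: ", name)
  sp <- factors$set_point[i]
  factors$nor_low[i] <- sp - (sp - factors$nor_low[i]) * (1 - fraction)
  factors$nor_high[i] <- sp + (factors$nor_high[i] - sp) * (1 - fraction)
  factors
}

#' Replicate responses measured at set-point conditions
#'
#' Summarises set-point replicate runs into the mean and standard deviation
#' used by the a priori power analysis (the expected noise level of the DoE)
#' and by the residual-to-set-point variance ratio diagnostic.
#'
#' @param values Numeric vector of at least 2 replicate responses.
#' @return An object of class `sp_sample` with elements `values`, `mean`
#'   and `sd`.
#' @export
set_point_sample <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("at least 2 set-point replicates are required to estimate sigma_SP")
  if (any(!is.finite(values)))
    stop("set-point replicates must be finite")
  s <- stats::sd(values)
  if (s <= 0)
    stop("set-point replicates are constant; sigma_SP must be > 0")
  structure(list(values = values, mean = mean(values), sd = s),
            class = "sp_sample")
}

#' @export
print.sp_sample <- function(x, ...) {
  cat(sprintf("Set-point sample: %d replicates, mean %.4g, sd %.4g\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}
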