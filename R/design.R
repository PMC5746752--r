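# Conference matrices (zero diagonal, +/-1 off-diagonal, C'C = (q-1) I) used
# for the fold-over construction of definitive screening designs.
# Order 4: skew-symmetric; orders 6 and 8: Paley construction over GF(5), GF(7).
conference_matrix <- function(order) {
  if (order == 4L) {
    return(matrix(c(0,  1,  1,  1,
                    -1, 0,  1, -1,
                    -1, -1, 0,  1,
                    -1, 1, -1,  0), nrow = 4, byrow = TRUE))
  }
  if (order %in% c(6L, 8L)) {
    q <- order - 1L
    residues <- unique((seq_len(q - 1L)^2) %% q)
    chi <- function(a) {
      a <- a %% q
      ifelse(a == 0, 0, ifelse(a %in% residues, 1, -1))
    }
    jac <- outer(0:(q - 1L), 0:(q - 1L), function(i, j) chi(j - i))
    if (q %% 4L == 1L) { # symmetric (q = 5)
      C <- rbind(c(0, rep(1, q)), cbind(rep(1, q), jac))
    } else {             # skew (q = 7)
      C <- rbind(c(0, rep(1, q)), cbind(rep(-1, q), jac))
    }
    return(C)
  }
  stop("no conference matrix available for order ", order)
}

#' Generate a definitive screening design
#'
#' Builds a three-level definitive screening design (DSD) for `m` numeric
#' factors by the conference-matrix fold-over construction: the runs are the
#' rows of a conference matrix `C`, their mirror images `-C`, and a single
#' all-zero center run. Main-effect columns are mutually orthogonal and
#' orthogonal to quadratic effects. For odd `m` the design for `m + 1`
#' factors is built and the last column dropped, so the run count is
#' `2m + 1` for even `m` and `2m + 3` for odd `m` (e.g. 13 runs for 5
#' factors).
#'
#' @param m Number of numeric factors, between 4 and 8.
#' @param factors Optional `dsd_factors` with `m` rows supplying names, set
#'   points and NORs; defaults to [default_factors()]. All factors must be
#'   numeric (a DSD has three levels).
#' @return An `n x m` numeric matrix of coded levels in \{-1, 0, +1\} of
#'   class `dsd_design`, with the factor specification attached as
#'   attribute `"factors"`.
#' @examples
#' d <- generate_dsd(5)
#' nrow(d)  # 13
#' crossprod(unclass(d))  # diagonal: orthogonal main effects
#' @export
generate_dsd <- function(m, factors = NULL) {
  if (!is.numeric(m) || length(m) != 1L || m != round(m))
    stop("m must be a single integer")
  m <- as.integer(m)
  if (m < 4L || m > 8L)
    stop("unsupported number of factors: ", m,
         " (supported range is 4 to 8)")
  if (is.null(factors)) factors <- default_factors(m)
  factors <- as_dsd_factors(factors)
  if (nrow(factors) != m)
    stop("factor specification has ", nrow(factors), " rows; expected ", m)
  if (any(factors$kind != "numeric"))
    stop("definitive screening designs require numeric factors; ",
         "categorical factors cannot take the mid level 0")
  order <- if (m %% 2L == 0L) m else m + 1L
  C <- conference_matrix(order)
  D <- rbind(C, -C, rep(0, order))[, seq_len(m), drop = FALSE]
  dimnames(D) <- list(paste0("run", seq_len(nrow(D))), factors$name)
  new_dsd_design(D, factors)
}

new_dsd_design <- function(values, factors) {
  structure(values, factors = factors, class = c("dsd_design", "matrix"))
}

#' Assemble a design matrix from coded run settings
#'
#' Wraps an `n x p` matrix (or data frame) of coded factor levels into a
#' `dsd_design`, validating it against a factor specification: columns are
#' aligned to `factors$name` by name when column names are present, numeric
#' factor levels must lie in \[-1, +1\], and two-level categorical factors
#' must be coded -1/+1.
#'
#' @param values Matrix or data frame of coded levels.
#' @param factors A `dsd_factors` specification.
#' @return A `dsd_design` matrix.
#' @export
design_matrix <- function(values, factors) {
  factors <- as_dsd_factors(factors)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("design values must be numeric")
  storage.mode(values) <- "double"
  if (!is.null(colnames(values))) {
    missing <- setdiff(factors$name, colnames(values))
    if (length(missing))
      stop("design is missing factor column(s): ",
           paste(missing, collapse = ", "))
    values <- values[, factors$name, drop = FALSE]
  } else {
    if (ncol(values) != nrow(factors))
      stop("design has ", ncol(values), " columns but ", nrow(factors),
           " factors were specified")
    colnames(values) <- factors$name
  }
  if (any(!is.finite(values)))
    stop("design contains non-finite values")
  num <- factors$kind == "numeric"
  if (any(values[, num, drop = FALSE] < -1 - 1e-8) ||
      any(values[, num, drop = FALSE] > 1 + 1e-8))
    stop("numeric factor levels must lie in [-1, +1] coded units")
  cat2 <- values[, !num, drop = FALSE]
  if (length(cat2) && !all(cat2 %in% c(-1, 1)))
    stop("categorical2 factors take coded levels -1/+1 only")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("run", seq_len(nrow(values)))
  new_dsd_design(values, factors)
}

#' @export
print.dsd_design <- function(x, ...) {
  f <- attr(x, "factors")
  cat(sprintf("Coded design: %d runs x %d factors\n", nrow(x), ncol(x)))
  print(unclass(structure(x, factors = NULL)), ...)
  invisible(x)
}

#' Retrieve the factor specification attached to a design
#'
#' @param design A `dsd_design`.
#' @return The `dsd_factors` the design was built with.
#' @export
design_factors <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("design carries no factor specification")
  f
}

# subscripting a dsd_design drops to a plain matrix on purpose; the class is
# only meaningful with its full factor set attached
#' @export
`[.dsd_design` <- function(x, i, j, ...) {
  unclass(structure(x, factors = NULL))[i, j, ...]
}
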