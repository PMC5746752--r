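# CSV dialect: comma-separated, header row, period decimal separator, UTF-8.
# Design file: one column per factor. Response file: run_id + one column per
# CQA. Factor / CQA metadata travel as JSON (see read_factors_json).

#' Read and write coded design matrices
#'
#' `read_design()` loads a CSV of coded run settings and validates it
#' against a factor specification; columns are matched by name, so column
#' order in the file is irrelevant. `write_design()` writes the design back
#' in the same dialect; a write/read round trip reproduces the design
#' exactly.
#'
#' @param path Path to a CSV file.
#' @param factors A `dsd_factors` specification (see [factor_specs()]).
#' @return `read_design()` returns a `dsd_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
read_design <- function(path, factors) {
  factors <- as_dsd_factors(factors)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(factors$name, names(df))
  if (length(missing))
    stop("design file '", path, "' is missing factor column(s): ",
         paste(missing, collapse = ", "))
  vals <- df[, factors$name, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1L))
  if (any(bad))
    stop("non-numeric values in design column(s): ",
         paste(names(vals)[bad], collapse = ", "))
  design_matrix(as.matrix(vals), factors)
}

#' @rdname read_design
#' @param design A `dsd_design` to write.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(unclass(structure(design, factors = NULL))),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write DoE response vectors
#'
#' A response file has a `run_id` column plus one column per CQA, in run
#' order matching the design. `read_response()` extracts one CQA column as
#' a named numeric vector; when a design is supplied the run count is
#' checked against it.
#'
#' @param path Path to a CSV file with columns `run_id` and `<cqa_name>`.
#' @param cqa_name Name of the response column to read; defaults to the
#'   single non-`run_id` column.
#' @param design Optional `dsd_design` used to check the run count.
#' @return `read_response()` returns a numeric vector with attribute
#'   `cqa_name`; `write_response()` returns `path` invisibly.
#' @export
read_response <- function(path, cqa_name = NULL, design = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"run_id" %in% names(df))
    stop("response file '", path, "' has no 'run_id' column")
  cqas <- setdiff(names(df), "run_id")
  if (is.null(cqa_name)) {
    if (length(cqas) != 1L)
      stop("response file has ", length(cqas),
           " CQA columns; supply cqa_name to pick one")
    cqa_name <- cqas
  }
  if (!cqa_name %in% cqas)
    stop("response file '", path, "' has no column '", cqa_name, "'")
  y <- df[[cqa_name]]
  if (!is.numeric(y))
    stop("response column '", cqa_name, "' is not numeric")
  if (any(!is.finite(y)))
    stop("response column '", cqa_name, "' contains non-finite values")
  if (!is.null(design) && length(y) != nrow(design))
    stop("response has ", length(y), " rows but the design has ",
         nrow(design), " runs")
  structure(as.numeric(y), cqa_name = cqa_name)
}

#' @rdname read_response
#' @param y Numeric response vector.
#' @export
write_response <- function(y, path, cqa_name = NULL) {
  if (is.null(cqa_name)) cqa_name <- attr(y, "cqa_name")
  if (is.null(cqa_name)) stop("cqa_name is required")
  df <- data.frame(run_id = seq_along(y), y = as.numeric(y))
  names(df)[2L] <- cqa_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read factor and CQA metadata from JSON
#'
#' Factor metadata schema: an array of objects
#' `{"name", "kind", "set_point", "nor_low", "nor_high"}` (kind optional,
#' default `"numeric"`). CQA metadata schema: an array of objects
#' `{"name", "usl_ds" | "threshold_direct", "clearances": [..],
#' "direction"}`; exactly one of `usl_ds` / `threshold_direct` per CQA
#' (see [cqa_spec()]).
#'
#' @param path Path to a JSON file.
#' @return `read_factors_json()` returns a `dsd_factors`;
#'   `read_cqa_json()` returns a named list of `cqa_spec` objects.
#' @export
read_factors_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_dsd_factors(as.data.frame(x, stringsAsFactors = FALSE))
}

#' @rdname read_factors_json
#' @export
read_cqa_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(x, function(el) {
    cqa_spec(name = el$name,
             usl_ds = el$usl_ds,
             threshold_direct = el$threshold_direct,
             clearances = if (!is.null(el$clearances))
               as.numeric(unlist(el$clearances)),
             direction = if (is.null(el$direction)) "upper" else el$direction)
  })
  names(specs) <- vapply(specs, function(s) s$name, character(1L))
  specs
}
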