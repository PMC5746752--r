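#' Run the full criticality-assessment workflow
#'
#' Orchestrates, per CQA: threshold derivation, a priori power, stepwise
#' model selection, retrospective power of the non-significant parameters,
#' and a criticality call for every process parameter:
#'
#' * `critical_significant` — the parameter is involved in the selected
#'   model;
#' * `non_critical_powered` — not selected, and its retrospective power
#'   reaches the cutoff (default 0.8): the chance its critical effect was
#'   overlooked is at most 1 - cutoff;
#' * `non_critical_after_mitigation` — reaches the cutoff only after a
#'   user-supplied mitigation (e.g. a NOR tightening) was applied;
#' * `potentially_overlooked` — power below the cutoff; the report
#'   enumerates the mitigation options (re-measure samples, re-run
#'   experiments, tighten the NOR) but never applies one on its own.
#'
#' @param design A `dsd_design` (or CSV path, resolved with `factors`).
#' @param responses Named list of response vectors (or CSV paths), one per
#'   CQA.
#' @param factors A `dsd_factors` (or JSON path).
#' @param cqas Named list of `cqa_spec` objects (or JSON path), names
#'   matching `responses`.
#' @param sp_samples Named list of [set_point_sample()]s (or numeric
#'   replicate vectors), one per CQA.
#' @param config A `retro_config`; its `alpha` is also used for model
#'   selection entry (exit is `2 * alpha`) and the a priori power.
#' @param power_cutoff Minimum retrospective power to call a parameter
#'   non-critical (default 0.8; 0.9 for a stricter residual risk).
#' @param apriori_step_count Weight-grid steps for the a priori stage.
#' @param mitigations Optional named list (per CQA) of named lists (per
#'   parameter) `list(type = "nor_tightening", fraction = ...)` recording
#'   user-chosen mitigations to apply before the retrospective stage.
#' @param include_interactions Passed to [build_candidates()].
#' @return An object of class `criticality_report`: per-CQA results
#'   (threshold, a priori power, fit, retrospective power, calls data
#'   frame) plus the configuration echo.
#' @export
run_workflow <- function(design, responses, factors, cqas, sp_samples,
                         config = retro_config(), power_cutoff = 0.8,
                         apriori_step_count = 100L, mitigations = NULL,
                         include_interactions = FALSE) {
  if (is.character(factors)) factors <- read_factors_json(factors)
  factors <- as_dsd_factors(factors)
  if (is.character(design)) design <- read_design(design, factors)
  if (is.character(cqas)) cqas <- read_cqa_json(cqas)
  if (!all(names(responses) %in% names(cqas)))
    stop("every response needs a matching cqa_spec: missing ",
         paste(setdiff(names(responses), names(cqas)), collapse = ", "))
  if (!all(names(responses) %in% names(sp_samples)))
    stop("every response needs a set-point sample")
  candidates <- build_candidates(factors,
                                 include_interactions = include_interactions)
  per_cqa <- lapply(names(responses), function(cq) {
    y <- responses[[cq]]
    if (is.character(y)) y <- read_response(y, cq, design)
    sp <- sp_samples[[cq]]
    if (!inherits(sp, "sp_sample")) sp <- set_point_sample(sp)
    cqa <- cqas[[cq]]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("CQA '", cq, "', stage '", what, "': ", conditionMessage(e),
             call. = FALSE))
    }
    cg_sp <- stage("critical gap (set point)",
                   critical_gap_setpoint(cqa, sp$mean))
    ap <- stage("a priori power",
                apriori_power(design, cg_sp, factors, sigma_sp = sp$sd,
                              alpha = config$alpha,
                              step_count = apriori_step_count,
                              direction = cqa$direction))
    fit <- stage("stepwise selection",
                 stepwise_select(design, y, candidates,
                                 p_enter = config$alpha,
                                 p_exit = 2 * config$alpha))
    facs_cq <- factors
    mit <- if (!is.null(mitigations)) mitigations[[cq]]
    mitigated <- character(0)
    if (!is.null(mit)) {
      for (pn in names(mit)) {
        m <- mit[[pn]]
        if (!identical(m$type, "nor_tightening"))
          stop("unsupported mitigation type '", m$type, "' for '", pn, "'")
        facs_cq <- shrink_nor(facs_cq, pn, m$fraction)
        mitigated <- c(mitigated, pn)
      }
    }
    rp <- stage("retrospective power",
                retrospective_power(design, y, facs_cq, cqa, fit, config))
    calls <- lapply(factors$name, function(pn) {
      if (pn %in% rp$significant_factors ||
          pn %in% unlist(lapply(fit$terms, `[[`, "factors"))) {
        pv <- fit$p_values[vapply(fit$terms, function(tm)
          pn %in% tm$factors, logical(1L))]
        data.frame(parameter = pn, status = "critical_significant",
                   p_value = min(pv), power = NA_real_,
                   mitigation = "none")
      } else {
        pw <- rp$per_parameter_power[[pn]]
        if (pw >= power_cutoff) {
          data.frame(parameter = pn,
                     status = if (pn %in% mitigated)
                       "non_critical_after_mitigation"
                     else "non_critical_powered",
                     p_value = NA_real_, power = pw,
                     mitigation = if (pn %in% mitigated)
                       sprintf("nor_tightening %.2f",
                               mit[[pn]]$fraction) else "none")
        } else {
          data.frame(parameter = pn, status = "potentially_overlooked",
                     p_value = NA_real_, power = pw,
                     mitigation = paste("options: re-measure samples;",
                                        "re-run experiments;",
                                        "tighten NOR"))
        }
      }
    })
    list(cqa = cq, threshold = cqa$threshold, cg_setpoint = cg_sp,
         apriori = ap, fit = fit,
         sigma_ratio = residual_sd_ratio(fit, sp),
         retro = rp, calls = do.call(rbind, calls))
  })
  names(per_cqa) <- names(responses)
  structure(list(per_cqa = per_cqa, power_cutoff = power_cutoff,
                 config = config, factors = factors),
            class = "criticality_report")
}

#' @export
print.criticality_report <- function(x, ...) {
  cat("Criticality assessment report\n")
  cat(sprintf("  power cutoff: %.2f, alpha: %.3g\n", x$power_cutoff,
              x$config$alpha))
  for (cq in names(x$per_cqa)) {
    r <- x$per_cqa[[cq]]
    cat(sprintf("\nCQA '%s' (threshold %.5g):\n", cq, r$threshold))
    cat(sprintf("  a priori mean power: %.4f | sigma_resid/sigma_SP: %.3g\n",
                r$apriori$mean_power, r$sigma_ratio))
    print(r$calls, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Serialize a criticality report (or other results) to JSON
#'
#' @param report A `criticality_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "criticality_report"))
  out <- list(
    power_cutoff = report$power_cutoff,
    alpha = report$config$alpha,
    seed = report$config$rng_seed,
    cqas = lapply(report$per_cqa, function(r) {
      list(threshold = r$threshold,
           cg_setpoint = r$cg_setpoint$value,
           cg_worstcase = if (!is.null(r$retro$cg_used))
             r$retro$cg_used$value,
           apriori_mean_power = r$apriori$mean_power,
           sigma_ratio = r$sigma_ratio,
           model = list(intercept = r$fit$intercept,
                        terms = as.list(r$fit$coefficients),
                        p_values = as.list(r$fit$p_values),
                        sigma_residues = r$fit$sigma_residues),
           retro_power = as.list(r$retro$per_parameter_power),
           calls = r$calls)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
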