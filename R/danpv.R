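#' Fit the full DANP-V evaluation pipeline
#'
#' The central fitter of the package. Chains the three analysis stages on a
#' set of questionnaire panels:
#' \enumerate{
#'   \item DEMATEL: aggregate the expert direct-influence panel, normalize,
#'     compute the criteria- and dimension-level total-influence matrices and
#'     causal profiles, and build the influential network relation map.
#'   \item DANP: derive global / local / dimension influential weights from
#'     the limit of the weighted supermatrix.
#'   \item modified VIKOR: per-criterion mean satisfaction of the resident
#'     and expert panels, aspiration gaps, weighted dimension and total
#'     aggregates, and size-weighted dual-panel integration.
#' }
#'
#' @param dematel_panel list of expert direct-influence matrices (0-4 scale,
#'   zero diagonal), in framework criterion order.
#' @param resident_survey,expert_survey satisfaction surveys: data.frames
#'   with columns `respondent_id`, `criterion_code`, `rating`.
#' @param framework a `criteria_framework` (default [case_framework()]).
#' @param aspiration,worst gap-scale anchors (defaults 10 and 0).
#' @param max_missing per-respondent tolerated missing-item fraction before
#'   the questionnaire is dropped whole (default 0).
#' @param inrm_threshold_D,inrm_threshold_C INRM edge thresholds; `NULL`
#'   (default) uses the off-diagonal mean rule.
#' @return object of class `danpv`: list with `framework`, `dematel`
#'   (a [dematel()] object), `inrm`, `weights` (a `weight_set`), `report`
#'   (a `vikor_report`), panel bookkeeping and the matched call.
#' @export
#' @examples
#' fw <- case_framework()
#' panel <- gen_dematel_panel(fw, k = 9, seed = 7)
#' res <- gen_satisfaction_survey(fw, 60, seed = 8)
#' exp <- gen_satisfaction_survey(fw, 10, seed = 9, panel_label = "expert")
#' fit <- danpv(panel, res, exp, fw)
#' coef(fit)
danpv <- function(dematel_panel, resident_survey, expert_survey,
                  framework = case_framework(), aspiration = 10, worst = 0,
                  max_missing = 0, inrm_threshold_D = NULL,
                  inrm_threshold_C = NULL) {
  dm <- dematel(dematel_panel, framework)
  inrm <- build_inrm(dm, inrm_threshold_D, inrm_threshold_C)
  weights <- danp_weights(dm, framework)

  vres <- validate_survey_panel(resident_survey, framework, max_missing)
  vexp <- validate_survey_panel(expert_survey, framework, max_missing)
  n_res <- length(unique(vres$valid$respondent_id))
  n_exp <- length(unique(vexp$valid$respondent_id))
  resident_means <- mean_performance(vres$valid, framework)
  expert_means <- mean_performance(vexp$valid, framework)

  report <- vikor_report(weights, resident_means, expert_means,
                         n_res, n_exp, framework,
                         aspiration = aspiration, worst = worst)
  structure(list(framework = framework, dematel = dm, inrm = inrm,
                 weights = weights, report = report,
                 n_resident = n_res, n_expert = n_exp,
                 rejected_residents = vres$rejected,
                 rejected_experts = vexp$rejected,
                 call = match.call()),
            class = "danpv")
}

#' @export
print.danpv <- function(x, ...) {
  cat("DANP-V evaluation\n")
  cat(sprintf("  framework: %d dimensions, %d criteria\n",
              nrow(x$framework$dimensions), n_criteria(x$framework)))
  cat(sprintf("  panels: %d residents, %d experts\n", x$n_resident, x$n_expert))
  cat(sprintf("  integrated total performance %.3f (gap %.3f)\n",
              x$report$total$perf_integrated, x$report$total$gap_integrated))
  cat("  dimension influence priority:",
      paste(dimension_priority(x$dematel$profile_D), collapse = " > "), "\n")
  invisible(x)
}

#' @export
summary.danpv <- function(object, ...) {
  structure(list(fit = object), class = "summary.danpv")
}

#' @export
print.summary.danpv <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\n")
  print(fit$report)
  cat("\nImprovement priority (largest integrated gap first):\n  ")
  cat(paste(utils::head(priority_ranking(fit$report), 5), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Extract influential weights from a fitted pipeline
#'
#' @param object a `danpv` fit.
#' @param type `"global"` (the influential weights, default), `"local"` or
#'   `"dimension"`.
#' @param ... unused.
#' @return named numeric weight vector.
#' @export
coef.danpv <- function(object, type = c("global", "local", "dimension"), ...) {
  type <- match.arg(type)
  object$weights[[type]]
}

#' Plot the INRM of a fitted pipeline
#'
#' @param x a `danpv` fit.
#' @param level `"dimension"` or `"criteria"`.
#' @param ... passed on to [plot.inrm()].
#' @return `x`, invisibly.
#' @export
plot.danpv <- function(x, level = c("dimension", "criteria"), ...) {
  plot(x$inrm, level = level, ...)
  invisible(x)
}
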