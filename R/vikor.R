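#' Per-criterion mean satisfaction of a survey panel
#'
#' @param survey data.frame with columns `respondent_id`, `criterion_code`,
#'   `rating` (1-10 scale). Missing ratings (NA rows) are ignored item-wise;
#'   respondent-level validity is handled upstream (see
#'   [validate_survey_panel()]).
#' @param framework a `criteria_framework`.
#' @return named numeric vector of means, in framework criterion order.
#' @export
mean_performance <- function(survey, framework) {
  codes <- framework$criteria$code
  out <- vapply(codes, function(code) {
    r <- survey$rating[survey$criterion_code == code]
    r <- r[!is.na(r)]
    if (length(r) == 0) {
      stop(errorCondition(sprintf("criterion %s has no ratings", code),
                          class = c("danpv_empty_panel", "danpv_error")))
    }
    mean(r)
  }, numeric(1))
  names(out) <- codes
  out
}

#' Drop invalid satisfaction questionnaires
#'
#' A respondent is dropped whole when their fraction of missing items (either
#' absent rows or NA ratings) exceeds `max_missing`. The default 0 drops any
#' respondent with at least one missing item.
#'
#' @param survey data.frame as in [mean_performance()].
#' @param framework a `criteria_framework`.
#' @param max_missing maximum tolerated missing fraction per respondent.
#' @return list with `valid` (surviving rows) and `rejected` respondent ids.
#' @export
validate_survey_panel <- function(survey, framework, max_missing = 0) {
  codes <- framework$criteria$code
  ids <- unique(survey$respondent_id)
  frac <- vapply(ids, function(id) {
    r <- survey[survey$respondent_id == id & survey$criterion_code %in% codes, ]
    n_ok <- sum(!is.na(r$rating[match(codes, r$criterion_code)]))
    1 - n_ok / length(codes)
  }, numeric(1))
  rejected <- ids[frac > max_missing]
  valid <- survey[!(survey$respondent_id %in% rejected), , drop = FALSE]
  list(valid = valid, rejected = rejected)
}

#' Aspiration-gap ratio
#'
#' The modified-VIKOR gap measures the normalized shortfall from the
#' aspiration level: (aspiration - performance) / (aspiration - worst).
#' It is 0 at the aspiration level and 1 at the worst level; larger gaps mark
#' more deficient criteria.
#'
#' @param performance numeric performance value(s) on the rating scale.
#' @param aspiration aspiration level (default 10).
#' @param worst worst level (default 0).
#' @return gap ratio(s) in `[0, 1]`.
#' @export
#' @examples
#' gap_ratio(8.036)  # 0.1964
gap_ratio <- function(performance, aspiration = 10, worst = 0) {
  stopifnot(aspiration > worst)
  if (any(performance < worst | performance > aspiration)) {
    stop(errorCondition("performance outside [worst, aspiration]",
                        class = c("danpv_scale_error", "danpv_error")))
  }
  (aspiration - performance) / (aspiration - worst)
}

#' Size-weighted integration of two panels
#'
#' Combines a resident-panel and an expert-panel value by their valid
#' respondent counts: (n_r p_r + n_e p_e) / (n_r + n_e). Being a convex
#' combination, the result always lies between the two panel values.
#'
#' @param p_resident,p_expert panel values (performances or gaps).
#' @param n_resident,n_expert valid respondent counts (>= 1).
#' @return the integrated value(s).
#' @export
#' @examples
#' integrate_panels(7.157, 140, 8.000, 10)  # 7.213
integrate_panels <- function(p_resident, n_resident, p_expert, n_expert) {
  stopifnot(n_resident >= 1, n_expert >= 1)
  (n_resident * p_resident + n_expert * p_expert) / (n_resident + n_expert)
}

#' Weighted dimension-level performance
#'
#' Aggregates member criterion performances with local weights (which sum to
#' 1 within each dimension).
#'
#' @param means named per-criterion performance vector.
#' @param weights a `weight_set`.
#' @param framework a `criteria_framework`.
#' @return named per-dimension performance vector.
#' @export
dimension_performance <- function(means, weights, framework) {
  means <- means[framework$criteria$code]
  dim_of <- criterion_dimension(framework)
  out <- vapply(framework$dimensions$code, function(d) {
    i <- dim_of == d
    sum(weights$local[i] * means[i])
  }, numeric(1))
  names(out) <- framework$dimensions$code
  out
}

#' Global-weighted total performance
#'
#' @param means named per-criterion performance vector.
#' @param weights a `weight_set` (global weights sum to 1).
#' @param framework a `criteria_framework`.
#' @return scalar total performance.
#' @export
total_performance <- function(means, weights, framework) {
  sum(weights$global * means[framework$criteria$code])
}

#' Normal-approximation margin of error for a proportion
#'
#' Cochran-style adequacy check for a satisfaction survey sample: margin =
#' z(confidence) * sqrt(p (1 - p) / n), with the two-sided normal quantile
#' (z = 1.960 at 95%). Maximum variability corresponds to p = 0.5.
#'
#' @param n sample size.
#' @param p assumed proportion (default 0.5, maximum variability).
#' @param confidence confidence level (default 0.95).
#' @return list with `n`, `p`, `confidence`, `z`, `margin_of_error` (as a
#'   fraction; multiply by 100 for percent).
#' @export
#' @examples
#' sample_margin_of_error(140)$margin_of_error  # 0.0828
sample_margin_of_error <- function(n, p = 0.5, confidence = 0.95) {
  stopifnot(n >= 1, p > 0, p < 1, confidence > 0, confidence < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  list(n = n, p = p, confidence = confidence, z = z,
       margin_of_error = z * sqrt(p * (1 - p) / n))
}

#' Build the dual-panel VIKOR evaluation report
#'
#' Produces the full performance/gap table of the modified-VIKOR stage: for
#' each criterion, each dimension and the total, the per-panel performance
#' and aspiration gap plus the size-weighted integrated values.
#'
#' Dimension- and total-level integration always applies the panel-size
#' formula to panel-level aggregates. By default those aggregates are
#' computed from the criterion means with local/global weights; printed
#' panel aggregates (e.g. from a published report) may be supplied instead
#' via `dim_perf_resident` / `dim_perf_expert` / `total_perf_resident` /
#' `total_perf_expert`, in which case integration runs from them exactly.
#'
#' @param weights a `weight_set`.
#' @param resident_means,expert_means named per-criterion mean vectors.
#' @param n_resident,n_expert valid panel sizes used as integration weights.
#' @param framework a `criteria_framework`.
#' @param aspiration,worst the gap-scale anchors (defaults 10 and 0).
#' @param dim_perf_resident,dim_perf_expert optional named per-dimension
#'   panel performances overriding the weighted aggregation.
#' @param total_perf_resident,total_perf_expert optional scalar panel totals.
#' @return object of class `vikor_report`: list with `criteria`, `dimensions`
#'   and `total` data.frames (full precision), plus the configuration.
#' @export
vikor_report <- function(weights, resident_means, expert_means,
                         n_resident, n_expert, framework,
                         aspiration = 10, worst = 0,
                         dim_perf_resident = NULL, dim_perf_expert = NULL,
                         total_perf_resident = NULL, total_perf_expert = NULL) {
  codes <- framework$criteria$code
  resident_means <- resident_means[codes]
  expert_means <- expert_means[codes]
  if (anyNA(resident_means) || anyNA(expert_means)) {
    stop(errorCondition("a panel is missing criterion means",
                        class = c("danpv_missing_panel", "danpv_error")))
  }
  gap <- function(p) gap_ratio(p, aspiration, worst)

  perf_int <- integrate_panels(resident_means, n_resident, expert_means, n_expert)
  criteria <- data.frame(
    code = codes, dimension = criterion_dimension(framework),
    local_weight = unname(weights$local), global_weight = unname(weights$global),
    perf_resident = unname(resident_means), gap_resident = unname(gap(resident_means)),
    perf_expert = unname(expert_means), gap_expert = unname(gap(expert_means)),
    perf_integrated = unname(perf_int), gap_integrated = unname(gap(perf_int)),
    stringsAsFactors = FALSE)

  if (is.null(dim_perf_resident))
    dim_perf_resident <- dimension_performance(resident_means, weights, framework)
  if (is.null(dim_perf_expert))
    dim_perf_expert <- dimension_performance(expert_means, weights, framework)
  dcodes <- framework$dimensions$code
  dim_perf_resident <- dim_perf_resident[dcodes]
  dim_perf_expert <- dim_perf_expert[dcodes]
  dim_int <- integrate_panels(dim_perf_resident, n_resident,
                              dim_perf_expert, n_expert)
  dimensions <- data.frame(
    code = dcodes, weight = unname(weights$dimension[dcodes]),
    perf_resident = unname(dim_perf_resident),
    gap_resident = unname(gap(dim_perf_resident)),
    perf_expert = unname(dim_perf_expert),
    gap_expert = unname(gap(dim_perf_expert)),
    perf_integrated = unname(dim_int), gap_integrated = unname(gap(dim_int)),
    stringsAsFactors = FALSE)

  if (is.null(total_perf_resident))
    total_perf_resident <- total_performance(resident_means, weights, framework)
  if (is.null(total_perf_expert))
    total_perf_expert <- total_performance(expert_means, weights, framework)
  tot_int <- integrate_panels(total_perf_resident, n_resident,
                              total_perf_expert, n_expert)
  total <- data.frame(
    perf_resident = total_perf_resident, gap_resident = gap(total_perf_resident),
    perf_expert = total_perf_expert, gap_expert = gap(total_perf_expert),
    perf_integrated = tot_int, gap_integrated = gap(tot_int))

  structure(list(criteria = criteria, dimensions = dimensions, total = total,
                 n_resident = n_resident, n_expert = n_expert,
                 aspiration = aspiration, worst = worst),
            class = "vikor_report")
}

#' Round half-up at a fixed number of decimals
#'
#' Reporting precision helper: 0.0985 rounds to 0.099 at 3 decimals. Applied
#' only at the reporting layer; all report values are stored at full
#' precision.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 3) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @export
print.vikor_report <- function(x, digits = 3, ...) {
  r <- function(v) format(round_half_up(v, digits), nsmall = digits)
  cat(sprintf("Modified-VIKOR evaluation (aspiration %g, worst %g; panels n=%d resident, n=%d expert)\n\n",
              x$aspiration, x$worst, x$n_resident, x$n_expert))
  hdr <- sprintf("%-5s %6s %6s | %7s %5s | %7s %5s | %7s %5s",
                 "", "lw", "gw", "res", "gap", "exp", "gap", "int", "gap")
  cat(hdr, "\n")
  for (d in x$dimensions$code) {
    dd <- x$dimensions[x$dimensions$code == d, ]
    cat(sprintf("%-5s %6s %6s | %7s %5s | %7s %5s | %7s %5s\n",
                d, r(dd$weight), "", r(dd$perf_resident), r(dd$gap_resident),
                r(dd$perf_expert), r(dd$gap_expert),
                r(dd$perf_integrated), r(dd$gap_integrated)))
    cc <- x$criteria[x$criteria$dimension == d, ]
    for (i in seq_len(nrow(cc))) {
      cat(sprintf("%-5s %6s %6s | %7s %5s | %7s %5s | %7s %5s\n",
                  paste0(" ", cc$code[i]), r(cc$local_weight[i]),
                  r(cc$global_weight[i]),
                  r(cc$perf_resident[i]), r(cc$gap_resident[i]),
                  r(cc$perf_expert[i]), r(cc$gap_expert[i]),
                  r(cc$perf_integrated[i]), r(cc$gap_integrated[i])))
    }
  }
  cat(sprintf("%-5s %6s %6s | %7s %5s | %7s %5s | %7s %5s\n", "Total", "", "",
              r(x$total$perf_resident), r(x$total$gap_resident),
              r(x$total$perf_expert), r(x$total$gap_expert),
              r(x$total$perf_integrated), r(x$total$gap_integrated)))
  invisible(x)
}

#' Improvement priority ranking of criteria
#'
#' Orders criteria by integrated aspiration gap, largest (most deficient)
#' first; ties are broken by global weight descending, then framework order.
#'
#' @param report a `vikor_report`.
#' @return character vector of criterion codes.
#' @export
priority_ranking <- function(report) {
  cc <- report$criteria
  ord <- order(-cc$gap_integrated, -cc$global_weight, seq_len(nrow(cc)))
  cc$code[ord]
}

#' Write a VIKOR report as CSV tables
#'
#' Writes `report_criteria.csv`, `report_dimensions.csv` and
#' `report_total.csv` at full precision.
#'
#' @param report a `vikor_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("report_criteria.csv", "report_dimensions.csv",
                            "report_total.csv"))
  utils::write.csv(report$criteria, paths[1], row.names = FALSE)
  utils::write.csv(report$dimensions, paths[2], row.names = FALSE)
  utils::write.csv(report$total, paths[3], row.names = FALSE)
  invisible(paths)
}
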