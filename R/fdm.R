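#' Triangular fuzzy number from a panel of scores
#'
#' The double-triangular Fuzzy Delphi construction summarises one panel of
#' ratings (all conservative, or all optimistic, ratings of one criterion) as
#' a triangular fuzzy number: lower bound = panel minimum, modal value =
#' geometric mean, upper bound = panel maximum.
#'
#' @param scores numeric vector of ratings on the 1-10 scale.
#' @return object of class `tfn`: list with `low`, `mid`, `high`.
#' @export
#' @examples
#' build_tfn(c(4, 9))  # mid is sqrt(36) = 6
build_tfn <- function(scores) {
  if (length(scores) == 0) {
    stop(errorCondition("cannot build a fuzzy number from an empty panel",
                        class = c("danpv_empty_panel", "danpv_error")))
  }
  stopifnot(all(scores >= 1), all(scores <= 10))
  structure(list(low = min(scores),
                 mid = exp(mean(log(scores))),
                 high = max(scores)),
            class = "tfn")
}

#' @export
print.tfn <- function(x, ...) {
  cat(sprintf("TFN (%.4g, %.4g, %.4g)\n", x$low, x$mid, x$high))
  invisible(x)
}

#' Gray-zone consensus of conservative and optimistic fuzzy numbers
#'
#' Implements the gray-zone test on the two triangular fuzzy numbers of one
#' criterion. With conservative TFN \eqn{(c_l, c_m, c_u)} and optimistic TFN
#' \eqn{(o_l, o_m, o_u)}:
#' \itemize{
#'   \item gray zone \eqn{Z = c_u - o_l}; check value \eqn{M = o_m - c_m};
#'   \item if \eqn{Z \le 0} the opinions do not overlap and the consensus is
#'     the midpoint \eqn{G = (c_m + o_m)/2};
#'   \item if \eqn{0 < Z \le M} the consensus is the abscissa of the crossing
#'     of the descending conservative edge with the ascending optimistic edge,
#'     \eqn{G = (c_u o_m - o_l c_m) / ((c_u - c_m) + (o_m - o_l))};
#'   \item if \eqn{Z > M} expert opinion has not converged: the consensus is
#'     undefined and the criterion is flagged for re-survey.
#' }
#' A degenerate crossing denominator (both triangles vertical at the same
#' point) falls back to the midpoint of the two modal values.
#'
#' @param cons,opt `tfn` objects for the conservative and optimistic panels.
#' @return list with `gray_zone`, `check_value`, `consensus` (NA when
#'   undefined) and logical `defined`.
#' @export
#' @examples
#' consensus_value(build_tfn(c(4, 5, 7)), build_tfn(c(6, 8, 9)))
consensus_value <- function(cons, opt) {
  z <- cons$high - opt$low
  m <- opt$mid - cons$mid
  if (z <= 0) {
    g <- (cons$mid + opt$mid) / 2
    defined <- TRUE
  } else if (z <= m) {
    den <- (cons$high - cons$mid) + (opt$mid - opt$low)
    g <- if (den == 0) (cons$mid + opt$mid) / 2 else
      (cons$high * opt$mid - opt$low * cons$mid) / den
    defined <- TRUE
  } else {
    g <- NA_real_
    defined <- FALSE
  }
  list(gray_zone = z, check_value = m, consensus = g, defined = defined)
}

#' Validate a Fuzzy Delphi questionnaire panel
#'
#' Questionnaires are accepted or rejected whole: an expert is invalid if any
#' framework criterion is missing from their responses, if any response is
#' incomplete (NA), out of the 1-10 scale, or has conservative >= optimistic
#' (an inconsistent pair).
#'
#' @param responses data.frame with columns `expert_id`, `criterion_code`,
#'   `conservative`, `optimistic`, one row per expert-criterion pair.
#' @param framework a `criteria_framework`.
#' @return list with `valid` (the surviving rows) and `rejected` (expert ids).
#' @export
validate_fdm_panel <- function(responses, framework) {
  stopifnot(all(c("expert_id", "criterion_code", "conservative", "optimistic")
                %in% names(responses)))
  codes <- framework$criteria$code
  experts <- unique(responses$expert_id)
  bad <- vapply(experts, function(e) {
    r <- responses[responses$expert_id == e, , drop = FALSE]
    r <- r[r$criterion_code %in% codes, , drop = FALSE]
    if (!all(codes %in% r$criterion_code)) return(TRUE)
    if (anyNA(r$conservative) || anyNA(r$optimistic)) return(TRUE)
    if (any(r$conservative < 1 | r$conservative > 10 |
            r$optimistic < 1 | r$optimistic > 10)) return(TRUE)
    any(r$conservative >= r$optimistic)
  }, logical(1))
  rejected <- experts[bad]
  valid <- responses[!(responses$expert_id %in% rejected) &
                       responses$criterion_code %in% codes, , drop = FALSE]
  if (nrow(valid) == 0) {
    stop(errorCondition("no valid questionnaires remain after screening",
                        class = c("danpv_empty_panel", "danpv_error")))
  }
  list(valid = valid, rejected = rejected)
}

#' Fuzzy Delphi screening of a criteria framework
#'
#' Runs the full screening round: questionnaire-level validation, triangular
#' fuzzy numbers per criterion for the conservative and optimistic panels,
#' gray-zone consensus, and retention against the threshold. Criteria whose
#' consensus is undefined (gray zone exceeds the check value) are reported
#' separately and never silently retained.
#'
#' @param responses data.frame as in [validate_fdm_panel()].
#' @param framework a `criteria_framework`.
#' @param threshold retention benchmark on the 1-10 consensus scale
#'   (default 4); retention is inclusive (consensus >= threshold).
#' @return object of class `fdm_screen`: list with `results` (one row per
#'   criterion: TFN components, gray zone, check value, consensus, retained),
#'   `retained` / `excluded` / `undefined` criterion code vectors,
#'   `rejected_experts`, `n_valid_experts` and `threshold`.
#' @export
fdm_screen <- function(responses, framework, threshold = 4) {
  stopifnot(threshold >= 1, threshold <= 10)
  val <- validate_fdm_panel(responses, framework)
  resp <- val$valid
  codes <- framework$criteria$code
  rows <- lapply(codes, function(code) {
    r <- resp[resp$criterion_code == code, , drop = FALSE]
    ct <- build_tfn(r$conservative)
    ot <- build_tfn(r$optimistic)
    cv <- consensus_value(ct, ot)
    data.frame(criterion_code = code,
               cons_low = ct$low, cons_mid = ct$mid, cons_high = ct$high,
               opt_low = ot$low, opt_mid = ot$mid, opt_high = ot$high,
               gray_zone = cv$gray_zone, check_value = cv$check_value,
               consensus = cv$consensus, defined = cv$defined,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$retained <- results$defined & results$consensus >= threshold
  structure(list(
    results = results,
    retained = results$criterion_code[results$retained],
    excluded = results$criterion_code[results$defined & !results$retained],
    undefined = results$criterion_code[!results$defined],
    rejected_experts = val$rejected,
    n_valid_experts = length(unique(resp$expert_id)),
    threshold = threshold), class = "fdm_screen")
}

#' @export
print.fdm_screen <- function(x, ...) {
  cat(sprintf("Fuzzy Delphi screening: %d valid experts (%d rejected)\n",
              x$n_valid_experts, length(x$rejected_experts)))
  cat(sprintf("  threshold %.3g: %d retained, %d excluded, %d without consensus\n",
              x$threshold, length(x$retained), length(x$excluded),
              length(x$undefined)))
  if (length(x$undefined))
    cat("  re-survey needed for:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Retained criteria of a screening result
#'
#' @param screening an `fdm_screen` object, or its `results` data.frame.
#' @param threshold retention benchmark; defaults to the one used when
#'   screening.
#' @return character vector of retained criterion codes.
#' @export
screen_criteria <- function(screening, threshold = NULL) {
  res <- if (inherits(screening, "fdm_screen")) screening$results else screening
  if (is.null(threshold)) {
    threshold <- if (inherits(screening, "fdm_screen")) screening$threshold else 4
  }
  res$criterion_code[res$defined & res$consensus >= threshold]
}
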