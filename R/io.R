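#' Read a satisfaction survey from CSV
#'
#' Expected columns: `respondent_id`, `criterion_code`, `rating`. Ratings
#' must be within the scale; violations are reported with their row numbers.
#'
#' @param path CSV path.
#' @param scale rating scale bounds (default c(1, 10)).
#' @return survey data.frame.
#' @export
read_survey <- function(path, scale = c(1, 10)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "criterion_code", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(errorCondition(
      sprintf("survey file %s is missing column(s): %s", path,
              paste(miss, collapse = ", ")),
      class = c("danpv_schema_error", "danpv_error")))
  }
  bad <- which(!is.na(df$rating) & (df$rating < scale[1] | df$rating > scale[2]))
  if (length(bad)) {
    stop(errorCondition(
      sprintf("survey file %s has out-of-scale rating(s) at row(s): %s", path,
              paste(utils::head(bad, 10), collapse = ", ")),
      class = c("danpv_schema_error", "danpv_error")))
  }
  df[need]
}

#' Write a satisfaction survey to CSV
#' @param survey survey data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE)
  invisible(path)
}

#' Read a DEMATEL questionnaire panel from long-form CSV
#'
#' Expected columns: `expert_id`, `from_code`, `to_code`, `value`. Matrices
#' are assembled in framework criterion order; missing cells default to 0 and
#' diagonals are forced to 0.
#'
#' @param path CSV path.
#' @param framework a `criteria_framework`.
#' @return named list of matrices, one per expert.
#' @export
read_dematel_panel <- function(path, framework) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "from_code", "to_code", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(errorCondition(
      sprintf("matrix file %s is missing column(s): %s", path,
              paste(miss, collapse = ", ")),
      class = c("danpv_schema_error", "danpv_error")))
  }
  codes <- framework$criteria$code
  bad <- which(!(df$from_code %in% codes) | !(df$to_code %in% codes))
  if (length(bad)) {
    stop(errorCondition(
      sprintf("matrix file %s has unknown criterion code(s) at row(s): %s",
              path, paste(utils::head(bad, 10), collapse = ", ")),
      class = c("danpv_schema_error", "danpv_error")))
  }
  lapply(split(df, df$expert_id), function(d) {
    m <- matrix(0, length(codes), length(codes), dimnames = list(codes, codes))
    m[cbind(match(d$from_code, codes), match(d$to_code, codes))] <- d$value
    diag(m) <- 0
    m
  })
}

#' Write a DEMATEL questionnaire panel to long-form CSV
#' @param panel named list of matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dematel_panel <- function(panel, path) {
  if (is.null(names(panel)))
    names(panel) <- sprintf("E%02d", seq_along(panel))
  rows <- lapply(names(panel), function(id) {
    m <- panel[[id]]
    codes <- rownames(m)
    data.frame(expert_id = id,
               from_code = rep(codes, times = ncol(m)),
               to_code = rep(codes, each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a Fuzzy Delphi panel from CSV
#'
#' Expected columns: `expert_id`, `criterion_code`, `conservative`,
#' `optimistic`.
#'
#' @param path CSV path.
#' @return responses data.frame.
#' @export
read_fdm_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "criterion_code", "conservative", "optimistic")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(errorCondition(
      sprintf("FDM file %s is missing column(s): %s", path,
              paste(miss, collapse = ", ")),
      class = c("danpv_schema_error", "danpv_error")))
  }
  df[need]
}

#' Write a Fuzzy Delphi panel to CSV
#' @param panel responses data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fdm_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
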