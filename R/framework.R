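#' Build a criteria framework
#'
#' A criteria framework is the ordered two-level hierarchy used throughout the
#' pipeline: evaluation dimensions, each holding one or more criteria. All
#' downstream matrices (direct influence, total influence, supermatrices) are
#' indexed in the framework's criterion order, which is dimension-major: the
#' criteria of the first dimension come first, then those of the second, and so
#' on. This makes every dimension a contiguous index block, which the
#' block-wise DANP arithmetic relies on.
#'
#' @param dimensions data.frame with columns `code` and `name`, one row per
#'   dimension, in evaluation order.
#' @param criteria data.frame with columns `code`, `name`, `dimension` (the
#'   parent dimension code) and optionally `description`.
#' @return An object of class `criteria_framework`: a list with elements
#'   `dimensions`, `criteria` (reordered dimension-major) and `blocks`, a named
#'   list mapping each dimension code to the integer indices of its criteria.
#' @export
#' @examples
#' fw <- criteria_framework(
#'   data.frame(code = c("D1", "D2"), name = c("Access", "Comfort")),
#'   data.frame(code = c("C11", "C21", "C22"),
#'              name = c("Paths", "Shade", "Noise"),
#'              dimension = c("D1", "D2", "D2")))
#' fw$blocks$D2
criteria_framework <- function(dimensions, criteria) {
  dimensions <- as.data.frame(dimensions, stringsAsFactors = FALSE)
  criteria <- as.data.frame(criteria, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "name") %in% names(dimensions)),
            all(c("code", "name", "dimension") %in% names(criteria)))
  if (is.null(criteria$description)) criteria$description <- ""

  if (anyDuplicated(dimensions$code) || anyDuplicated(criteria$code) ||
      any(criteria$code %in% dimensions$code)) {
    stop(errorCondition("duplicate dimension or criterion codes",
                        class = c("danpv_duplicate_code", "danpv_error")))
  }
  orphan <- setdiff(criteria$dimension, dimensions$code)
  if (length(orphan)) {
    stop(errorCondition(
      sprintf("criteria reference unknown dimension(s): %s",
              paste(orphan, collapse = ", ")),
      class = c("danpv_orphan_criterion", "danpv_error")))
  }
  empty <- setdiff(dimensions$code, criteria$dimension)
  if (length(empty)) {
    stop(errorCondition(
      sprintf("dimension(s) without criteria: %s", paste(empty, collapse = ", ")),
      class = c("danpv_empty_dimension", "danpv_error")))
  }

  # dimension-major ordering, stable within dimension
  ord <- order(match(criteria$dimension, dimensions$code))
  criteria <- criteria[ord, , drop = FALSE]
  rownames(criteria) <- NULL

  idx <- seq_len(nrow(criteria))
  blocks <- split(idx, factor(criteria$dimension, levels = dimensions$code))

  structure(list(dimensions = dimensions, criteria = criteria, blocks = blocks),
            class = "criteria_framework")
}

#' @export
print.criteria_framework <- function(x, ...) {
  cat(sprintf("Criteria framework: %d dimensions, %d criteria\n",
              nrow(x$dimensions), nrow(x$criteria)))
  for (d in seq_len(nrow(x$dimensions))) {
    code <- x$dimensions$code[d]
    members <- x$criteria$code[x$blocks[[code]]]
    cat(sprintf("  %s %s: %s\n", code, x$dimensions$name[d],
                paste(members, collapse = ", ")))
  }
  invisible(x)
}

#' Number of criteria in a framework
#' @param framework a `criteria_framework`.
#' @return integer count of criteria.
#' @export
n_criteria <- function(framework) nrow(framework$criteria)

#' Read a criteria framework from a CSV document
#'
#' The document has one record per row with columns `code`, `name`, `parent`.
#' Rows with an empty `parent` define dimensions (in order); rows with a
#' non-empty `parent` define criteria belonging to that dimension. An optional
#' `description` column is carried through.
#'
#' @param path path to the CSV file.
#' @return a validated [criteria_framework()].
#' @seealso [write_framework()] for the inverse.
#' @export
load_framework <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("code", "name", "parent")
  if (!all(need %in% names(df))) {
    stop(errorCondition(
      sprintf("framework file must have columns %s", paste(need, collapse = ", ")),
      class = c("danpv_schema_error", "danpv_error")))
  }
  df$parent[is.na(df$parent)] <- ""
  is_dim <- df$parent == ""
  dims <- data.frame(code = df$code[is_dim], name = df$name[is_dim],
                     stringsAsFactors = FALSE)
  crit <- data.frame(code = df$code[!is_dim], name = df$name[!is_dim],
                     dimension = df$parent[!is_dim], stringsAsFactors = FALSE)
  if (!is.null(df$description)) crit$description <- df$description[!is_dim]
  criteria_framework(dims, crit)
}

#' Write a criteria framework to a CSV document
#'
#' @param framework a `criteria_framework`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_framework <- function(framework, path) {
  dims <- data.frame(code = framework$dimensions$code,
                     name = framework$dimensions$name,
                     parent = "", description = "",
                     stringsAsFactors = FALSE)
  crit <- data.frame(code = framework$criteria$code,
                     name = framework$criteria$name,
                     parent = framework$criteria$dimension,
                     description = framework$criteria$description,
                     stringsAsFactors = FALSE)
  utils::write.csv(rbind(dims, crit), path, row.names = FALSE)
  invisible(path)
}

#' The bundled community-environment evaluation framework
#'
#' Returns the 6-dimension, 16-criterion framework used in the bundled case
#' study of community environmental factors bearing on the mental health of
#' elderly migrants: leisure entertainment, health promotion, social
#' interaction, self-actualization, daily tasks and environmental exposure.
#'
#' @return a `criteria_framework` with 6 dimensions and 16 criteria.
#' @export
#' @examples
#' case_framework()
case_framework <- function() {
  dims <- data.frame(
    code = paste0("D", 1:6),
    name = c("Leisure entertainment", "Health promotion", "Social interaction",
             "Self-actualization", "Daily tasks", "Environmental exposure"),
    stringsAsFactors = FALSE)
  crit <- data.frame(
    code = c("C11", "C12", "C13", "C21", "C22", "C31", "C32", "C41", "C42",
             "C51", "C52", "C53", "C54", "C61", "C62", "C63"),
    name = c("Entertainment Venues", "Art Viewing Space",
             "Historical & Cultural Sites", "Recreation & Fitness Facilities",
             "Healthcare Facilities", "Venues for Strong Social Interaction",
             "Multi-Functional Spaces", "Intergenerational Activities",
             "Skill Development", "Ancestral Worship Sites",
             "Living Convenience Facilities", "Transportation & Mobility",
             "Pet-Friendly Facilities", "Landscape Vegetation",
             "Acoustic Environment Quality", "Ambient Temperature"),
    dimension = c("D1", "D1", "D1", "D2", "D2", "D3", "D3", "D4", "D4",
                  "D5", "D5", "D5", "D5", "D6", "D6", "D6"),
    stringsAsFactors = FALSE)
  criteria_framework(dims, crit)
}

# map each criterion index to its dimension code, in framework order
criterion_dimension <- function(framework) {
  framework$criteria$dimension
}
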