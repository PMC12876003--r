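#' Aggregate a panel of direct-influence matrices
#'
#' Expert questionnaires are combined by the element-wise arithmetic mean,
#' the standard DEMATEL panel aggregation. All matrices must share shape and
#' a zero diagonal.
#'
#' @param matrices list of square numeric matrices (one per expert), entries
#'   on the 0-`scale_max` influence scale, zero diagonal.
#' @return the mean matrix, with the dimnames of the first matrix.
#' @export
aggregate_panel <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  n <- nrow(matrices[[1]])
  for (m in matrices) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      stop(errorCondition("direct matrices must all be square with equal size",
                          class = c("danpv_shape_error", "danpv_error")))
    }
    stopifnot(all(diag(m) == 0), all(m >= 0))
  }
  Reduce(`+`, matrices) / length(matrices)
}

#' Normalize a direct-influence matrix
#'
#' Divides by \eqn{s = \max(\max_i \sum_j a_{ij}, \max_j \sum_i a_{ij})}, the
#' larger of the maximum row and column sums, so the result has both maximum
#' row sum and maximum column sum at most 1 and (for nonnegative input with a
#' strict inequality somewhere) spectral radius below 1. A zero matrix maps
#' to itself.
#'
#' @param A nonnegative square matrix with zero diagonal.
#' @return the normalized matrix D.
#' @export
normalize_direct <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), all(A >= 0))
  s <- max(max(rowSums(A)), max(colSums(A)))
  if (s == 0) return(A)
  A / s
}

#' Total-influence matrix
#'
#' Closed form of the infinite sum of direct and indirect influence,
#' \eqn{T = D + D^2 + D^3 + \dots = D (I - D)^{-1}}, valid when the spectral
#' radius of D is below 1. The solve is dense (n is small) and refuses
#' ill-conditioned systems, which indicate an invalid normalization.
#'
#' @param D normalized direct-influence matrix.
#' @return the total-influence matrix T, same dimnames as D.
#' @export
total_influence <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  IminusD <- diag(n) - D
  if (rcond(IminusD) < 1e-12) {
    stop(errorCondition(
      "I - D is numerically singular; the direct matrix was not normalized",
      class = c("danpv_singular", "danpv_error")))
  }
  T <- D %*% solve(IminusD)
  dimnames(T) <- dimnames(D)
  T
}

#' Dimension-level total influence
#'
#' Collapses the criteria-level total-influence matrix to dimension level:
#' entry (p, q) is the arithmetic mean of the block of T_C rows in dimension p
#' and columns in dimension q.
#'
#' @param T_C criteria-level total-influence matrix in framework order.
#' @param framework a `criteria_framework`.
#' @return K x K dimension-level matrix T_D with dimension codes as dimnames.
#' @export
dimension_total_influence <- function(T_C, framework) {
  stopifnot(nrow(T_C) == n_criteria(framework))
  codes <- framework$dimensions$code
  K <- length(codes)
  T_D <- matrix(0, K, K, dimnames = list(codes, codes))
  for (p in codes) for (q in codes) {
    T_D[p, q] <- mean(T_C[framework$blocks[[p]], framework$blocks[[q]]])
  }
  T_D
}

#' Causal profile of a total-influence matrix
#'
#' For each node i: r (row sum, influence given), c (column sum, influence
#' received), prominence r + c (total involvement) and relation r - c (net
#' causal role; positive = net cause, negative = net receiver). These are the
#' coordinates of the influential network relation map.
#'
#' @param T a square total-influence matrix with dimnames.
#' @return data.frame with columns `code`, `r`, `c`, `prominence`, `relation`.
#' @export
causal_profile <- function(T) {
  stopifnot(is.matrix(T), nrow(T) == ncol(T))
  codes <- rownames(T)
  if (is.null(codes)) codes <- as.character(seq_len(nrow(T)))
  data.frame(code = codes, r = unname(rowSums(T)), c = unname(colSums(T)),
             prominence = unname(rowSums(T) + colSums(T)),
             relation = unname(rowSums(T) - colSums(T)),
             stringsAsFactors = FALSE)
}

#' Influence priority order
#'
#' Orders nodes by net causal influence: relation (r - c) descending, ties
#' broken by prominence descending and then by input order. Net causes come
#' first; improving them propagates through the influence network.
#'
#' @param profile a [causal_profile()] data.frame.
#' @return character vector of codes, most influential first.
#' @export
dimension_priority <- function(profile) {
  ord <- order(-profile$relation, -profile$prominence, seq_len(nrow(profile)))
  profile$code[ord]
}

#' Test-retest consistency of influence questionnaires
#'
#' Compares two direct-relation matrices (typically the aggregated matrices of
#' a survey and its repeat) by the total and mean absolute entry-wise
#' difference over all n^2 ordered pairs.
#'
#' @param M1,M2 square matrices of equal size.
#' @return list with `n_pairs`, `total_abs_diff`, `mean_abs_diff`.
#' @export
retest_consistency <- function(M1, M2) {
  if (!all(dim(M1) == dim(M2))) {
    stop(errorCondition("matrices must have identical shape",
                        class = c("danpv_shape_error", "danpv_error")))
  }
  total <- sum(abs(M1 - M2))
  n_pairs <- length(M1)
  list(n_pairs = n_pairs, total_abs_diff = total,
       mean_abs_diff = total / n_pairs)
}

#' Run the DEMATEL stage on an expert panel
#'
#' Aggregates the panel, normalizes, computes the criteria-level
#' total-influence matrix T_C, collapses it to the dimension level T_D, and
#' derives causal profiles at both levels.
#'
#' @param panel list of direct-influence matrices in framework order.
#' @param framework a `criteria_framework`.
#' @return object of class `dematel`: list with `direct` (aggregated matrix),
#'   `D` (normalized), `T_C`, `T_D`, `profile_C`, `profile_D`.
#' @export
dematel <- function(panel, framework) {
  A <- aggregate_panel(panel)
  codes <- framework$criteria$code
  stopifnot(nrow(A) == length(codes))
  dimnames(A) <- list(codes, codes)
  D <- normalize_direct(A)
  T_C <- total_influence(D)
  T_D <- dimension_total_influence(T_C, framework)
  structure(list(direct = A, D = D, T_C = T_C, T_D = T_D,
                 profile_C = causal_profile(T_C),
                 profile_D = causal_profile(T_D)),
            class = "dematel")
}

#' @export
print.dematel <- function(x, ...) {
  cat(sprintf("DEMATEL total-influence analysis: %d criteria, %d dimensions\n",
              nrow(x$T_C), nrow(x$T_D)))
  cat("Dimension influence priority:",
      paste(dimension_priority(x$profile_D), collapse = " > "), "\n")
  invisible(x)
}
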