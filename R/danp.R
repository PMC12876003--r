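#' Block-wise row normalization of the criteria total-influence matrix
#'
#' Within each (row-dimension, column-dimension) block of T_C, every row is
#' divided by its sum over that block, so block rows become stochastic.
#' All-zero block rows are left at zero (degenerate; noted via a message).
#'
#' @param T_C criteria-level total-influence matrix in framework order.
#' @param framework a `criteria_framework`.
#' @return the block-row-normalized matrix.
#' @export
normalize_tc_blocks <- function(T_C, framework) {
  stopifnot(nrow(T_C) == n_criteria(framework))
  out <- T_C
  for (p in framework$dimensions$code) for (q in framework$dimensions$code) {
    ri <- framework$blocks[[p]]; ci <- framework$blocks[[q]]
    block <- T_C[ri, ci, drop = FALSE]
    s <- rowSums(block)
    zero <- s == 0
    if (any(zero)) message(sprintf("all-zero block row(s) in block (%s, %s)", p, q))
    s[zero] <- 1
    out[ri, ci] <- block / s
  }
  out
}

#' Unweighted supermatrix
#'
#' The transpose of the block-normalized total-influence matrix: columns of
#' the supermatrix are "influenced-by" distributions, the common DANP
#' formulation.
#'
#' @param Tn block-normalized matrix from [normalize_tc_blocks()].
#' @return a list of class `supermatrix` with `values` and `stage`.
#' @export
build_unweighted_supermatrix <- function(Tn) {
  structure(list(values = t(Tn), stage = "unweighted"), class = "supermatrix")
}

#' Weight the supermatrix by normalized dimension influence
#'
#' Each row of T_D is normalized by its row sum; the (p, q) block of the
#' unweighted supermatrix is then scaled by the normalized T_D entry (q, p).
#' For non-degenerate inputs the result is column-stochastic.
#'
#' @param W unweighted `supermatrix`.
#' @param T_D dimension-level total-influence matrix.
#' @param framework a `criteria_framework`.
#' @return a weighted `supermatrix`.
#' @export
weight_supermatrix <- function(W, T_D, framework) {
  stopifnot(inherits(W, "supermatrix"), W$stage == "unweighted")
  rs <- rowSums(T_D)
  if (any(rs == 0)) {
    stop(errorCondition("T_D has an all-zero row: disconnected dimension",
                        class = c("danpv_degenerate", "danpv_error")))
  }
  TDn <- T_D / rs
  V <- W$values
  codes <- framework$dimensions$code
  for (p in codes) for (q in codes) {
    ri <- framework$blocks[[p]]; ci <- framework$blocks[[q]]
    V[ri, ci] <- V[ri, ci] * TDn[codes == q, codes == p]
  }
  structure(list(values = V, stage = "weighted"), class = "supermatrix")
}

#' Limit supermatrix
#'
#' Raises the weighted supermatrix to successive powers by repeated squaring
#' until the maximum entry-wise change drops below `tol` (default 1e-9) or
#' `max_squarings` is reached. If the squaring limit does not have identical
#' columns (a reducible or periodic structure; the canonical example is a
#' period-2 cycle), a Cesaro fallback averages consecutive powers,
#' (P + P W)/2, which resolves period-2 oscillation. Failure after the
#' fallback is reported with diagnostics.
#'
#' @param W weighted, column-stochastic `supermatrix`.
#' @param tol convergence tolerance on the entry-wise change.
#' @param max_squarings cap on the number of squarings.
#' @return a limit `supermatrix`; all columns agree to tolerance.
#' @export
limit_supermatrix <- function(W, tol = 1e-9, max_squarings = 200) {
  stopifnot(inherits(W, "supermatrix"), W$stage == "weighted")
  V0 <- W$values
  cols_identical <- function(M, eps) {
    max(apply(M, 1, function(r) diff(range(r)))) < eps
  }
  P <- V0
  for (k in seq_len(max_squarings)) {
    P2 <- P %*% P
    # renormalize columns to damp numerical drift from stochasticity
    cs <- colSums(P2)
    cs[cs == 0] <- 1
    P2 <- sweep(P2, 2, cs, "/")
    if (max(abs(P2 - P)) < tol) {
      P <- P2
      break
    }
    P <- P2
  }
  if (!cols_identical(P, 1e-6)) {
    P <- (P + P %*% V0) / 2
    if (!cols_identical(P, 1e-6)) {
      stop(errorCondition(
        sprintf(paste0("limit supermatrix did not converge to identical columns",
                       " (max column spread %.3g): reducible or periodic structure"),
                max(apply(P, 1, function(r) diff(range(r))))),
        class = c("danpv_nonconvergence", "danpv_error")))
    }
  }
  structure(list(values = P, stage = "limit"), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("%s supermatrix, %d x %d\n", x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Influential weights from a limit supermatrix
#'
#' Global weights are the (identical) columns of the limit supermatrix,
#' renormalized to sum to 1. Dimension weights are the sums of member global
#' weights; local weights are globals renormalized within each dimension, so
#' that global(c) = dimension(d(c)) x local(c).
#'
#' @param limit a limit `supermatrix`.
#' @param framework a `criteria_framework`.
#' @return a [weight_set()] object.
#' @export
derive_weight_set <- function(limit, framework) {
  stopifnot(inherits(limit, "supermatrix"), limit$stage == "limit")
  g <- rowMeans(limit$values)
  g <- g / sum(g)
  names(g) <- framework$criteria$code
  weight_set(global = g, framework = framework)
}

#' Construct a weight set
#'
#' A weight set holds the three nested weight vectors of the DANP stage:
#' global criterion weights (the influential weights, summing to 1),
#' dimension weights (sums of member globals) and local weights (globals
#' renormalized within each dimension). It can be built either from a global
#' vector or from local + dimension vectors (as printed in case-study
#' reports).
#'
#' @param global named vector of global weights (one per criterion), or NULL.
#' @param local named vector of within-dimension weights, used with
#'   `dimension` when `global` is NULL.
#' @param dimension named vector of dimension weights.
#' @param framework a `criteria_framework`.
#' @return object of class `weight_set` with elements `global`, `local`,
#'   `dimension`.
#' @export
weight_set <- function(global = NULL, local = NULL, dimension = NULL,
                       framework) {
  codes <- framework$criteria$code
  dcodes <- framework$dimensions$code
  dim_of <- criterion_dimension(framework)
  if (is.null(global)) {
    stopifnot(!is.null(local), !is.null(dimension))
    local <- local[codes]; dimension <- dimension[dcodes]
    global <- unname(dimension[dim_of]) * local
    names(global) <- codes
  } else {
    global <- global[codes]
    dimension <- vapply(dcodes, function(d) sum(global[dim_of == d]), numeric(1))
    if (any(dimension == 0)) {
      stop(errorCondition("a dimension has zero total weight",
                          class = c("danpv_degenerate", "danpv_error")))
    }
    local <- global / unname(dimension[dim_of])
  }
  structure(list(global = global, local = local, dimension = dimension),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Influential weights (global):\n")
  print(round(x$global, 3))
  cat("Dimension weights:\n")
  print(round(x$dimension, 3))
  invisible(x)
}

#' DANP influential weights from DEMATEL total-influence matrices
#'
#' Chains the DANP stages: block-normalize T_C, transpose into the unweighted
#' supermatrix, weight by normalized T_D, take the supermatrix limit, and
#' read off global / local / dimension weights.
#'
#' @param dm a [dematel()] object (or a list with `T_C` and `T_D`).
#' @param framework a `criteria_framework`.
#' @return a `weight_set`.
#' @export
danp_weights <- function(dm, framework) {
  Tn <- normalize_tc_blocks(dm$T_C, framework)
  W <- build_unweighted_supermatrix(Tn)
  Ww <- weight_supermatrix(W, dm$T_D, framework)
  derive_weight_set(limit_supermatrix(Ww), framework)
}
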