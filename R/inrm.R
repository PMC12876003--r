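#' Build the influential network relation map (INRM)
#'
#' Nodes are placed at (prominence, relation) coordinates; a directed edge
#' p -> q is drawn when the total influence T(p, q) reaches the threshold.
#' The default threshold is the mean of the off-diagonal entries of the
#' matrix in question (inclusive: entries equal to the mean are kept), applied
#' separately at the dimension and the criteria level.
#'
#' @param dm a [dematel()] object.
#' @param threshold_D,threshold_C edge thresholds; `NULL` (default) uses the
#'   off-diagonal mean of `T_D` / `T_C`.
#' @return object of class `inrm`: list with `nodes_D`, `nodes_C` (causal
#'   profiles), `edges_D`, `edges_C` (data.frames from/to/weight) and the
#'   thresholds used.
#' @export
build_inrm <- function(dm, threshold_D = NULL, threshold_C = NULL) {
  stopifnot(inherits(dm, "dematel"))
  mk_edges <- function(T, thr) {
    if (is.null(thr)) thr <- mean(T[row(T) != col(T)])
    idx <- which(T >= thr & row(T) != col(T), arr.ind = TRUE)
    list(edges = data.frame(from = rownames(T)[idx[, 1]],
                            to = colnames(T)[idx[, 2]],
                            weight = T[idx],
                            stringsAsFactors = FALSE),
         threshold = thr)
  }
  ed <- mk_edges(dm$T_D, threshold_D)
  ec <- mk_edges(dm$T_C, threshold_C)
  structure(list(nodes_D = dm$profile_D, nodes_C = dm$profile_C,
                 edges_D = ed$edges, edges_C = ec$edges,
                 threshold_D = ed$threshold, threshold_C = ec$threshold),
            class = "inrm")
}

#' @export
print.inrm <- function(x, ...) {
  cat(sprintf("INRM: %d dimension edges (threshold %.4g), %d criteria edges (threshold %.4g)\n",
              nrow(x$edges_D), x$threshold_D, nrow(x$edges_C), x$threshold_C))
  invisible(x)
}

#' Export an INRM as a DOT graph description
#'
#' @param inrm an [build_inrm()] result.
#' @param level `"dimension"` or `"criteria"`.
#' @return character vector of DOT lines.
#' @export
inrm_dot <- function(inrm, level = c("dimension", "criteria")) {
  level <- match.arg(level)
  nodes <- if (level == "dimension") inrm$nodes_D else inrm$nodes_C
  edges <- if (level == "dimension") inrm$edges_D else inrm$edges_C
  c("digraph INRM {",
    sprintf('  "%s" [prominence=%.6g, relation=%.6g];',
            nodes$code, nodes$prominence, nodes$relation),
    sprintf('  "%s" -> "%s" [weight=%.6g];', edges$from, edges$to, edges$weight),
    "}")
}

#' Write INRM edge lists and DOT files
#'
#' Writes, for each level, a CSV edge list, a CSV node table with
#' prominence/relation coordinates, and a DOT file.
#'
#' @param inrm an `inrm` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_inrm <- function(inrm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (level in c("dimension", "criteria")) {
    nodes <- if (level == "dimension") inrm$nodes_D else inrm$nodes_C
    edges <- if (level == "dimension") inrm$edges_D else inrm$edges_C
    p1 <- file.path(dir, paste0("inrm_", level, "_edges.csv"))
    p2 <- file.path(dir, paste0("inrm_", level, "_nodes.csv"))
    p3 <- file.path(dir, paste0("inrm_", level, ".dot"))
    utils::write.csv(edges, p1, row.names = FALSE)
    utils::write.csv(nodes, p2, row.names = FALSE)
    writeLines(inrm_dot(inrm, level), p3)
    paths <- c(paths, p1, p2, p3)
  }
  invisible(paths)
}

#' Plot an INRM
#'
#' Scatter of nodes at (prominence, relation) with directed edges drawn as
#' arrows, the usual cause-effect diagram of DEMATEL analyses: nodes above
#' the zero line are net causes, nodes below are net receivers.
#'
#' @param x an `inrm` object.
#' @param level `"dimension"` or `"criteria"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.inrm <- function(x, level = c("dimension", "criteria"), ...) {
  level <- match.arg(level)
  nodes <- if (level == "dimension") x$nodes_D else x$nodes_C
  edges <- if (level == "dimension") x$edges_D else x$edges_C
  graphics::plot(nodes$prominence, nodes$relation, pch = 19,
                 xlab = "prominence (r + c)", ylab = "relation (r - c)", ...)
  graphics::abline(h = 0, lty = 3)
  if (nrow(edges)) {
    i <- match(edges$from, nodes$code); j <- match(edges$to, nodes$code)
    graphics::arrows(nodes$prominence[i], nodes$relation[i],
                     nodes$prominence[j], nodes$relation[j],
                     length = 0.08, col = "grey50")
  }
  graphics::text(nodes$prominence, nodes$relation, nodes$code, pos = 3)
  invisible(x)
}
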