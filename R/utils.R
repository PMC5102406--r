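## Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' All stochastic operations in the package route their randomness through this
#' helper so that a seed in a config fully determines the output without
#' clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Topological order of a directed graph given as an edge data.frame
#'
#' Kahn's algorithm over the node vector; errors if the graph has a cycle.
#' @param nodes character vector of node ids
#' @param edges data.frame with columns `parent`, `child`
#' @return nodes in a topological order (parents before children)
#' @noRd
topological_order <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(factor(edges$child, levels = nodes))
    indeg[names(tab)] <- as.integer(tab)
  }
  kids <- split(edges$child, factor(edges$parent, levels = nodes))
  order_out <- character(0)
  queue <- nodes[indeg == 0L]
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (w in kids[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order_out) != length(nodes))
    stop("graph contains a cycle; a directed acyclic graph is required")
  order_out
}

#' @noRd
is_acyclic <- function(nodes, edges) {
  ok <- TRUE
  tryCatch(topological_order(nodes, edges), error = function(e) ok <<- FALSE)
  ok
}

#' Geometric mean of strictly positive values
#' @noRd
geometric_mean <- function(x) exp(mean(log(x)))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
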