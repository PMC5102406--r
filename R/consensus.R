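## Consensus module: node/edge-count curves over the frequency cutoff,
## slope-minimum cutoff detection, consensus extraction and neighborhood
## queries.

#' @noRd
edge_table <- function(x) {
  if (inherits(x, "ensemble_summary")) return(x$edges)
  if (is.data.frame(x)) {
    stopifnot("f" %in% names(x))
    if (!all(c("parent", "child") %in% names(x)))
      stop("edge table needs parent/child columns")
    return(x)
  }
  if (is.numeric(x))  # bare frequency vector: invent disjoint endpoints
    return(data.frame(parent = sprintf("a%06d", seq_along(x)),
                      child = sprintf("b%06d", seq_along(x)),
                      f = as.numeric(x), stringsAsFactors = FALSE))
  stop("cannot interpret edge input")
}

#' Edge- and node-count curves against the frequency cutoff
#'
#' For every cutoff on the grid, counts the edges with f >= cutoff and the
#' nodes among their endpoints.  The slope of the edge curve is computed by
#' central differences after moving-average smoothing, and is the basis of
#' [detect_cutoff()].
#'
#' @param x an `ensemble_summary`, an edge data.frame with an `f` column, or
#'   a bare numeric vector of edge frequencies.
#' @param step grid step (default 0.01; the grid spans 0.001 to 1).
#' @param smooth_window moving-average window, in grid steps (odd; default
#'   5).
#' @return a `frequency_curve` data.frame with columns `cutoff`, `edges`,
#'   `nodes`, `slope`.
#' @export
frequency_curves <- function(x, step = 0.01, smooth_window = 5) {
  edges <- edge_table(x)
  if (!nrow(edges)) stop("no edges observed")
  grid <- unique(c(0.001, seq(step, 1, by = step)))
  e_count <- vapply(grid, function(g) sum(edges$f >= g), 0L)
  n_count <- vapply(grid, function(g) {
    keep <- edges$f >= g
    length(unique(c(edges$parent[keep], edges$child[keep])))
  }, 0L)
  k <- max(1L, smooth_window)
  if (k %% 2L == 0L) k <- k + 1L
  pad <- (k - 1L) / 2L
  padded <- c(rep(e_count[1L], pad), e_count, rep(e_count[length(e_count)], pad))
  smoothed <- stats::filter(padded, rep(1 / k, k), sides = 2)
  smoothed <- as.numeric(smoothed)[(pad + 1L):(pad + length(e_count))]
  slope <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    lo <- max(1L, i - 1L); hi <- min(length(grid), i + 1L)
    slope[i] <- (smoothed[hi] - smoothed[lo]) / (grid[hi] - grid[lo])
  }
  structure(data.frame(cutoff = grid, edges = e_count, nodes = n_count,
                       slope = slope),
            class = c("frequency_curve", "data.frame"))
}

#' Pick the consensus cutoff at the slope minimum of the edge curve
#'
#' The edge curve is nonincreasing, so its most negative slope sits in the
#' low-frequency false-positive mass; the informative set point is the
#' plateau where the curve flattens between that mass and the
#' high-confidence edges.  The cutoff returned is the grid point inside the
#' search window minimizing |slope|, ties going to the smallest cutoff
#' (conservative toward larger networks).
#'
#' @param curve a `frequency_curve`.
#' @param window search window (default `c(0.2, 0.9)`).
#' @return the selected cutoff f*.
#' @export
detect_cutoff <- function(curve, window = c(0.2, 0.9)) {
  stopifnot(inherits(curve, "frequency_curve"))
  if (length(window) != 2L || window[1L] >= window[2L] ||
      window[1L] <= 0 || window[2L] >= 1 + 1e-9)
    stop("search window must be a nonempty interval inside (0, 1)")
  in_win <- curve$cutoff >= window[1L] & curve$cutoff <= window[2L]
  if (!any(in_win)) stop("search window contains no grid point")
  sub <- curve[in_win, ]
  a <- abs(sub$slope)
  # ties (to numerical tolerance) go to the smallest cutoff
  sub$cutoff[which(a <= min(a) + 1e-8 * max(1, min(a)))[1L]]
}

#' @noRd
consensus_network_new <- function(edges, cutoff, M = NA_integer_) {
  nodes <- sort(unique(c(edges$parent, edges$child)))
  structure(list(cutoff = cutoff, nodes = nodes, edges = edges,
                 n_nodes = length(nodes), n_edges = nrow(edges),
                 edges_per_node = if (length(nodes)) nrow(edges) / length(nodes)
                                  else NA_real_,
                 M = M),
            class = "consensus_network")
}

#' Extract the consensus network at a frequency cutoff
#'
#' Retains the edges with f >= f* (inclusive threshold: an edge present in
#' 600 of 1,000 networks survives a 0.6 cutoff).  Each retained edge keeps
#' its frequency, its sign r, and — when the summary carries per-variant
#' counts — the modulator and conditional class of its most frequent
#' variant.  The node set is the union of retained edge endpoints, and
#' edges-per-node = |edges| / |nodes| summarizes sparsity.
#'
#' @param x an `ensemble_summary` or an edge data.frame with `f` (and
#'   optionally `r`) columns.
#' @param cutoff the frequency cutoff f* in (0, 1].
#' @return a `consensus_network`.
#' @export
extract_consensus <- function(x, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("cutoff must lie in (0, 1]")
  edges <- edge_table(x)
  keep <- edges[edges$f >= cutoff, , drop = FALSE]
  if (!"r" %in% names(keep)) keep$r <- rep(NA_real_, nrow(keep))
  keep$modulator <- rep(NA_character_, nrow(keep))
  keep$class <- rep("plain", nrow(keep))
  if (inherits(x, "ensemble_summary") && nrow(keep)) {
    ev <- x$edge_variants
    for (i in seq_len(nrow(keep))) {
      vi <- ev[ev$parent == keep$parent[i] & ev$child == keep$child[i], ,
               drop = FALSE]
      if (nrow(vi)) {
        top <- vi[which.max(vi$f), ]
        keep$modulator[i] <- top$modulator
        keep$class[i] <- top$class
      }
    }
  }
  rownames(keep) <- NULL
  consensus_network_new(keep, cutoff,
                        if (inherits(x, "ensemble_summary")) x$M
                        else NA_integer_)
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf(
    "consensus_network: %d nodes, %d edges at f >= %.3g (%.2f edges per node)\n",
    x$n_nodes, x$n_edges, x$cutoff,
    x$edges_per_node))
  invisible(x)
}

#' Neighborhood of seed nodes in the consensus network
#'
#' Returns the induced subgraph on the nodes within `radius` edges of any
#' seed, traversing edges without regard to direction.  Radius 0 returns
#' the seed nodes with no edges; seeds absent from the network are reported
#' with a warning, not an error.
#'
#' @param net a `consensus_network`.
#' @param seeds character vector of node ids.
#' @param radius traversal depth (default 2).
#' @return a `consensus_network` restricted to the neighborhood (cutoff and
#'   edge annotations preserved).
#' @export
neighborhood <- function(net, seeds, radius = 2) {
  stopifnot(inherits(net, "consensus_network"))
  unknown <- setdiff(seeds, net$nodes)
  if (length(unknown))
    warning("unknown seed node(s): ", paste(unknown, collapse = ", "))
  seeds <- intersect(seeds, net$nodes)
  g <- igraph::graph_from_data_frame(net$edges[c("parent", "child")],
                                     directed = TRUE,
                                     vertices = net$nodes)
  inside <- if (length(seeds))
    unique(names(unlist(igraph::ego(g, order = radius, nodes = seeds,
                                    mode = "all"))))
  else character(0)
  keep <- net$edges$parent %in% inside & net$edges$child %in% inside &
    radius >= 1
  sub <- consensus_network_new(net$edges[keep, , drop = FALSE], net$cutoff,
                               net$M)
  sub$nodes <- sort(unique(c(inside, sub$nodes)))
  sub$n_nodes <- length(sub$nodes)
  sub$edges_per_node <- if (sub$n_nodes) sub$n_edges / sub$n_nodes else NA_real_
  sub
}
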