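#' Directed functional-connectivity graph
#'
#' Container for the output of a connectivity method: a directed edge list
#' over units with per-edge statistics, plus the connection density (the
#' fraction of ordered unit pairs with a significant edge).
#'
#' @param edges data.frame with at least `source`, `target` and a statistic
#'   column; self-edges are rejected.
#' @param units all unit ids the method was run over (defines the density
#'   denominator).
#' @param method provenance string, e.g. `"ccg"` or `"te"`.
#' @param params list of method parameters (bin size, alpha, scale, ...).
#' @return list of class `connectivity_graph` with `edges`, `units`,
#'   `method`, `params`, `density`.
#' @export
connectivity_graph <- function(edges, units, method = "unknown",
                               params = list()) {
  if (nrow(edges) && any(edges$source == edges$target))
    stop("self-edges are not allowed")
  n <- length(units)
  dens <- if (n >= 2) nrow(edges) / (n * (n - 1)) else 0
  structure(list(edges = edges, units = units, method = method,
                 params = params, density = dens),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %s: %d units, %d edges (density %.4g)\n",
              x$method, length(x$units), nrow(x$edges), x$density))
  invisible(x)
}

# igraph (undirected, simplified) view of the significant-edge graph,
# including isolated units.
as_igraph_undirected <- function(g) {
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(g$edges)) g$edges[, c("source", "target")] else
      data.frame(source = integer(), target = integer()),
    directed = FALSE,
    vertices = data.frame(name = g$units))
  igraph::simplify(ig)
}

#' Modularity of a connectivity graph
#'
#' Louvain community detection on the symmetrized, binarized
#' significant-edge graph, returning the standard Newman-Girvan modularity
#' Q of the resulting partition. Isolated units are retained as their own
#' communities (they do not change Q). Returns NA for an edgeless graph.
#'
#' @param g a [connectivity_graph()].
#' @param seed seed for the (stochastic) Louvain pass.
#' @return modularity Q (between -0.5 and 1), or NA.
#' @export
modularity_q <- function(g, seed = 1L) {
  if (!nrow(g$edges)) return(NA_real_)
  ig <- as_igraph_undirected(g)
  set.seed(seed)
  cl <- igraph::cluster_louvain(ig)
  igraph::modularity(ig, igraph::membership(cl))
}
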