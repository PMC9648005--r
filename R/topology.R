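#' Topology statistics of a layered network
#'
#' Computes the descriptive statistics used to characterize the curated
#' chondrocyte network: component and interaction counts, the mean number of
#' distinct neighbors per node, and the characteristic (mean shortest) path
#' length.
#'
#' `n_interactions` counts every interaction row (both layers, including
#' parallel edges). `mean_unique_neighbors` counts, for each node, the
#' distinct adjacent nodes ignoring direction, multiplicity and layer --
#' reciprocal and multi-layer edges between the same pair collapse to one
#' neighbor. `mean_shortest_path` is the average hop-count distance over all
#' reachable ordered pairs of distinct nodes, under the chosen direction mode
#' (unreachable pairs are excluded; the default is undirected).
#'
#' @param net a `layered_network` with at least one component.
#' @param direction `"undirected"` (default) or `"directed"`.
#' @return a list of class `topology_stats` with fields `n_components`,
#'   `n_interactions`, `mean_unique_neighbors`, `mean_shortest_path`.
#' @export
topology_stats <- function(net, direction = c("undirected", "directed")) {
  direction <- match.arg(direction)
  validate_network(net)
  n <- nrow(net$components)
  if (n == 0) stop("empty network")
  ints <- net$interactions

  if (nrow(ints)) {
    pairs <- unique(data.frame(
      a = pmin(ints$source, ints$target),
      b = pmax(ints$source, ints$target), stringsAsFactors = FALSE))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]  # self-loops: not neighbors
    mean_nb <- sum(table(c(pairs$a, pairs$b))[net$components$id], na.rm = TRUE) / n
  } else {
    mean_nb <- 0
  }

  g <- igraph::graph_from_data_frame(
    unique(ints[, c("source", "target")]),
    directed = (direction == "directed"),
    vertices = net$components$id)
  d <- igraph::distances(g, mode = "out")
  d <- d[row(d) != col(d)]
  finite <- is.finite(d)
  msp <- if (any(finite)) mean(d[finite]) else NA_real_

  structure(list(n_components = n,
                 n_interactions = nrow(ints),
                 mean_unique_neighbors = as.numeric(mean_nb),
                 mean_shortest_path = msp,
                 direction = direction),
            class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf(paste0("topology (%s): %d components, %d interactions, ",
                     "%.2f mean unique neighbors, %.2f mean shortest path\n"),
              x$direction, x$n_components, x$n_interactions,
              x$mean_unique_neighbors, x$mean_shortest_path))
  invisible(x)
}
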