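#' Node degree scores
#'
#' `Deg(v) = |N(v)|`, the number of direct neighbours.
#'
#' @param net A network (anything accepted by [as_hub_network()]).
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family local scoring methods
#' @export
score_degree <- function(net) {
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  deg <- igraph::degree(net)[nodes]
  stats::setNames(as.numeric(deg), nodes)
}

#' Maximum connected component of a node's neighbourhood
#'
#' Induces the subgraph on the open neighbourhood `N(v)` and returns its
#' largest connected component `MC(v)`. When several components tie in vertex
#' count, the one whose sorted vertex list is lexicographically smallest is
#' chosen, so the result (and the DMNC edge count) is deterministic. An
#' isolated node has an empty neighbourhood component.
#'
#' @param net A network.
#' @param v A node ID.
#' @return A list with `vertices` (sorted character vector) and `edge_count`
#'   (edges induced among them).
#' @family local scoring methods
#' @export
max_neighborhood_component <- function(net, v) {
  net <- as_hub_network(net)
  check_nodes_known(net, v)
  nb <- sort_ids(names(igraph::neighbors(net, v)))
  if (length(nb) == 0L) {
    return(list(vertices = character(0), edge_count = 0L))
  }
  sub <- igraph::induced_subgraph(net, nb)
  comp <- igraph::components(sub)
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, sort_ids)
  sizes <- lengths(parts)
  best <- parts[sizes == max(sizes)]
  # lexicographically smallest sorted vertex list among tied components
  keys <- vapply(best, paste, character(1), collapse = "\r")
  pick <- best[[order_ids(keys)[1L]]]
  list(
    vertices = pick,
    edge_count = igraph::gsize(igraph::induced_subgraph(net, pick))
  )
}

#' Maximum Neighborhood Component scores
#'
#' `MNC(v) = |V(MC(v))|`: the vertex count of the largest connected component
#' of the subgraph induced by `v`'s neighbours. Isolated nodes score 0.
#'
#' @inheritParams score_degree
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family local scoring methods
#' @export
score_mnc <- function(net) {
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  vapply(nodes, function(v) {
    length(max_neighborhood_component(net, v)$vertices)
  }, numeric(1))
}

#' Density of Maximum Neighborhood Component scores
#'
#' `DMNC(v) = |E(MC(v))| / |V(MC(v))|^epsilon` with `epsilon = 1.7` by
#' default. Defined as 0 when `MC(v)` has fewer than two vertices (no induced
#' edge), which covers isolated nodes and edgeless neighbourhoods.
#'
#' @inheritParams score_degree
#' @param epsilon Positive exponent applied to the component's vertex count.
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family local scoring methods
#' @export
score_dmnc <- function(net, epsilon = 1.7) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    abort("`epsilon` must be a single positive number")
  }
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  vapply(nodes, function(v) {
    mc <- max_neighborhood_component(net, v)
    nv <- length(mc$vertices)
    if (nv < 2L) return(0)
    mc$edge_count / nv^epsilon
  }, numeric(1))
}

#' Enumerate the maximal cliques of a network
#'
#' Every maximal clique with at least two vertices, each exactly once;
#' singleton cliques (isolated nodes) are excluded so that the MCC
#' degree-fallback holds uniformly. Clique enumeration is exponential in the
#' worst case; dense graphs beyond a few thousand nodes may be impractical.
#'
#' @inheritParams score_degree
#' @return A list of sorted character vectors, ordered deterministically.
#' @family local scoring methods
#' @export
enumerate_maximal_cliques <- function(net) {
  net <- as_hub_network(net)
  cl <- igraph::max_cliques(net, min = 2)
  cl <- lapply(cl, function(x) sort_ids(names(x)))
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order_ids(keys)]
}

#' Maximal Clique Centrality scores
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over all maximal cliques `C` that
#' contain `v`. When no two neighbours of `v` are adjacent, every maximal
#' clique containing `v` is a single edge and the score equals the degree;
#' isolated nodes score 0. Scores use double-precision factorials, exact up to
#' clique size 18 and overflowing to `Inf` past size 170.
#'
#' @inheritParams score_degree
#' @param cliques Optionally, a precomputed result of
#'   [enumerate_maximal_cliques()] for `net` (it is checked for consistency).
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family local scoring methods
#' @export
score_mcc <- function(net, cliques = NULL) {
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  if (is.null(cliques)) {
    cliques <- enumerate_maximal_cliques(net)
  } else {
    miss <- setdiff(unique(unlist(cliques)), nodes)
    if (length(miss)) {
      abort(paste0(
        "clique set is inconsistent with the network; unknown node(s): ",
        paste(miss, collapse = ", ")
      ))
    }
  }
  score <- stats::setNames(numeric(length(nodes)), nodes)
  for (cl in cliques) {
    score[cl] <- score[cl] + factorial(length(cl) - 1L)
  }
  score
}
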