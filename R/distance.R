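#' All-pairs shortest-path distances and path counts
#'
#' Runs a breadth-first search from every node, recording hop distances and the
#' number of distinct shortest paths to every other node. Pairs in different
#' components have distance `Inf` and path count 0. Also records the component
#' partition and each component's diameter (maximum pairwise distance; 0 for
#' singletons), which the per-component centrality rescaling needs.
#'
#' @param net A network (anything accepted by [as_hub_network()]).
#' @return An object of class `distance_index`: a list with elements `nodes`
#'   (sorted IDs), `dist` and `sigma` (node-by-node matrices), `component`
#'   (named labels), `component_sizes`, and `diameter` (named by component
#'   label).
#' @export
all_pairs_shortest <- function(net) {
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  n <- length(nodes)
  adj <- adjacency_index(net, nodes)

  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) {
    bs <- bfs_counts(adj, n, s)
    dist[s, ] <- bs$dist
    sigma[s, ] <- bs$sigma
  }

  ci <- component_index(net)
  diam <- vapply(split(nodes, ci$membership[nodes]), function(members) {
    d <- dist[members, members, drop = FALSE]
    max(d[is.finite(d)])
  }, numeric(1))

  structure(
    list(
      nodes = nodes, dist = dist, sigma = sigma,
      component = ci$membership, component_sizes = ci$sizes,
      diameter = diam
    ),
    class = "distance_index"
  )
}

#' @export
print.distance_index <- function(x, ...) {
  cat(sprintf(
    "<distance_index: %d nodes, %d component(s), max diameter %s>\n",
    length(x$nodes), length(x$component_sizes),
    if (length(x$diameter)) max(x$diameter) else NA
  ))
  invisible(x)
}

# Neighbour index lists (sorted integer indices into `nodes`).
adjacency_index <- function(net, nodes = network_nodes(net)) {
  n <- length(nodes)
  el <- igraph::as_edgelist(net, names = TRUE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(el)) {
    a <- match(el[, 1L], nodes)
    b <- match(el[, 2L], nodes)
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
    adj <- lapply(adj, sort)
  }
  adj
}

# Level-synchronous BFS from source index s: hop distances and shortest-path
# counts. Frontiers are processed in increasing index order so discovery order
# is deterministic (and the first discoverer of a node is its smallest-ID
# predecessor, which build_spt() relies on).
bfs_counts <- function(adj, n, s, want_parent = FALSE) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  parent <- rep(NA_integer_, n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      dv1 <- dist[v] + 1
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dv1
          sigma[w] <- sigma[v]
          if (want_parent) parent[w] <- v
          nxt <- c(nxt, w)
        } else if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
        }
      }
    }
    frontier <- sort(unique(nxt))
  }
  list(dist = dist, sigma = sigma, parent = parent)
}

#' Build a breadth-first shortest-path tree
#'
#' The tree spans the root's component; each node's tree depth equals its hop
#' distance from the root. Ties are resolved deterministically: a node's
#' parent is its smallest-ID neighbour at the previous depth.
#'
#' @param net A network.
#' @param s Root node ID.
#' @return An object of class `shortest_path_tree`: list with `root`,
#'   `members` (sorted IDs of the root's component), `parent` (named character
#'   vector, `NA` for the root) and `depth` (named integer vector).
#' @export
build_spt <- function(net, s) {
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  check_nodes_known(net, s)
  adj <- adjacency_index(net, nodes)
  bs <- bfs_counts(adj, length(nodes), match(s, nodes), want_parent = TRUE)
  inside <- which(is.finite(bs$dist))
  members <- nodes[inside]
  parent <- ifelse(is.na(bs$parent[inside]), NA_character_, nodes[bs$parent[inside]])
  names(parent) <- members
  depth <- as.integer(bs$dist[inside])
  names(depth) <- members
  structure(
    list(root = s, members = members, parent = parent, depth = depth),
    class = "shortest_path_tree"
  )
}

#' @export
print.shortest_path_tree <- function(x, ...) {
  cat(sprintf(
    "<shortest_path_tree rooted at %s: %d nodes, depth %d>\n",
    x$root, length(x$members), max(x$depth)
  ))
  invisible(x)
}

# Subtree size of every member of a shortest-path tree (number of nodes whose
# root path passes through it, counting itself; the root's is the whole tree).
spt_subtree_sizes <- function(tree) {
  size <- stats::setNames(rep(1L, length(tree$members)), tree$members)
  ord <- names(sort(tree$depth, decreasing = TRUE))
  for (w in ord) {
    p <- tree$parent[[w]]
    if (!is.na(p)) size[[p]] <- size[[p]] + size[[w]]
  }
  size
}
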