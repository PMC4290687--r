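new_subnetwork_view <- function(selected, first_stage, edges) {
  structure(
    list(selected = selected, first_stage = first_stage, edges = edges),
    class = "hub_subnetwork"
  )
}

#' @export
print.hub_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<hub_subnetwork: %d selected node(s), %d first-stage neighbour(s), %d edge(s) (%d abstract)>\n",
    length(x$selected), length(x$first_stage), nrow(x$edges),
    sum(x$edges$type == "abstract")
  ))
  invisible(x)
}

# canonical empty edge table for subnetwork views
subnet_edge_tbl <- function(from = character(0), to = character(0),
                            type = character(0), distance = integer(0),
                            path = character(0)) {
  tibble(from = from, to = to, type = type, distance = distance, path = path)
}

# real (direct) edges of the full network among `within`, canonically oriented
induced_edge_tbl <- function(net, within) {
  sub <- igraph::induced_subgraph(net, within)
  el <- igraph::as_edgelist(sub, names = TRUE)
  if (nrow(el) == 0L) return(subnet_edge_tbl())
  nodes <- network_nodes(net)
  ra <- match(el[, 1L], nodes)
  rb <- match(el[, 2L], nodes)
  from <- ifelse(ra <= rb, el[, 1L], el[, 2L])
  to <- ifelse(ra <= rb, el[, 2L], el[, 1L])
  ord <- order(match(from, nodes), match(to, nodes))
  subnet_edge_tbl(from[ord], to[ord], rep("real", length(ord)),
                  rep(1L, length(ord)), rep(NA_character_, length(ord)))
}

#' Expand a node selection with its first-stage neighbours
#'
#' Adds every node directly interacting with the selection (the "first-stage"
#' nodes) and returns the subnetwork induced by the union, so a top-k hub set
#' can be viewed or re-scored together with its immediate partners.
#'
#' @param net A network (anything accepted by [as_hub_network()]).
#' @param selected Character vector of selected node IDs (or a ranked tibble
#'   with a `node` column).
#' @return A `hub_subnetwork` object: `selected`, `first_stage` (neighbours
#'   outside the selection) and `edges` (tibble of the induced edges with
#'   columns `from`, `to`, `type = "real"`, `distance = 1`, `path = NA`).
#' @export
expand_first_stage <- function(net, selected) {
  net <- as_hub_network(net)
  selected <- selection_ids(selected)
  check_nodes_known(net, selected)
  nb <- unique(unlist(lapply(selected, function(v) {
    names(igraph::neighbors(net, v))
  })))
  first_stage <- sort_ids(setdiff(nb %||% character(0), selected))
  new_subnetwork_view(
    selected = sort_ids(selected),
    first_stage = first_stage,
    edges = induced_edge_tbl(net, c(selected, first_stage))
  )
}

#' Shortest-path abstraction among a selected node group
#'
#' Adjacent selected pairs keep their real edge. Each non-adjacent pair in the
#' same component is joined by an "abstract" (dotted) edge annotated with the
#' hop distance in the full network and one concrete shortest path (among
#' equal-length paths, the lexicographically smallest node sequence from the
#' smaller-ID endpoint). Pairs in different components are omitted.
#'
#' @inheritParams expand_first_stage
#' @return A `hub_subnetwork` object whose `edges` tibble mixes `type =
#'   "real"` rows (distance 1) and `type = "abstract"` rows (distance >= 2,
#'   `path` a comma-separated node sequence including both endpoints).
#' @export
group_shortest_paths <- function(net, selected) {
  net <- as_hub_network(net)
  selected <- sort_ids(selection_ids(selected))
  check_nodes_known(net, selected)
  nodes <- network_nodes(net)
  adj <- adjacency_index(net, nodes)
  ci <- component_index(net)

  edges <- induced_edge_tbl(net, selected)
  if (length(selected) >= 2L) {
    # distances from every selected target, reused across pairs
    dist_to <- lapply(selected, function(v) {
      bfs_counts(adj, length(nodes), match(v, nodes))$dist
    })
    names(dist_to) <- selected
    for (i in seq_len(length(selected) - 1L)) {
      for (j in seq(i + 1L, length(selected))) {
        u <- selected[i]
        v <- selected[j]
        if (ci$membership[[u]] != ci$membership[[v]]) next
        d <- dist_to[[v]][match(u, nodes)]
        if (d < 2) next # adjacent: already a real edge
        path <- lex_shortest_path(adj, nodes, u, v, dist_to[[v]])
        edges <- dplyr::bind_rows(
          edges,
          subnet_edge_tbl(u, v, "abstract", as.integer(d),
                          paste(path, collapse = ","))
        )
      }
    }
  }
  new_subnetwork_view(selected, character(0), edges)
}

# Greedy lexicographically-smallest shortest path from u to v given the
# distance field toward v: always step to the smallest-ID neighbour that
# strictly decreases the remaining distance.
lex_shortest_path <- function(adj, nodes, u, v, dist_v) {
  cur <- match(u, nodes)
  target <- match(v, nodes)
  path <- integer(dist_v[cur] + 1L)
  path[1L] <- cur
  step <- 1L
  while (cur != target) {
    nb <- adj[[cur]]
    cur <- min(nb[dist_v[nb] == dist_v[cur] - 1])
    step <- step + 1L
    path[step] <- cur
  }
  nodes[path]
}

selection_ids <- function(selected) {
  if (is.data.frame(selected)) {
    if (!"node" %in% names(selected)) {
      abort("a data-frame selection needs a `node` column")
    }
    selected <- selected$node
  }
  unique(as.character(selected))
}

#' Write a subnetwork view to an edge-list TSV
#'
#' Columns: `from`, `to`, `type` (`real` for direct edges, `abstract` for
#' dotted shortest-path links), `distance` (hops), `path` (comma-separated
#' node sequence for abstract edges) and `role` annotations for the node
#' provenance of each endpoint (`selected` or `first_stage`).
#'
#' @param view A `hub_subnetwork` from [expand_first_stage()] or
#'   [group_shortest_paths()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(view, path) {
  if (!inherits(view, "hub_subnetwork")) {
    abort("`view` must be a hub_subnetwork object")
  }
  role <- function(v) ifelse(v %in% view$selected, "selected", "first_stage")
  out <- view$edges
  out$from_role <- role(out$from)
  out$to_role <- role(out$to)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
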