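#' Closeness centrality (per-component)
#'
#' `Clo(v)` is the sum over all other nodes `w` of `1 / dist(v, w)`.
#' Unreachable nodes are infinitely distant and contribute 0, so disconnected
#' networks are scored without special handling; on a connected network this
#' is classic harmonic-sum closeness.
#'
#' @param net A network (anything accepted by [as_hub_network()]).
#' @param dindex Optionally, a precomputed [all_pairs_shortest()] index for
#'   `net`.
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family global scoring methods
#' @export
score_closeness <- function(net, dindex = NULL) {
  net <- as_hub_network(net)
  dindex <- dindex %||% all_pairs_shortest(net)
  inv <- 1 / dindex$dist
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv)
}

#' EcCentricity scores (per-component)
#'
#' `EC(v) = (|V(C(v))| / |V|) * 1 / max{dist(v, w): w in C(v)}`: the inverse
#' eccentricity of `v` within its component, rescaled by the fraction of the
#' network that component holds so scores are comparable across disconnected
#' components. Isolated nodes score 0.
#'
#' @inheritParams score_closeness
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family global scoring methods
#' @export
score_eccentricity <- function(net, dindex = NULL) {
  net <- as_hub_network(net)
  dindex <- dindex %||% all_pairs_shortest(net)
  n <- length(dindex$nodes)
  csize <- dindex$component_sizes[dindex$component]
  ecc <- node_eccentricity(dindex)
  ifelse(ecc > 0, (csize / n) / ecc, 0)
}

# max finite distance from each node (0 for nodes in singleton components)
node_eccentricity <- function(dindex) {
  apply(dindex$dist, 1L, function(r) max(r[is.finite(r)]))
}

#' Radiality scores (per-component)
#'
#' `Rad(v) = (|V(C(v))| / |V|) * sum over w in C(v), w != v of
#' (Delta + 1 - dist(v, w)) / max{dist(v, w): w in C(v)}`, where `Delta` is
#' the diameter of `v`'s component. The leading factor rescales per-component
#' values by component size; isolated nodes score 0.
#'
#' The default denominator is the node's own maximum distance (its
#' eccentricity). `normalization = "size"` divides by `|V(C(v))| - 1` instead,
#' the classic normalisation; the two agree on rankings within a component but
#' differ across components.
#'
#' @inheritParams score_closeness
#' @param normalization `"eccentricity"` (default) or `"size"`.
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family global scoring methods
#' @export
score_radiality <- function(net, dindex = NULL,
                            normalization = c("eccentricity", "size")) {
  normalization <- match.arg(normalization)
  net <- as_hub_network(net)
  dindex <- dindex %||% all_pairs_shortest(net)
  nodes <- dindex$nodes
  n <- length(nodes)
  csize <- dindex$component_sizes[dindex$component]
  delta <- dindex$diameter[dindex$component]
  ecc <- node_eccentricity(dindex)
  out <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(n)) {
    if (csize[i] < 2L) next
    row <- dindex$dist[i, ]
    fin <- is.finite(row) & row > 0
    total <- sum(delta[i] + 1 - row[fin])
    denom <- if (normalization == "eccentricity") ecc[i] else csize[i] - 1
    out[i] <- (csize[i] / n) * total / denom
  }
  out
}

#' BottleNeck scores
#'
#' For every node `s`, a breadth-first shortest-path tree `T_s` is built over
#' `s`'s component (deterministic parents: smallest-ID neighbour at the
#' previous depth). `p_s(v) = 1` when more than `|V(T_s)| / 4` of the
#' root-to-node tree paths pass through `v` — that is, when `v`'s subtree
#' (counting `v` itself; the whole tree for `v = s`) holds more than a quarter
#' of the tree — and `BN(v)` is the sum of `p_s(v)` over all roots `s`.
#'
#' @inheritParams score_closeness
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family global scoring methods
#' @export
score_bottleneck <- function(net) {
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  n <- length(nodes)
  adj <- adjacency_index(net, nodes)
  score <- stats::setNames(numeric(n), nodes)
  for (s in seq_len(n)) {
    bs <- bfs_counts(adj, n, s, want_parent = TRUE)
    members <- which(is.finite(bs$dist))
    nmem <- length(members)
    size <- stats::setNames(rep(1, nmem), members)
    for (w in members[order(bs$dist[members], decreasing = TRUE)]) {
      p <- bs$parent[w]
      if (!is.na(p)) size[[as.character(p)]] <- size[[as.character(p)]] + size[[as.character(w)]]
    }
    hit <- members[size[as.character(members)] > nmem / 4]
    score[hit] <- score[hit] + 1
  }
  score
}

# Per-node sum over unordered pairs {s,t} in v's component (s,t != v) of
# f(sigma_st(v), sigma_st); shared engine for Stress and Betweenness.
pair_path_sums <- function(dindex, ratio) {
  nodes <- dindex$nodes
  out <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    members <- setdiff(names(which(dindex$component == dindex$component[[v]])), v)
    if (length(members) < 2L) next
    d_sv <- dindex$dist[members, v]
    d_vt <- dindex$dist[v, members]
    on_path <- outer(d_sv, d_vt, "+") == dindex$dist[members, members]
    through <- outer(dindex$sigma[members, v], dindex$sigma[v, members]) * on_path
    if (ratio) through <- through / dindex$sigma[members, members]
    out[[v]] <- sum(through) / 2
  }
  out
}

#' Stress centrality (per-component)
#'
#' `Str(v)` is the number of shortest paths that pass through `v`: the sum
#' over unordered pairs `{s, t}` in `v`'s component (both different from `v`)
#' of `sigma_st(v)`, the count of shortest `s`-`t` paths using `v`.
#'
#' @inheritParams score_closeness
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family global scoring methods
#' @export
score_stress <- function(net, dindex = NULL) {
  net <- as_hub_network(net)
  dindex <- dindex %||% all_pairs_shortest(net)
  pair_path_sums(dindex, ratio = FALSE)
}

#' Betweenness centrality (per-component)
#'
#' `BC(v)` is the sum over unordered pairs `{s, t}` in `v`'s component (both
#' different from `v`) of `sigma_st(v) / sigma_st`: the fraction of shortest
#' `s`-`t` paths that pass through `v`.
#'
#' @inheritParams score_closeness
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family global scoring methods
#' @export
score_betweenness <- function(net, dindex = NULL) {
  net <- as_hub_network(net)
  dindex <- dindex %||% all_pairs_shortest(net)
  pair_path_sums(dindex, ratio = TRUE)
}

#' Edge Percolated Component scores
#'
#' Monte-Carlo percolation connectivity. In each of `iterations` rounds an
#' independent uniform `[0, 1)` number is drawn for every edge (in a fixed
#' order: edges sorted by endpoint IDs, so a given seed is reproducible across
#' platforms) and edges whose number falls below `threshold` are removed.
#' `EPC(v) = (1/|V|) * sum over rounds of the number of nodes still connected
#' to v` (a node counts as connected to itself). The score scales linearly
#' with `iterations`; rankings do not depend on the scale.
#'
#' @inheritParams score_closeness
#' @param threshold Edge-removal threshold in `[0, 1]`. 0 keeps every edge, 1
#'   removes every edge.
#' @param iterations Number of percolated replicate networks (default 1000).
#' @param seed Optional integer seed; when supplied the caller's RNG state is
#'   left untouched and results are bit-reproducible.
#' @return Named numeric vector over all nodes, sorted by ID.
#' @family global scoring methods
#' @export
score_epc <- function(net, threshold = 0.5, iterations = 1000, seed = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single number in [0, 1]")
  }
  if (!is.numeric(iterations) || length(iterations) != 1L ||
      is.na(iterations) || iterations < 1 || iterations != round(iterations)) {
    abort("`iterations` must be a positive integer")
  }
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  n <- length(nodes)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))

  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }

  # canonical edge order: endpoints sorted within an edge, edges sorted by
  # (low, high) endpoint rank; eid[k] is the igraph edge index of canonical
  # edge k
  el <- igraph::as_edgelist(net, names = TRUE)
  m <- nrow(el)
  ra <- match(el[, 1L], nodes)
  rb <- match(el[, 2L], nodes)
  eid <- order(pmin(ra, rb), pmax(ra, rb))

  total <- numeric(n)
  for (k in seq_len(iterations)) {
    r <- stats::runif(m)
    drop <- eid[r < threshold]
    gk <- if (length(drop)) igraph::delete_edges(net, drop) else net
    memb <- igraph::components(gk)$membership
    total <- total + tabulate(memb)[memb]
  }
  stats::setNames(total / n, nodes)
}
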