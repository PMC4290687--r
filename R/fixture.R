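#' Generate a clique-planted synthetic benchmark network
#'
#' Builds a labelled test network that mimics the clustering of essential
#' proteins in interaction maps: vertex-disjoint planted cliques (the
#' "complexes") sit on top of a sparse random background. Background-background
#' and clique-background node pairs are wired independently with
#' `background_edge_prob`; no extra edges are added between different planted
#' cliques, so each clique is a maximal clique of the result. Clique members
#' are labelled essential with probability `essential_fraction` and background
#' nodes with probability `background_rate` (independent draws).
#'
#' Node IDs are generated so that clique nodes sort as `q01_01, q01_02, ...`
#' and background nodes as `bg001, ...`. Given a `seed`, output is
#' deterministic and the caller's RNG state is left untouched.
#'
#' @param n_background Number of background nodes (default 200).
#' @param clique_sizes Integer vector of planted clique sizes, each at least 3
#'   (default three 6-cliques).
#' @param background_edge_prob Wiring probability for background pairs
#'   (default 0.02).
#' @param essential_fraction Probability that a clique member is labelled
#'   essential (default 0.9).
#' @param background_rate Probability that a background node is labelled
#'   essential (default 0.05).
#' @param seed Optional integer seed.
#' @return A list with elements `network` (an igraph), `essential` (character
#'   vector of essential node IDs) and `labels` (tibble `node`, `planted`,
#'   `essential`).
#' @export
generate_fixture <- function(n_background = 200, clique_sizes = c(6, 6, 6),
                             background_edge_prob = 0.02,
                             essential_fraction = 0.9,
                             background_rate = 0.05, seed = NULL) {
  if (!is.numeric(n_background) || length(n_background) != 1L ||
      is.na(n_background) || n_background < 0 ||
      n_background != round(n_background)) {
    abort("`n_background` must be a single non-negative integer")
  }
  if (length(clique_sizes) &&
      (!is.numeric(clique_sizes) || any(is.na(clique_sizes)) ||
       any(clique_sizes < 3) || any(clique_sizes != round(clique_sizes)))) {
    abort("`clique_sizes` must be integers of at least 3")
  }
  for (p in list(background_edge_prob, essential_fraction, background_rate)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      abort("probabilities must be single numbers in [0, 1]")
    }
  }
  if (length(clique_sizes) == 0L && n_background == 0L) {
    abort("infeasible fixture: no clique nodes and no background nodes")
  }

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

  clique_nodes <- list()
  for (i in seq_along(clique_sizes)) {
    clique_nodes[[i]] <- sprintf("q%02d_%02d", i, seq_len(clique_sizes[i]))
  }
  bg_nodes <- if (n_background > 0) sprintf("bg%03d", seq_len(n_background)) else character(0)
  planted <- unlist(clique_nodes) %||% character(0)

  edges <- character(0)
  for (cl in clique_nodes) {
    pairs <- utils::combn(cl, 2L)
    edges <- c(edges, as.character(pairs))
  }

  # random wiring: bg-bg pairs, then clique-bg pairs, in a fixed order so a
  # given seed reproduces the same graph
  add_random_pairs <- function(a, b = NULL) {
    if (is.null(b)) {
      if (length(a) < 2L) return(character(0))
      pairs <- utils::combn(a, 2L)
    } else {
      if (length(a) == 0L || length(b) == 0L) return(character(0))
      pairs <- rbind(rep(a, each = length(b)), rep(b, times = length(a)))
    }
    keep <- stats::runif(ncol(pairs)) < background_edge_prob
    as.character(pairs[, keep, drop = FALSE])
  }
  edges <- c(edges, add_random_pairs(bg_nodes))
  edges <- c(edges, add_random_pairs(planted, bg_nodes))

  net <- build_network(edges, isolated = c(planted, bg_nodes))

  ess_planted <- planted[stats::runif(length(planted)) < essential_fraction]
  ess_bg <- bg_nodes[stats::runif(length(bg_nodes)) < background_rate]
  essential <- sort_ids(c(ess_planted, ess_bg))

  nodes <- network_nodes(net)
  labels <- tibble(
    node = nodes,
    planted = nodes %in% planted,
    essential = nodes %in% essential
  )
  list(network = net, essential = essential, labels = labels)
}

#' Write a generated fixture to disk
#'
#' Writes the network as a two-column edge-list TSV (isolated nodes as
#' single-field rows) and the labels as a one-ID-per-line essential list plus
#' a full label table.
#'
#' @param fixture A fixture list from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- fixture$network
  el <- igraph::as_edgelist(net, names = TRUE)
  nodes <- network_nodes(net)
  lines <- character(0)
  if (nrow(el)) {
    ra <- match(el[, 1L], nodes)
    rb <- match(el[, 2L], nodes)
    from <- ifelse(ra <= rb, el[, 1L], el[, 2L])
    to <- ifelse(ra <= rb, el[, 2L], el[, 1L])
    ord <- order(match(from, nodes), match(to, nodes))
    lines <- paste(from[ord], to[ord], sep = "\t")
  }
  iso <- nodes[igraph::degree(net)[nodes] == 0]
  writeLines(c(lines, iso), file.path(dir, "network.tsv"))
  writeLines(fixture$essential, file.path(dir, "essential.txt"))
  readr::write_tsv(fixture$labels, file.path(dir, "labels.tsv"), progress = FALSE)
  invisible(dir)
}
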