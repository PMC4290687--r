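#' Read an undirected network from a SIF file or a two-column edge list
#'
#' Loads a network of opaque string node identifiers. Self-loops and duplicate
#' (including reciprocal) edges are dropped so the result is a simple
#' undirected graph; the number removed is reported with [message()]. Rows
#' containing a single field declare an isolated node, which is retained with
#' degree 0.
#'
#' @param path Path to the network file.
#' @param format `"auto"` (default: decided by the `.sif` extension), `"sif"`
#'   for Cytoscape Simple Interaction Format rows
#'   (`source interaction target [target ...]`), or `"edgelist"` for
#'   whitespace/tab-separated `source target` rows. Edge-list lines starting
#'   with `#` are skipped; fields after the first two are ignored.
#' @return An [igraph::igraph] object: undirected, simple, with vertex names
#'   and vertices ordered by node ID.
#' @examples
#' tf <- tempfile(fileext = ".sif")
#' writeLines(c("a pp b c", "b pp c"), tf)
#' g <- read_network(tf)
#' igraph::gsize(g)
#' @export
read_network <- function(path, format = c("auto", "sif", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("network file not found: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "edgelist"
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*$", lines)
  if (format == "edgelist") keep <- keep & !grepl("^\\s*#", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    abort(paste0("no network records in file: ", path))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")

  edges <- character(0)
  isolated <- character(0)
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    nf <- length(f)
    if (nf == 1L) {
      isolated <- c(isolated, f)
    } else if (format == "edgelist") {
      edges <- c(edges, f[1L], f[2L])
    } else if (nf == 2L) {
      abort(sprintf(
        "malformed SIF row at line %d: interaction type without target", idx[i]
      ))
    } else {
      # "source interaction t1 t2 ..." -> source-t1, source-t2, ...
      for (t in f[3:nf]) edges <- c(edges, f[1L], t)
    }
  }
  build_network(edges, isolated)
}

# Construct the canonical simple undirected graph from an interleaved edge
# endpoint vector plus isolated nodes; vertices sorted by ID for determinism.
build_network <- function(edges, isolated = character(0)) {
  nodes <- sort_ids(unique(c(edges, isolated)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(edges)) {
    g <- igraph::add_edges(g, edges)
  }
  before <- igraph::gsize(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- before - igraph::gsize(g)
  if (dropped > 0) {
    inform(sprintf(
      "removed %d self-loop/duplicate record(s); %d nodes, %d edges retained",
      dropped, igraph::vcount(g), igraph::gsize(g)
    ))
  }
  g
}

#' Coerce an object to a hubrank network
#'
#' Accepts an [igraph::igraph] (made undirected and simple if needed, vertices
#' relabelled to their `name` attribute) or a data frame whose first two
#' columns are edge endpoints (rows with a missing second field declare
#' isolated nodes).
#'
#' @param x An igraph object or an edge data frame.
#' @return An undirected simple named igraph with vertices sorted by ID.
#' @export
as_hub_network <- function(x) {
  if (igraph::is_igraph(x)) {
    if (is.null(igraph::V(x)$name)) {
      igraph::V(x)$name <- as.character(seq_len(igraph::vcount(x)))
    }
    el <- igraph::as_edgelist(x, names = TRUE)
    iso <- igraph::V(x)$name[igraph::degree(x) == 0]
    return(build_network(as.character(t(el)), iso))
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) abort("edge data frame needs at least two columns")
    from <- as.character(x[[1L]])
    to <- as.character(x[[2L]])
    iso <- from[is.na(to) | to == ""]
    ok <- !(is.na(to) | to == "")
    return(build_network(as.character(rbind(from[ok], to[ok])), iso))
  }
  abort("cannot interpret `x` as a network (need an igraph or a data frame)")
}

network_nodes <- function(net) {
  sort_ids(igraph::V(net)$name)
}

check_nodes_known <- function(net, v) {
  miss <- setdiff(v, igraph::V(net)$name)
  if (length(miss)) {
    abort(paste0("unknown node(s): ", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Connected components of a network
#'
#' Components are labelled deterministically by the smallest node ID (byte
#' order) they contain.
#'
#' @param net A network (anything accepted by [as_hub_network()]).
#' @return A tibble with columns `node`, `component` (label), and
#'   `component_size`, ordered by node ID.
#' @export
network_components <- function(net) {
  net <- as_hub_network(net)
  ci <- component_index(net)
  tibble(
    node = names(ci$membership),
    component = unname(ci$membership),
    component_size = unname(ci$sizes[ci$membership])
  )
}

# Internal: membership named by node (labels = smallest member ID) + sizes.
component_index <- function(net) {
  nodes <- network_nodes(net)
  if (length(nodes) == 0L) {
    return(list(membership = character(0), sizes = integer(0)))
  }
  comp <- igraph::components(net)
  memb <- comp$membership[nodes]
  labels <- vapply(
    split(nodes, memb), function(m) m[[1L]], character(1)
  )
  membership <- labels[as.character(memb)]
  names(membership) <- nodes
  sizes <- table(membership)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  list(membership = membership, sizes = sizes)
}

#' Write a node score table to TSV
#'
#' Writes one row per node with one column per scoring method. Rows are sorted
#' by node ID and method columns follow the canonical order of
#' [hub_methods()]; scores keep full double precision (at least 6 significant
#' digits).
#'
#' @param table A data frame with a `node` column and one numeric column per
#'   method, as returned by [hub_score()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    abort("score table must be a non-empty data frame")
  }
  if (!"node" %in% names(table)) abort("score table needs a `node` column")
  methods <- intersect(hub_methods(), names(table))
  extra <- setdiff(names(table), c("node", hub_methods()))
  out <- table[order_ids(table$node), c("node", methods, extra), drop = FALSE]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a node-ID list (one ID per line)
#'
#' Used for essential-protein label files and subnetwork node selections.
#' Blank lines and lines starting with `#` are skipped. Several files may be
#' given; their union is returned (the union rule for multiple label sources).
#'
#' @param paths Character vector of file paths.
#' @return Character vector of unique node IDs, sorted.
#' @export
read_node_list <- function(paths) {
  ids <- character(0)
  for (p in paths) {
    if (!file.exists(p)) abort(paste0("node list file not found: ", p))
    lines <- trimws(readLines(p, warn = FALSE, encoding = "UTF-8"))
    lines <- lines[lines != "" & !startsWith(lines, "#")]
    ids <- c(ids, lines)
  }
  sort_ids(unique(ids))
}

#' Read a two-column ID mapping table
#'
#' @param path Path to a TSV with source IDs in column 1 and target IDs in
#'   column 2 (no header).
#' @return A named character vector mapping source to target IDs.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) abort(paste0("ID map file not found: ", path))
  df <- utils::read.table(
    path, sep = "\t", header = FALSE, colClasses = "character",
    comment.char = "#", quote = ""
  )
  if (ncol(df) < 2L) abort("ID map needs two tab-separated columns")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Apply an ID mapping to a vector of node IDs
#'
#' IDs absent from the map pass through unchanged.
#'
#' @param ids Character vector of IDs.
#' @param map Named character vector from [read_id_map()].
#' @return Remapped character vector.
#' @export
apply_id_map <- function(ids, map) {
  hit <- ids %in% names(map)
  ids[hit] <- unname(map[ids[hit]])
  ids
}
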