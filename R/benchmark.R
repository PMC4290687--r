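#' Degree threshold splitting hubs from the periphery
#'
#' The maximum integer `t` such that nodes of degree greater than `t` jointly
#' hold more than half of the total degree:
#' `2 * sum(Deg(v) for Deg(v) > t) > sum(Deg(v))`. Nodes above the threshold
#' are called high-degree, the rest low-degree.
#'
#' @param net A network with at least one edge.
#' @return A single integer threshold.
#' @export
degree_threshold <- function(net) {
  net <- as_hub_network(net)
  deg <- score_degree(net)
  total <- sum(deg)
  if (total == 0) abort("degree threshold is undefined for an edgeless network")
  ok <- vapply(0:max(deg), function(t) 2 * sum(deg[deg > t]) > total, logical(1))
  max(which(ok)) - 1L # candidates start at t = 0
}

#' Partition nodes into high- and low-degree classes
#'
#' @param net A network.
#' @param t Non-negative integer threshold, typically from
#'   [degree_threshold()]. A node is `high` when its degree exceeds `t`.
#' @return A tibble with columns `node`, `degree`, `degree_class`
#'   (`"high"`/`"low"`).
#' @export
partition_by_degree <- function(net, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    abort("`t` must be a single non-negative integer")
  }
  deg <- score_degree(net)
  tibble(
    node = names(deg),
    degree = as.integer(unname(deg)),
    degree_class = unname(ifelse(deg > t, "high", "low"))
  )
}

#' Precision of essential-node prediction in a top-k list
#'
#' `precision@k` = (number of essential nodes among the k top-ranked) / k.
#'
#' @param ranked A ranked tibble from [rank_nodes()].
#' @param essential Character vector of essential node IDs.
#' @param k Cut-off; must not exceed the list length.
#' @return A single number in `[0, 1]`.
#' @export
precision_at_k <- function(ranked, essential, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    abort("`k` must be a single positive integer")
  }
  if (k > nrow(ranked)) {
    abort(sprintf("`k` (%d) exceeds the ranked list length (%d)", k, nrow(ranked)))
  }
  mean(ranked$node[seq_len(k)] %in% essential)
}

#' Pairwise overlap of top-k lists across methods
#'
#' For every pair of methods, the percentage of nodes shared by their top-k
#' lists: `100 * |top_k(A) intersect top_k(B)| / k`.
#'
#' @param lists Named list of ranked tibbles (one per method), each already
#'   cut to the same length `k`.
#' @param k The common list length; every element of `lists` must have exactly
#'   `k` rows.
#' @return A symmetric numeric matrix (percent), 100 on the diagonal, with
#'   method names as dimnames.
#' @export
overlap_matrix <- function(lists, k = 100) {
  if (length(lists) < 1L || is.null(names(lists))) {
    abort("`lists` must be a named list of ranked tibbles")
  }
  lens <- vapply(lists, nrow, integer(1))
  if (any(lens != k)) {
    abort(sprintf(
      "all lists must be cut at k = %d (got lengths: %s)",
      k, paste(lens, collapse = ", ")
    ))
  }
  tops <- lapply(lists, function(x) x$node)
  p <- length(tops)
  out <- matrix(100, p, p, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i < j) {
        out[i, j] <- out[j, i] <- 100 * length(intersect(tops[[i]], tops[[j]])) / k
      }
    }
  }
  out
}

#' Low-degree capture counts in top-k lists
#'
#' For each method and cut-off k, counts how many of the k top-ranked nodes
#' are low-degree, and how many of those are also essential — the "a | b"
#' cells of a low-degree capture table, which expose methods able to find
#' essential nodes that degree-based ranking misses.
#'
#' @param lists Named list of ranked tibbles (full rankings or top lists).
#' @param essential Character vector of essential node IDs.
#' @param partition A degree partition tibble from [partition_by_degree()].
#' @param ks Integer vector of cut-offs.
#' @return A tibble with columns `method`, `k`, `essential_low` and `low`.
#' @export
low_degree_table <- function(lists, essential, partition, ks) {
  if (is.null(names(lists))) abort("`lists` must be a named list")
  low_nodes <- partition$node[partition$degree_class == "low"]
  miss <- setdiff(unique(unlist(lapply(lists, `[[`, "node"))), partition$node)
  if (length(miss)) {
    abort("degree partition does not cover all ranked nodes")
  }
  grid <- tidyr::expand_grid(method = names(lists), k = as.integer(ks))
  counts <- purrr::pmap(grid, function(method, k) {
    top <- lists[[method]]$node[seq_len(min(k, nrow(lists[[method]])))]
    low <- intersect(top, low_nodes)
    tibble(essential_low = length(intersect(low, essential)), low = length(low))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(counts))
}

#' Run the full essentiality benchmark
#'
#' Scores every node with the requested methods, ranks each method, derives
#' the degree threshold and high/low partition, and assembles the benchmark
#' statistics: precision@k per method and cut-off, the pairwise top-k overlap
#' matrix, and the low-degree capture table.
#'
#' @param net A network (anything accepted by [as_hub_network()]).
#' @param essential Character vector of essential node IDs (labels absent from
#'   the network are dropped with a warning).
#' @param ks Precision cut-offs (default 10, 20, ..., 100; values beyond the
#'   node count are dropped).
#' @param overlap_k Cut-off for the overlap matrix (default 100, capped at the
#'   node count).
#' @param methods,epsilon,epc_threshold,epc_iterations,epc_seed,radiality_normalization
#'   Passed to [hub_score()].
#' @return An object of class `hub_benchmark`: a list with `scores`,
#'   `rankings` (named list of ranked tibbles), `threshold`, `partition`,
#'   `precision` (tibble `method`, `k`, `precision`), `overlap` (matrix),
#'   `low_degree` (tibble), `essential` (labels used) and `summary` counts.
#'   [tidy()], [glance()] and [ggplot2::autoplot()] methods are available.
#' @export
run_benchmark <- function(net, essential, ks = seq(10, 100, by = 10),
                          overlap_k = 100, methods = "all", epsilon = 1.7,
                          epc_threshold = 0.5, epc_iterations = 1000,
                          epc_seed = NULL,
                          radiality_normalization = c("eccentricity", "size")) {
  net <- as_hub_network(net)
  nodes <- network_nodes(net)
  essential <- unique(as.character(essential))
  outside <- setdiff(essential, nodes)
  if (length(outside)) {
    warn(sprintf(
      "%d essential label(s) not present in the network were ignored",
      length(outside)
    ))
    essential <- intersect(essential, nodes)
  }

  scores <- hub_score(net,
    methods = methods, epsilon = epsilon,
    epc_threshold = epc_threshold, epc_iterations = epc_iterations,
    epc_seed = epc_seed, radiality_normalization = radiality_normalization
  )
  used <- setdiff(names(scores), "node")
  rankings <- lapply(used, function(m) rank_nodes(scores, m))
  names(rankings) <- used

  t <- degree_threshold(net)
  partition <- partition_by_degree(net, t)

  ks <- as.integer(ks[ks >= 1 & ks <= length(nodes)])
  precision <- tidyr::expand_grid(method = used, k = ks)
  precision$precision <- purrr::pmap_dbl(precision, function(method, k) {
    precision_at_k(rankings[[method]], essential, k)
  })

  ok <- min(overlap_k, length(nodes))
  overlap <- overlap_matrix(lapply(rankings, top_k, k = ok), k = ok)

  low_degree <- low_degree_table(rankings, essential, partition, ks)

  high <- partition$node[partition$degree_class == "high"]
  low <- partition$node[partition$degree_class == "low"]
  summary <- tibble(
    n_nodes = length(nodes),
    n_edges = igraph::gsize(net),
    degree_threshold = t,
    n_essential = length(essential),
    n_high = length(high),
    n_low = length(low),
    essential_high = length(intersect(essential, high)),
    essential_low = length(intersect(essential, low))
  )

  structure(
    list(
      scores = scores, rankings = rankings, threshold = t,
      partition = partition, precision = precision, overlap = overlap,
      low_degree = low_degree, essential = essential, summary = summary,
      overlap_k = ok
    ),
    class = "hub_benchmark"
  )
}

#' @export
print.hub_benchmark <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<hub_benchmark: %d nodes, %d edges>\n",
      "  degree threshold %d (%d high / %d low); %d essential ",
      "(%d high, %d low)\n  methods: %s\n"
    ),
    s$n_nodes, s$n_edges, s$degree_threshold, s$n_high, s$n_low,
    s$n_essential, s$essential_high, s$essential_low,
    paste(names(x$rankings), collapse = ", ")
  ))
  invisible(x)
}

#' Tidy a benchmark report into a long precision table
#'
#' @param x A `hub_benchmark` object.
#' @param ... Unused.
#' @return A tibble with columns `method`, `k`, `precision`, `essential_low`,
#'   `low` (the low-degree capture counts at the same cut-off).
#' @method tidy hub_benchmark
#' @export
tidy.hub_benchmark <- function(x, ...) {
  dplyr::left_join(x$precision, x$low_degree, by = c("method", "k"))
}

#' One-row summary of a benchmark report
#'
#' @inheritParams tidy.hub_benchmark
#' @return A one-row tibble: node/edge counts, degree threshold, class sizes
#'   and essential counts per class.
#' @method glance hub_benchmark
#' @export
glance.hub_benchmark <- function(x, ...) {
  x$summary
}

#' Precision curves for a benchmark report
#'
#' @param object A `hub_benchmark` object.
#' @param ... Unused.
#' @return A ggplot of precision@k against k, one line per method.
#' @method autoplot hub_benchmark
#' @export
autoplot.hub_benchmark <- function(object, ...) {
  ggplot2::ggplot(
    object$precision,
    ggplot2::aes(x = .data$k, y = .data$precision, colour = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "top k", y = "precision@k", colour = "method",
      title = "Essential-node prediction precision by scoring method"
    ) +
    ggplot2::theme_minimal()
}

#' Write benchmark report files
#'
#' Emits the quantitative surface of a benchmark as TSV files plus a JSON
#' summary: `scores.tsv`, `precision.tsv` (wide, methods by k),
#' `overlap.tsv`, `low_degree.tsv` (cells formatted `essential_low | low`)
#' and `summary.json`.
#'
#' @param report A `hub_benchmark` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(report, dir) {
  if (!inherits(report, "hub_benchmark")) {
    abort("`report` must be a hub_benchmark object")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_scores(report$scores, file.path(dir, "scores.tsv"))

  wide <- tidyr::pivot_wider(
    report$precision,
    names_from = "k", values_from = "precision", names_prefix = "top_"
  )
  readr::write_tsv(wide, file.path(dir, "precision.tsv"), progress = FALSE)

  ov <- as.data.frame(report$overlap)
  ov <- dplyr::bind_cols(tibble(method = rownames(report$overlap)), ov)
  readr::write_tsv(ov, file.path(dir, "overlap.tsv"), progress = FALSE)

  ld <- report$low_degree
  ld$cell <- sprintf("%d | %d", ld$essential_low, ld$low)
  ldw <- tidyr::pivot_wider(
    ld[, c("method", "k", "cell")],
    names_from = "k", values_from = "cell", names_prefix = "top_"
  )
  readr::write_tsv(ldw, file.path(dir, "low_degree.tsv"), progress = FALSE)

  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      as.list(report$summary),
      file.path(dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
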