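#' Canonical scoring-method names
#'
#' The eleven methods in their canonical order, used for every multi-method
#' output: the four local methods first (Degree, MNC, DMNC, MCC), then the
#' seven global ones (Closeness, EcCentricity, Radiality, BottleNeck, Stress,
#' Betweenness, EPC).
#'
#' @return Character vector of length 11.
#' @export
hub_methods <- function() {
  c(
    "Degree", "MNC", "DMNC", "MCC",
    "Closeness", "EcCentricity", "Radiality", "BottleNeck",
    "Stress", "Betweenness", "EPC"
  )
}

method_aliases <- c(
  deg = "Degree", degree = "Degree",
  mnc = "MNC", dmnc = "DMNC", mcc = "MCC",
  clo = "Closeness", closeness = "Closeness",
  ec = "EcCentricity", eccentricity = "EcCentricity",
  rad = "Radiality", radiality = "Radiality",
  bn = "BottleNeck", bottleneck = "BottleNeck",
  str = "Stress", stress = "Stress",
  bc = "Betweenness", betweenness = "Betweenness",
  epc = "EPC"
)

# Resolve user-supplied method names ("all", canonical names, or the usual
# short aliases, case-insensitive) to canonical order.
match_methods <- function(methods) {
  if (length(methods) == 1L && tolower(methods) == "all") {
    return(hub_methods())
  }
  key <- tolower(methods)
  hit <- method_aliases[key]
  if (anyNA(hit)) {
    abort(paste0(
      "unknown method name(s): ", paste(methods[is.na(hit)], collapse = ", "),
      "; valid names are: ", paste(hub_methods(), collapse = ", ")
    ))
  }
  intersect(hub_methods(), unique(unname(hit)))
}

#' Score every node with the requested hub-ranking methods
#'
#' One-stop scoring: computes any subset of the eleven methods and returns a
#' tidy node-by-method table. Shortest-path machinery and the maximal-clique
#' enumeration are computed once and shared among the methods that need them.
#'
#' @param net A network (anything accepted by [as_hub_network()]).
#' @param methods `"all"` (default) or a character vector of method names
#'   (canonical names or common abbreviations such as `"Deg"`, `"BC"`).
#' @param epsilon DMNC exponent (default 1.7); see [score_dmnc()].
#' @param epc_threshold,epc_iterations,epc_seed Percolation settings for EPC;
#'   see [score_epc()].
#' @param radiality_normalization Passed to [score_radiality()].
#' @return A tibble with a `node` column (sorted by ID) and one numeric column
#'   per requested method, in canonical order.
#' @examples
#' g <- as_hub_network(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
#' hub_score(g, methods = c("Degree", "MCC"))
#' @export
hub_score <- function(net, methods = "all", epsilon = 1.7,
                      epc_threshold = 0.5, epc_iterations = 1000,
                      epc_seed = NULL,
                      radiality_normalization = c("eccentricity", "size")) {
  net <- as_hub_network(net)
  methods <- match_methods(methods)
  nodes <- network_nodes(net)

  needs_dist <- c("Closeness", "EcCentricity", "Radiality", "Stress", "Betweenness")
  dindex <- if (any(methods %in% needs_dist)) all_pairs_shortest(net) else NULL

  cols <- lapply(methods, function(m) {
    switch(m,
      Degree = score_degree(net),
      MNC = score_mnc(net),
      DMNC = score_dmnc(net, epsilon = epsilon),
      MCC = score_mcc(net),
      Closeness = score_closeness(net, dindex),
      EcCentricity = score_eccentricity(net, dindex),
      Radiality = score_radiality(net, dindex,
        normalization = radiality_normalization
      ),
      BottleNeck = score_bottleneck(net),
      Stress = score_stress(net, dindex),
      Betweenness = score_betweenness(net, dindex),
      EPC = score_epc(net,
        threshold = epc_threshold, iterations = epc_iterations,
        seed = epc_seed
      )
    )
  })
  names(cols) <- methods
  out <- tibble(node = nodes)
  for (m in methods) out[[m]] <- unname(cols[[m]][nodes])
  out
}
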