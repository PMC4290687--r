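#' Rank nodes by a scoring method
#'
#' Orders every node by score, best first. Ties are broken deterministically
#' by node ID (byte order, ascending). The `normalized_rank` column rescales
#' rank position to `[0, 1]` with 1 for the top node — the numeric counterpart
#' of a red-to-green essentiality colour ramp.
#'
#' @param scores A score table from [hub_score()] (columns `node` plus one per
#'   method), or any data frame with a `node` column and numeric method
#'   columns.
#' @param method Name of the method column to rank by (canonical name or
#'   alias).
#' @return A tibble with columns `node`, `score`, `rank` (1 = best) and
#'   `normalized_rank`, ordered best first.
#' @export
rank_nodes <- function(scores, method) {
  if (!is.data.frame(scores) || !"node" %in% names(scores)) {
    abort("`scores` must be a data frame with a `node` column")
  }
  method <- match_methods(method)
  if (length(method) != 1L) abort("`method` must name exactly one method")
  if (!method %in% names(scores)) {
    abort(paste0("method `", method, "` has not been computed in this table"))
  }
  s <- as.numeric(scores[[method]])
  if (any(!is.finite(s))) {
    warn(paste0("non-finite ", method, " scores present; they rank last"))
  }
  by_id <- order_ids(scores$node)
  ord <- by_id[order(-s[by_id])] # stable sort: ties stay in ID order
  n <- length(ord)
  tibble(
    node = scores$node[ord],
    score = s[ord],
    rank = seq_len(n),
    normalized_rank = if (n == 1L) 1 else (n - seq_len(n)) / (n - 1)
  )
}

#' Take the top k of a ranked list
#'
#' @param ranked A ranked tibble from [rank_nodes()].
#' @param k Number of nodes to keep (requests beyond the list length return
#'   the whole list).
#' @param include_ties If `TRUE`, nodes tied with the k-th score are kept even
#'   past position k.
#' @return The leading rows of `ranked`.
#' @export
top_k <- function(ranked, k, include_ties = FALSE) {
  if (!is.data.frame(ranked) || !all(c("node", "score") %in% names(ranked))) {
    abort("`ranked` must be a ranked list with `node` and `score` columns")
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    abort("`k` must be a single positive integer")
  }
  n <- nrow(ranked)
  k <- min(as.integer(k), n)
  if (include_ties && k < n) {
    cutoff <- ranked$score[k]
    while (k < n && ranked$score[k + 1L] == cutoff) k <- k + 1L
  }
  ranked[seq_len(k), , drop = FALSE]
}

#' Write a ranked list to TSV
#'
#' @param ranked A tibble from [rank_nodes()] or [top_k()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked <- function(ranked, path) {
  readr::write_tsv(ranked, path, progress = FALSE)
  invisible(path)
}
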