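# Brute-force oracles, independent of the package's BFS/Brandes-style code
# paths: Floyd-Warshall distances, explicit shortest-path enumeration, boolean
# transitive closure, exhaustive subset clique checks.

# Erdos-Renyi style random graph with named nodes; returns both the package
# network and the raw adjacency matrix the oracles work from.
rand_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  ut <- upper.tri(A)
  A[ut] <- stats::runif(sum(ut)) < p
  A <- A | t(A)
  el <- which(A & upper.tri(A), arr.ind = TRUE)
  df <- data.frame(
    from = c(nodes[el[, 1]], nodes[colSums(A) == 0]),
    to = c(nodes[el[, 2]], rep(NA_character_, sum(colSums(A) == 0)))
  )
  list(net = as_hub_network(df), A = A, nodes = nodes)
}

# graph from an explicit edge data frame (tiny fixtures built in code)
graph_of <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  as_hub_network(data.frame(from = e[, 1], to = e[, 2]))
}

# Floyd-Warshall all-pairs hop distances
oracle_dist <- function(A) {
  n <- nrow(A)
  D <- ifelse(A, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# component partition by boolean transitive closure
oracle_components <- function(A) {
  n <- nrow(A)
  R <- A | diag(n) > 0
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  memb <- apply(R, 1, function(r) rownames(A)[which(r)[1]])
  stats::setNames(memb, rownames(A))
}

# every shortest s-t path, as a list of index vectors (depth-bounded DFS)
oracle_enum_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (w in which(A[s, ])) {
    if (D[w, t] == D[s, t] - 1) {
      for (pp in oracle_enum_paths(A, D, w, t)) out <- c(out, list(c(s, pp)))
    }
  }
  out
}

# stress and betweenness for every node by explicit path enumeration over
# unordered within-component pairs
oracle_path_centralities <- function(A) {
  n <- nrow(A)
  D <- oracle_dist(A)
  stress <- btw <- stats::setNames(numeric(n), rownames(A))
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(D[s, t])) next
      paths <- oracle_enum_paths(A, D, s, t)
      sigma <- length(paths)
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior)) {
        cnt <- table(interior)
        idx <- as.integer(names(cnt))
        stress[idx] <- stress[idx] + as.numeric(cnt)
        btw[idx] <- btw[idx] + as.numeric(cnt) / sigma
      }
    }
  }
  list(stress = stress, betweenness = btw, dist = D, sigma_check = NULL)
}

# shortest-path counts between all pairs via enumeration
oracle_sigma <- function(A) {
  n <- nrow(A)
  D <- oracle_dist(A)
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (is.finite(D[s, t])) {
        S[s, t] <- length(oracle_enum_paths(A, D, s, t))
      }
    }
  }
  S
}

oracle_closeness <- function(A) {
  D <- oracle_dist(A)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv, na.rm = FALSE)
}

oracle_eccentricity <- function(A) {
  D <- oracle_dist(A)
  n <- nrow(A)
  memb <- oracle_components(A)
  csize <- table(memb)
  out <- vapply(seq_len(n), function(v) {
    row <- D[v, setdiff(which(memb == memb[v]), v)]
    if (length(row) == 0) return(0)
    (as.numeric(csize[[memb[v]]]) / n) / max(row)
  }, numeric(1))
  stats::setNames(out, rownames(A))
}

oracle_radiality <- function(A) {
  D <- oracle_dist(A)
  n <- nrow(A)
  memb <- oracle_components(A)
  csize <- table(memb)
  out <- vapply(seq_len(n), function(v) {
    others <- setdiff(which(memb == memb[v]), v)
    if (length(others) == 0) return(0)
    inside <- which(memb == memb[v])
    delta <- max(D[inside, inside])
    (as.numeric(csize[[memb[v]]]) / n) *
      sum(delta + 1 - D[v, others]) / max(D[v, others])
  }, numeric(1))
  stats::setNames(out, rownames(A))
}

# BottleNeck from first principles: parents from the Floyd-Warshall distance
# field (smallest-ID neighbour one step closer to the root), then count, for
# every node v, how many root-to-w paths contain v by walking parent chains.
oracle_bottleneck <- function(A) {
  n <- nrow(A)
  D <- oracle_dist(A)
  score <- stats::setNames(numeric(n), rownames(A))
  for (s in seq_len(n)) {
    members <- which(is.finite(D[s, ]))
    parent <- rep(NA_integer_, n)
    for (w in setdiff(members, s)) {
      cand <- which(A[w, ] & D[s, ] == D[s, w] - 1)
      parent[w] <- min(cand)
    }
    cnt <- stats::setNames(numeric(n), rownames(A))
    for (w in members) {
      v <- w
      repeat {
        cnt[v] <- cnt[v] + 1
        if (v == s) break
        v <- parent[v]
      }
    }
    hit <- members[cnt[members] > length(members) / 4]
    score[hit] <- score[hit] + 1
  }
  score
}

# exhaustive-subset maximal clique enumeration (bitmask over all vertex
# subsets; n <= 20 or so)
oracle_max_cliques <- function(A) {
  n <- nrow(A)
  subsets <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2) next
    pairs_ok <- all(A[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
    if (!pairs_ok) next
    outside <- setdiff(seq_len(n), idx)
    maximal <- !any(vapply(outside, function(o) all(A[o, idx]), logical(1)))
    if (maximal) subsets <- c(subsets, list(sort(rownames(A)[idx])))
  }
  subsets
}

oracle_mcc <- function(A) {
  cl <- oracle_max_cliques(A)
  score <- stats::setNames(numeric(nrow(A)), rownames(A))
  for (s in cl) score[s] <- score[s] + factorial(length(s) - 1)
  score
}

# MNC / DMNC by brute-force component extraction on the induced neighbourhood
# (transitive closure), with the lexicographic tie-break on tied components
oracle_mnc_dmnc <- function(A, epsilon = 1.7) {
  n <- nrow(A)
  mnc <- dmnc <- stats::setNames(numeric(n), rownames(A))
  for (v in seq_len(n)) {
    nb <- which(A[v, ])
    if (length(nb) == 0) next
    sub <- A[nb, nb, drop = FALSE]
    rownames(sub) <- colnames(sub) <- rownames(A)[nb]
    memb <- oracle_components(sub)
    parts <- split(names(memb), memb)
    parts <- lapply(parts, sort)
    sizes <- lengths(parts)
    best <- parts[sizes == max(sizes)]
    keys <- vapply(best, paste, character(1), collapse = "\r")
    pick <- best[[order(keys, method = "radix")[1]]]
    mnc[v] <- length(pick)
    edges <- sum(sub[pick, pick]) / 2
    dmnc[v] <- if (length(pick) < 2) 0 else edges / length(pick)^epsilon
  }
  list(mnc = mnc, dmnc = dmnc)
}

# named-vector comparison helper
expect_scores_equal <- function(got, want, tol = 1e-9) {
  expect_equal(got[sort(names(got), method = "radix")],
               want[sort(names(want), method = "radix")],
               tolerance = tol)
}
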