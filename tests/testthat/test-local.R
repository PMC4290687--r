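k4 <- graph_of("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d")
star4 <- graph_of("c0", "l1", "c0", "l2", "c0", "l3", "c0", "l4")
with_iso <- as_hub_network(data.frame(from = c("a", "iso"), to = c("b", NA)))

test_that("degree scores count neighbours (star, K4, isolated node)", {
  expect_equal(score_degree(star4)[["c0"]], 4)
  expect_equal(unname(score_degree(k4)), rep(3, 4))
  expect_equal(score_degree(with_iso)[["iso"]], 0)
})

test_that("maximum neighbourhood component matches hand cases and the oracle", {
  mc <- max_neighborhood_component(k4, "a")
  expect_equal(mc$vertices, c("b", "c", "d"))
  expect_equal(mc$edge_count, 3)

  mc_star <- max_neighborhood_component(star4, "c0")
  expect_equal(length(mc_star$vertices), 1)
  expect_equal(mc_star$edge_count, 0)
  expect_equal(mc_star$vertices, "l1") # lexicographic tie-break

  expect_equal(max_neighborhood_component(with_iso, "iso")$vertices, character(0))
  expect_error(max_neighborhood_component(k4, "zz"), "unknown node")

  for (seed in 1:6) {
    rg <- rand_graph(20, 0.3, seed)
    want <- oracle_mnc_dmnc(rg$A)
    expect_scores_equal(score_mnc(rg$net), want$mnc)
    expect_scores_equal(score_dmnc(rg$net), want$dmnc)
  }
})

test_that("MNC and DMNC formulas evaluate exactly on closed-form cases", {
  expect_equal(score_mnc(k4)[["a"]], 3)
  expect_equal(score_mnc(star4)[["c0"]], 1)
  expect_equal(score_mnc(with_iso)[["iso"]], 0)

  expect_equal(score_dmnc(k4)[["a"]], 3 / 3^1.7, tolerance = 1e-9)
  expect_equal(score_dmnc(star4)[["c0"]], 0)
  # MC(v) a 4-path: neighbourhood of "v" is a path l1-l2-l3-l4
  g <- graph_of(
    "v", "l1", "v", "l2", "v", "l3", "v", "l4",
    "l1", "l2", "l2", "l3", "l3", "l4"
  )
  expect_equal(score_dmnc(g)[["v"]], 3 / 4^1.7, tolerance = 1e-9)
  expect_error(score_dmnc(k4, epsilon = -1), "positive")
})

test_that("maximal clique enumeration matches the exhaustive-subset oracle", {
  expect_equal(enumerate_maximal_cliques(k4), list(c("a", "b", "c", "d")))
  expect_equal(
    enumerate_maximal_cliques(star4),
    list(c("c0", "l1"), c("c0", "l2"), c("c0", "l3"), c("c0", "l4"))
  )
  for (seed in 1:6) {
    rg <- rand_graph(12, 0.4, seed)
    got <- enumerate_maximal_cliques(rg$net)
    want <- oracle_max_cliques(rg$A)
    key <- function(x) sort(vapply(x, paste, character(1), collapse = "|"))
    expect_equal(key(got), key(want))
  }
})

test_that("MCC sums factorials over maximal cliques, with the degree fallback", {
  expect_equal(score_mcc(k4)[["a"]], 6) # (4-1)!
  expect_equal(score_mcc(star4)[["c0"]], 4) # edgeless neighbourhood -> degree
  expect_equal(score_mcc(with_iso)[["iso"]], 0)
  # two edge-disjoint triangles sharing only v
  bowtie <- graph_of("v", "a", "v", "b", "a", "b", "v", "x", "v", "y", "x", "y")
  expect_equal(score_mcc(bowtie)[["v"]], 4) # 2 * (3-1)!
  expect_error(
    score_mcc(k4, cliques = list(c("a", "ghost"))),
    "inconsistent"
  )
})

test_that("local-method invariants hold on random graphs", {
  for (seed in 1:10) {
    rg <- rand_graph(15, 0.25, seed)
    deg <- score_degree(rg$net)
    mcc <- score_mcc(rg$net)
    mnc <- score_mnc(rg$net)
    dmnc <- score_dmnc(rg$net)
    pos <- deg > 0
    expect_true(all(mcc[pos] >= deg[pos]))
    expect_true(all(mnc <= deg))
    mc_edgeless <- vapply(rg$nodes, function(v) {
      max_neighborhood_component(rg$net, v)$edge_count == 0
    }, logical(1))
    expect_equal(dmnc == 0, mc_edgeless, ignore_attr = TRUE)
  }
  # triangle-free graph: every maximal clique is an edge, so MCC = degree
  tree <- graph_of("a", "b", "b", "c", "b", "d", "d", "e", "a", "f")
  expect_equal(score_mcc(tree), score_degree(tree))
})

test_that("local scores are invariant under node relabeling", {
  rg <- rand_graph(14, 0.3, 5)
  relabel <- stats::setNames(sprintf("Z%02d", sample(14)), rg$nodes)
  el <- igraph::as_edgelist(rg$net)
  iso <- names(which(igraph::degree(rg$net) == 0))
  g2 <- as_hub_network(data.frame(
    from = c(relabel[el[, 1]], relabel[iso]),
    to = c(relabel[el[, 2]], rep(NA, length(iso)))
  ))
  for (f in list(score_degree, score_mnc, score_dmnc, score_mcc)) {
    s1 <- f(rg$net)
    s2 <- f(g2)
    expect_equal(unname(s2[relabel[names(s1)]]), unname(s1))
  }
})
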