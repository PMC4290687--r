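test_that("degree threshold satisfies its defining inequality, maximally", {
  # degree multiset {3,3,1,1,1,1}: two adjacent centres with two leaves each
  g <- graph_of("a", "b", "a", "x1", "a", "x2", "b", "y1", "b", "y2")
  expect_equal(degree_threshold(g), 2)
  expect_equal(degree_threshold(graph_of("a", "b")), 0)
  iso_only <- as_hub_network(data.frame(from = c("a", "b"), to = c(NA, NA)))
  expect_error(degree_threshold(iso_only), "edgeless")

  for (seed in 1:6) {
    rg <- rand_graph(25, 0.15, seed)
    deg <- score_degree(rg$net)
    total <- sum(deg)
    t <- degree_threshold(rg$net)
    expect_true(2 * sum(deg[deg > t]) > total)
    expect_false(2 * sum(deg[deg > t + 1]) > total)
  }
})

test_that("degree partition splits at strictly-greater-than-threshold", {
  star <- graph_of("c", "l1", "c", "l2", "c", "l3", "c", "l4")
  p <- partition_by_degree(star, 1)
  expect_equal(p$degree_class[p$node == "c"], "high")
  expect_equal(sum(p$degree_class == "low"), 4)
  p_all_low <- partition_by_degree(star, 4)
  expect_true(all(p_all_low$degree_class == "low"))
  expect_error(partition_by_degree(star, -1), "non-negative")
})

test_that("precision@k is the essential fraction of the top k", {
  ranked <- tibble::tibble(node = sprintf("n%02d", 1:10), score = 10:1)
  expect_equal(precision_at_k(ranked, sprintf("n%02d", 1:9), 10), 0.9)
  expect_equal(precision_at_k(ranked, character(0), 5), 0)
  expect_equal(precision_at_k(ranked, ranked$node, 10), 1)
  expect_error(precision_at_k(ranked, "n01", 11), "exceeds")
})

test_that("overlap matrix is symmetric percent sharing with 100 diagonal", {
  l1 <- tibble::tibble(node = sprintf("a%02d", 1:10), score = 10:1)
  l2 <- tibble::tibble(node = sprintf("b%02d", 1:10), score = 10:1)
  l3 <- l1
  m <- overlap_matrix(list(A = l1, B = l2, C = l3), k = 10)
  expect_equal(m["A", "B"], 0)
  expect_equal(m["A", "C"], 100)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))

  shared <- tibble::tibble(node = c(sprintf("a%02d", 1:3), sprintf("c%02d", 1:7)),
                           score = 10:1)
  m2 <- overlap_matrix(list(A = l1, S = shared), k = 10)
  expect_equal(m2["A", "S"], 30)
  expect_error(overlap_matrix(list(A = l1, B = l2[1:5, ]), k = 10), "cut at k")
})

test_that("low-degree capture counts match an exhaustive recount", {
  fx <- generate_fixture(
    n_background = 60, clique_sizes = c(5, 5),
    background_edge_prob = 0.05, essential_fraction = 1,
    background_rate = 0.1, seed = 31
  )
  scores <- hub_score(fx$network, methods = c("Degree", "MCC"), epc_seed = 1)
  lists <- list(
    Degree = rank_nodes(scores, "Degree"),
    MCC = rank_nodes(scores, "MCC")
  )
  part <- partition_by_degree(fx$network, degree_threshold(fx$network))
  tbl <- low_degree_table(lists, fx$essential, part, ks = c(10, 20))
  low_set <- part$node[part$degree_class == "low"]
  for (i in seq_len(nrow(tbl))) {
    top <- lists[[tbl$method[i]]]$node[seq_len(tbl$k[i])]
    expect_equal(tbl$low[i], length(intersect(top, low_set)))
    expect_equal(
      tbl$essential_low[i],
      length(intersect(intersect(top, low_set), fx$essential))
    )
    expect_lte(tbl$essential_low[i], tbl$low[i])
    expect_lte(tbl$low[i], tbl$k[i])
  }
  expect_error(
    low_degree_table(lists, fx$essential, part[-1, ], ks = 10),
    "cover"
  )
})

test_that("fixture generator plants cliques, wires background, labels nodes", {
  k5 <- generate_fixture(
    n_background = 0, clique_sizes = 5,
    background_edge_prob = 0, essential_fraction = 1, seed = 1
  )
  expect_equal(igraph::vcount(k5$network), 5)
  expect_equal(igraph::gsize(k5$network), 10)
  expect_equal(length(k5$essential), 5)

  frozen <- generate_fixture(
    n_background = 20, clique_sizes = c(4, 4),
    background_edge_prob = 0, essential_fraction = 1,
    background_rate = 0, seed = 2
  )
  comp <- network_components(frozen$network)
  sizes <- table(comp$component_size)
  expect_equal(unname(sizes[["1"]]), 20) # isolated background
  expect_equal(unname(sizes[["4"]]), 8) # two intact 4-cliques
  expect_setequal(frozen$essential, frozen$labels$node[frozen$labels$planted])

  # realized random edge count within 3 binomial standard deviations
  fx <- generate_fixture(
    n_background = 200, clique_sizes = c(6, 6, 6),
    background_edge_prob = 0.02, essential_fraction = 0.9,
    background_rate = 0.05, seed = 7
  )
  n_pairs <- choose(200, 2) + 18 * 200
  expected <- 45 + n_pairs * 0.02
  sdev <- sqrt(n_pairs * 0.02 * 0.98)
  expect_lt(abs(igraph::gsize(fx$network) - expected), 3 * sdev)

  expect_identical(
    igraph::as_edgelist(generate_fixture(seed = 5)$network),
    igraph::as_edgelist(generate_fixture(seed = 5)$network)
  )
  expect_error(generate_fixture(clique_sizes = 2), "at least 3")
})

test_that("the full benchmark emits coherent tables and plays with tidy/glance", {
  fx <- generate_fixture(
    n_background = 80, clique_sizes = c(6, 6),
    background_edge_prob = 0.03, essential_fraction = 0.9,
    background_rate = 0.05, seed = 17
  )
  rep <- suppressWarnings(run_benchmark(
    fx$network, fx$essential,
    ks = c(5, 10, 20), overlap_k = 20,
    epc_iterations = 100, epc_seed = 1
  ))
  expect_s3_class(rep, "hub_benchmark")
  expect_equal(sort(names(rep$rankings)), sort(hub_methods()))
  expect_equal(nrow(rep$precision), 11 * 3)
  expect_true(all(rep$precision$precision >= 0 & rep$precision$precision <= 1))
  expect_equal(rep$overlap, t(rep$overlap))
  expect_equal(dim(rep$overlap), c(11, 11))

  td <- tidy(rep)
  expect_true(all(c("method", "k", "precision", "essential_low", "low") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_high + gl$n_low, gl$n_nodes)
  expect_equal(gl$essential_high + gl$essential_low, gl$n_essential)
  plt <- ggplot2::autoplot(rep)
  expect_s3_class(plt, "ggplot")

  # empty essential set: all precision 0
  rep0 <- run_benchmark(fx$network, character(0),
    ks = 10, overlap_k = 10,
    methods = c("Degree", "MNC"), epc_seed = 1
  )
  expect_true(all(rep0$precision$precision == 0))

  # labels outside the network are ignored with a warning
  expect_warning(
    run_benchmark(fx$network, c(fx$essential, "ghost1"),
      ks = 10, overlap_k = 10, methods = "Degree"
    ),
    "ignored"
  )
})

test_that("benchmark report files land on disk in the documented shapes", {
  fx <- generate_fixture(
    n_background = 40, clique_sizes = 5, background_edge_prob = 0.05,
    essential_fraction = 1, background_rate = 0, seed = 3
  )
  rep <- run_benchmark(fx$network, fx$essential,
    ks = c(5, 10), overlap_k = 10,
    epc_iterations = 50, epc_seed = 1
  )
  dir <- withr::local_tempdir()
  write_benchmark(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("scores.tsv", "precision.tsv", "overlap.tsv", "low_degree.tsv",
           "summary.json")
  ))))
  prec <- readr::read_tsv(file.path(dir, "precision.tsv"), show_col_types = FALSE)
  expect_equal(names(prec), c("method", "top_5", "top_10"))
  expect_equal(nrow(prec), 11)
  ld <- readr::read_tsv(file.path(dir, "low_degree.tsv"), show_col_types = FALSE)
  expect_true(all(grepl("^\\d+ \\| \\d+$", ld$top_5)))
})
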