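test_that("edge-list loading dedupes, drops self-loops, keeps components", {
  f <- withr::local_tempfile(lines = c("# comment", "A\tB", "B\tC", "A\tB"))
  g <- suppressMessages(load_edge_list(f))
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)

  f2 <- withr::local_tempfile(lines = c("A\tA", "A\tB"))
  g2 <- suppressMessages(load_edge_list(f2))
  expect_equal(igraph::ecount(g2), 1)
  expect_true("A" %in% igraph::V(g2)$name)

  f3 <- withr::local_tempfile(lines = c("A\tB", "C\tD"))
  g3 <- load_edge_list(f3)
  expect_equal(igraph::vcount(g3), 4)
  expect_equal(igraph::components(g3)$no, 2)
})

test_that("edge-list loading rejects empty and malformed files", {
  f <- withr::local_tempfile(lines = c("# only a comment"))
  expect_error(load_edge_list(f), "no data rows")
  f2 <- withr::local_tempfile(lines = c("A\tB", "oops"))
  expect_error(load_edge_list(f2), "line 2")
  f3 <- withr::local_tempfile(lines = c("A\tA"))
  expect_error(suppressMessages(load_edge_list(f3)), "no valid edges")
})

test_that("degree sum equals twice the edge count", {
  g <- random_graph(25, seed = 7)
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
})

test_that("LCC matches hand-enumerated components and tie rule", {
  g <- path_graph()
  expect_equal(suppressWarnings(
    largest_connected_component(g, c("A", "B", "D"))), c("A", "B"))

  tri <- two_component_graph()
  expect_equal(largest_connected_component(tri, c("A", "B", "C")),
               c("A", "B", "C"))

  # isolated singletons: lexicographic tie-break
  iso <- graph_from_edges("A","Z", "B","Z", "C","Z")
  expect_equal(largest_connected_component(iso, c("C", "B", "A")), "A")

  expect_equal(largest_connected_component(g, character(0)), character(0))
})

test_that("LCC is connected and maximal on random graphs (brute force)", {
  for (seed in 1:5) {
    g <- random_graph(15, p = 0.12, seed = seed)
    set.seed(seed + 100)
    genes <- sample(igraph::V(g)$name, 8)
    lcc <- largest_connected_component(g, genes)
    edges <- igraph::as_edgelist(g)
    comps <- brute_components(edges[edges[, 1] %in% genes &
                                      edges[, 2] %in% genes, ,
                                    drop = FALSE], genes)
    expect_equal(length(lcc), max(lengths(comps)))
    expect_true(any(vapply(comps, function(cc) setequal(cc, lcc),
                           logical(1))))
  }
})

test_that("multi-source BFS distances match a Floyd-Warshall oracle", {
  for (seed in 1:4) {
    g <- random_graph(12, p = 0.2, seed = seed)
    nodes <- igraph::V(g)$name
    oracle <- brute_distances(igraph::as_edgelist(g), nodes)
    set.seed(seed)
    sources <- sample(nodes, 3)
    d <- shortest_path_lengths(g, sources)
    expect_equal(d[nodes],
                 apply(oracle[sources, nodes, drop = FALSE], 2, min))
  }
  g <- two_component_graph()
  d <- shortest_path_lengths(g, "A")
  expect_equal(unname(d["A"]), 0)
  expect_equal(unname(d["B"]), 1)
  expect_equal(unname(d["X"]), Inf)
  expect_error(shortest_path_lengths(g, "nope"), "not in graph")
})

test_that("degree-matched sampling preserves the binned-degree histogram", {
  g <- random_graph(30, p = 0.2, seed = 3)
  binning <- degree_binning(g)
  set.seed(11)
  genes <- sample(names(binning$bin_of), 12)
  out <- degree_matched_sample(g, genes, binning)
  expect_length(out, length(genes))
  expect_false(anyDuplicated(out) > 0)
  expect_equal(table(binning$bin_of[out]), table(binning$bin_of[genes]))

  # whole-universe request returns the whole universe
  all_genes <- names(binning$bin_of)
  expect_setequal(degree_matched_sample(g, all_genes, binning), all_genes)

  set.seed(5)
  a <- degree_matched_sample(g, genes, binning)
  set.seed(5)
  b <- degree_matched_sample(g, genes, binning)
  expect_identical(a, b)
})

test_that("degree-matched sampling covers every bin member over many draws", {
  g <- random_graph(30, p = 0.2, seed = 3)
  binning <- degree_binning(g)
  bin_id <- names(which.max(lengths(binning$members)))
  members <- binning$members[[bin_id]]
  probe <- members[1]
  set.seed(21)
  draws <- replicate(400, degree_matched_sample(g, probe, binning))
  counts <- table(factor(draws, levels = members))
  expect_true(all(counts > 0))
  # uniformity sanity: chi-square not wildly off
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("sampling errors are informative", {
  g <- random_graph(30, p = 0.2, seed = 3)
  binning <- degree_binning(g)
  smallest <- names(which.min(lengths(binning$members)))
  members <- binning$members[[smallest]]
  over <- rep(members[1], length(members) + 1)
  expect_error(degree_matched_sample(g, over, binning), "coarser")
  expect_error(degree_matched_sample(g, "absent", binning),
               "sampling universe")
})

test_that("graph summary JSON records counts and degree histogram", {
  g <- path_graph()
  f <- withr::local_tempfile(fileext = ".json")
  write_graph_summary(g, f)
  got <- jsonlite::read_json(f)
  expect_equal(got$nodes, 4)
  expect_equal(got$edges, 3)
  expect_equal(got$degree_histogram$`1`, 2)
  expect_equal(got$degree_histogram$`2`, 2)
})
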