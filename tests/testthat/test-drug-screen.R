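test_that("amplitude matches its defining identities", {
  expect_equal(amplitude(2, 1), 2 / 3, tolerance = 1e-12)
  expect_identical(amplitude(1, 1), 0)
  expect_equal(amplitude(1, 2), -2 / 3, tolerance = 1e-12)
  set.seed(14)
  t <- stats::runif(50, 0.1, 5)
  c <- stats::runif(50, 0.1, 5)
  expect_equal(amplitude(t, c), -amplitude(c, t), tolerance = 1e-12)
  expect_error(amplitude(1, -1), "undefined")
})

test_that("signature construction applies strict thresholds", {
  a <- c(g1 = 0.67, g2 = 0.8, g3 = -0.8, g4 = 0.1, g5 = -0.67)
  sig <- build_signature(a)
  expect_equal(sig$up, "g2")
  expect_equal(sig$down, "g3")
  empty <- build_signature(stats::setNames(numeric(0), character(0)))
  expect_length(empty$up, 0)
  expect_error(drug_signature(c("a", "b"), c("b", "c")), "overlap")
})

test_that("closest distance reproduces hand-computed BFS values", {
  g <- path_graph()
  expect_equal(as.numeric(closest_distance(g, c("A", "B"), "B")), 0)
  expect_equal(as.numeric(closest_distance(g, "A", "B")), 1)
  # S = {A}, T = {C, D}: (2 + 3) / 2
  expect_equal(as.numeric(closest_distance(g, "A", c("C", "D"))), 2.5)
  g2 <- two_component_graph()
  expect_error(closest_distance(g2, "A", "X"), "reachable")
  d <- closest_distance(g2, "A", c("B", "X"))
  expect_equal(as.numeric(d), 1)
  expect_equal(attr(d, "n_reachable"), 1)
  expect_equal(attr(d, "n_targets"), 2)
})

test_that("adding module genes never increases the closest distance", {
  g <- random_graph(40, p = 0.12, seed = 20)
  nodes <- igraph::V(g)$name
  set.seed(21)
  for (i in 1:20) {
    s <- sample(nodes, 5)
    t <- sample(nodes, 4)
    extra <- sample(setdiff(nodes, s), 3)
    d1 <- tryCatch(as.numeric(closest_distance(g, s, t)),
                   error = function(e) NA)
    d2 <- tryCatch(as.numeric(closest_distance(g, c(s, extra), t)),
                   error = function(e) NA)
    if (!is.na(d1) && !is.na(d2)) expect_lte(d2, d1)
  }
})

test_that("proximity z is reproducible and detects planted proximity", {
  st <- generate_study(seed = 5, n_genes = 300L, planted_size = 15L,
                       n_drugs = 4L, n_proximal = 2L, n_concordant = 1L)
  binning <- degree_binning(st$graph)
  prox_drug <- st$drugs[[1]]
  set.seed(8)
  res <- proximity_z(st$graph, st$planted, prox_drug$targets, binning,
                     n_perm = 200)
  set.seed(8)
  res2 <- proximity_z(st$graph, st$planted, prox_drug$targets, binning,
                      n_perm = 200)
  expect_identical(res$z_score, res2$z_score)
  expect_identical(res$p_value, res2$p_value)
  expect_lt(res$z_score, 0)
  expect_identical(res$distance, as.numeric(
    closest_distance(st$graph, st$planted, prox_drug$targets)))
})

test_that("signature test matches exhaustive draw enumeration on a small
          background", {
  background <- sprintf("g%02d", 1:20)
  module <- background[1:6]
  sig <- drug_signature(up = background[c(1, 2, 3, 10)],
                        down = background[c(4, 11)], drug = "d")
  res <- signature_module_test(module, sig, background)
  expect_equal(sum(res$contingency), 20)
  # enumeration oracle: all C(20, 6) module placements, regulated set fixed
  reg <- union(sig$up, sig$down)
  combos <- utils::combn(20, 6)
  overlaps <- colSums(matrix(background[combos] %in% reg, nrow = 6))
  obs <- length(intersect(module, reg))
  expect_equal(res$p_value, mean(overlaps >= obs), tolerance = 1e-12)

  # degenerate cases
  all_reg <- drug_signature(up = background, down = character(0))
  expect_equal(signature_module_test(module, all_reg, background)$p_value,
               1)
  none <- drug_signature(character(0), character(0))
  expect_equal(signature_module_test(module, none, background)$p_value, 1)
})

test_that("the repurposing screen ranks a planted proximal and concordant
          drug first and is deterministic", {
  st <- generate_study(seed = 9, n_genes = 300L, planted_size = 15L,
                       n_drugs = 8L, n_proximal = 1L, n_concordant = 1L)
  set.seed(30)
  tab <- repurpose_screen(st$drugs, st$planted, st$graph, n_perm = 200)
  expect_equal(tab$drug[1], st$truth$proximal_drugs[1])
  expect_true(tab$significant[1])
  set.seed(30)
  tab2 <- repurpose_screen(st$drugs, st$planted, st$graph, n_perm = 200)
  expect_identical(tab, tab2)
  # single-drug panel: adjusted p equals raw p
  set.seed(31)
  one <- repurpose_screen(st$drugs[1], st$planted, st$graph, n_perm = 200)
  expect_equal(one$adj_p_proximity, one$proximity_p)
})

test_that("GMT signatures round-trip through files", {
  sets <- list(d1_UP = c("a", "b"), d1_DOWN = c("c"),
               d2_UP = c("x", "y", "z"), d2_DOWN = c("q"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  sigs <- read_signature_gmt(f)
  expect_setequal(names(sigs), c("d1", "d2"))
  expect_equal(sigs$d1$up, c("a", "b"))
  expect_equal(sigs$d2$down, "q")
  expect_equal(read_gmt(f)$d2_UP, c("x", "y", "z"))
})
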