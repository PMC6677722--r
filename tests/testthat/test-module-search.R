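# Shared fixture: a scored random graph with a co-expression network built
# from block-correlated expression.
make_search_fixture <- function(seed = 1) {
  st <- generate_study(seed = seed, n_genes = 400L, mean_degree = 6,
                       planted_size = 15L, n_samples = 60L,
                       n_drugs = 4L, n_proximal = 1L, n_concordant = 1L)
  universe <- igraph::V(st$graph)$name
  s0 <- initial_scores(st$profile, universe)
  scores <- rwr_smooth(st$graph, s0)
  mu <- mean_score(scores, universe)
  net <- build_coexpressed_network(st$graph, st$expr)
  list(study = st, scores = scores, mu = mu, net = net)
}

test_that("module score follows the mean-centred sum over sqrt(m)", {
  scores <- c(a = 1, b = 2, c = 1)
  expect_equal(module_score("a", scores, mu = 1), 0)
  expect_equal(module_score("b", scores, mu = 1), 1)
  expect_equal(module_score(c("b", "b2"), c(b = 2, b2 = 2), mu = 1),
               2 / sqrt(2))
  expect_error(module_score(character(0), scores, 1), "empty")
  expect_error(module_score("zz", scores, 1), "unscored")
})

test_that("connectivity significance agrees with exact combinatorics", {
  # k_m = 0 collapses to the full sum
  expect_identical(connectivity_significance(50, 10, 5, 0), 1)
  # all three neighbours inside a 3-gene module: one subset out of C(10,3)
  expect_equal(connectivity_significance(10, 3, 3, 3), 1 / choose(10, 3),
               tolerance = 1e-12)
  expect_error(connectivity_significance(10, 10, 3, 1), "m < N")
  expect_error(connectivity_significance(10, 3, 10, 1), "k_i")
  expect_error(connectivity_significance(10, 3, 3, 4), "k_m")
})

test_that("connectivity significance matches subset enumeration on small
          networks", {
  for (N in c(7, 9)) {
    for (m in c(2, 4)) {
      for (k_i in c(2, 4, N - 1)) {
        subsets <- utils::combn(N, k_i)
        inside <- colSums(subsets <= m)
        for (k_m in 0:min(k_i, m)) {
          expect_equal(connectivity_significance(N, m, k_i, k_m),
                       mean(inside >= k_m), tolerance = 1e-12,
                       label = sprintf("N=%d m=%d ki=%d km=%d",
                                       N, m, k_i, k_m))
        }
      }
    }
  }
})

test_that("expanded score equals the recomputed score on the union", {
  fx <- make_search_fixture(2)
  nodes <- igraph::V(fx$study$graph)$name
  set.seed(77)
  for (i in 1:50) {
    genes <- sample(nodes, sample(2:10, 1))
    mod <- structure(list(genes = genes[-1], seed = genes[2],
                          size = length(genes) - 1L,
                          sum_excess = sum(fx$scores[genes[-1]] - fx$mu),
                          score = module_score(genes[-1], fx$scores,
                                               fx$mu)),
                     class = "gps_module")
    expect_equal(expanded_score(mod, genes[1], fx$scores, fx$mu),
                 module_score(genes, fx$scores, fx$mu),
                 tolerance = 1e-12)
  }
})

test_that("a candidate at the mean strictly lowers a positive module score", {
  scores <- c(a = 2, b = 1)
  mod <- structure(list(genes = "a", seed = "a", size = 1L,
                        sum_excess = 1, score = 1), class = "gps_module")
  expect_lt(expanded_score(mod, "b", scores, mu = 1), mod$score)
  expect_error(expanded_score(mod, "a", scores, mu = 1), "already")
})

test_that("growth is deterministic, score-monotone and recovers planted
          genes from an inside seed", {
  fx <- make_search_fixture(3)
  planted <- fx$study$planted
  seed_gene <- planted[1]
  mod <- grow_module(seed_gene, fx$net, fx$scores, fx$mu,
                     interactome = fx$study$graph)
  mod2 <- grow_module(seed_gene, fx$net, fx$scores, fx$mu,
                      interactome = fx$study$graph)
  expect_identical(mod$genes, mod2$genes)

  # score identity at the end of growth
  expect_equal(mod$score, module_score(mod$genes, fx$scores, fx$mu),
               tolerance = 1e-12)
  # strict monotonicity along the admission order
  zs <- vapply(seq_along(mod$genes), function(k) {
    module_score(mod$genes[seq_len(k)], fx$scores, fx$mu)
  }, numeric(1))
  if (length(zs) > 1) expect_true(all(diff(zs) > 0))
  expect_gte(mean(planted %in% mod$genes), 0.8)
})

test_that("every admitted gene is connected to the module in the
          co-expressed network", {
  fx <- make_search_fixture(4)
  # grow from the first planted seed whose module actually expands
  for (seed_gene in fx$study$planted) {
    mod <- grow_module(seed_gene, fx$net, fx$scores, fx$mu,
                       interactome = fx$study$graph)
    if (mod$size > 1) break
  }
  expect_gt(mod$size, 1)
  expect_setequal(largest_connected_component(fx$net, mod$genes),
                  sort(mod$genes))
})

test_that("candidate eligibility reports failed criteria", {
  fx <- make_search_fixture(5)
  g <- fx$study$graph
  mod <- grow_module(fx$study$planted[1], fx$net, fx$scores, fx$mu,
                     interactome = g)
  frontier <- setdiff(unique(unlist(lapply(
    mod$genes, function(x) igraph::neighbors(g, x)$name))), mod$genes)
  verdicts <- lapply(frontier, candidate_eligible, module = mod,
                     net = fx$net, scores = fx$scores, mu = fx$mu,
                     interactome = g)
  # growth terminated, so no frontier gene may be eligible
  expect_true(all(!vapply(verdicts, isTRUE, logical(1))))
  expect_true(all(lengths(lapply(verdicts, attr, "reasons")) > 0))
  not_nb <- setdiff(igraph::V(g)$name,
                    c(mod$genes, frontier))[1]
  expect_error(candidate_eligible(not_nb, mod, fx$net, fx$scores, fx$mu,
                                  interactome = g),
               "does not interact")
})

test_that("the ensemble has one raw module per seed draw and is
          reproducible", {
  fx <- make_search_fixture(6)
  params <- growth_params(seeds_per_gene = 0.5, rng_seed = 42)
  ens <- build_raw_modules(fx$net, fx$scores, fx$mu, params,
                           interactome = fx$study$graph)
  n <- igraph::vcount(fx$study$graph)
  expect_length(ens$raw_modules, round(0.5 * n))
  expect_true(all(vapply(ens$raw_modules, `[[`, integer(1), "size") >= 1))
  ens2 <- build_raw_modules(fx$net, fx$scores, fx$mu, params,
                            interactome = fx$study$graph)
  expect_identical(ens$seeds, ens2$seeds)
  expect_identical(lapply(ens$raw_modules, `[[`, "genes"),
                   lapply(ens2$raw_modules, `[[`, "genes"))
})

test_that("final-module assembly filters, pools and takes the network LCC", {
  fx <- make_search_fixture(7)
  params <- growth_params(rng_seed = 1)
  ens <- build_raw_modules(fx$net, fx$scores, fx$mu, params,
                           interactome = fx$study$graph)
  final <- assemble_final_module(ens, fx$net, params)
  expect_true(all(final$confidence > 0 & final$confidence <= 1))
  # a gene present in every top module has confidence 1 and is retained
  top_always <- names(final$confidence)[final$confidence == 1]
  expect_true(length(top_always) > 0)
  expect_true(all(top_always %in% final$genes))
  # the final module is connected in the co-expressed network
  expect_setequal(largest_connected_component(fx$net, final$genes),
                  final$genes)
  # everything filtered out -> informative error
  strict <- growth_params(min_module_size = 10000L)
  expect_error(assemble_final_module(ens, fx$net, strict),
               "min_module_size")
})

test_that("one surviving module yields its own network LCC", {
  fx <- make_search_fixture(8)
  mod <- grow_module(fx$study$planted[1], fx$net, fx$scores, fx$mu,
                     interactome = fx$study$graph)
  ens <- structure(list(raw_modules = list(mod), seeds = mod$seed),
                   class = "gps_module_ensemble")
  params <- growth_params(min_module_size = 2L)
  final <- assemble_final_module(ens, fx$net, params)
  expect_setequal(final$genes,
                  largest_connected_component(fx$net, mod$genes))
})
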