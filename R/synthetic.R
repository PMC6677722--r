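# Seeded synthetic-data generators with planted ground truth.
#
# Every pipeline stage can be exercised without external data: a heavy-tailed
# interactome, a planted connected subgraph whose genes carry elevated
# length-normalized mutation rates and block-correlated expression, and a
# drug panel whose "proximal" drugs target the planted module while decoys
# receive degree-matched random targets.

#' Generate a synthetic interactome
#'
#' Scale-free (preferential attachment, default) or static power-law
#' ("configuration") model; the largest connected component is retained and
#' vertices are named `g0001`, `g0002`, ...  Degree-matched nulls are only
#' meaningful on heavy-tailed graphs, hence the scale-free default.
#'
#' @param n_genes Number of genes (>= 50).
#' @param model `"scale-free"` or `"configuration"`.
#' @param mean_degree Target mean degree.
#' @param seed Optional integer RNG seed.
#' @return An igraph object.
#' @export
generate_interactome <- function(n_genes = 500L,
                                 model = c("scale-free", "configuration"),
                                 mean_degree = 6, seed = NULL) {
  model <- match.arg(model)
  if (n_genes < 50L) stop("n_genes must be >= 50", call. = FALSE)
  n_edges <- round(n_genes * mean_degree / 2)
  if (n_edges < n_genes - 1L) {
    stop("mean_degree too small for a connected graph", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (model == "scale-free") {
    m <- max(1L, round(mean_degree / 2))
    g <- igraph::sample_pa(n_genes, m = m, directed = FALSE)
  } else {
    g <- igraph::sample_fitness_pl(n_genes, no.of.edges = n_edges,
                                   exponent.out = 2.3)
  }
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  igraph::V(g)$name <- sprintf("g%04d", seq_len(igraph::vcount(g)))
  g
}

#' Plant a connected module
#'
#' Grows a connected subgraph of the requested size by random expansion
#' from a random start vertex, at each step absorbing the frontier gene
#' with the most links into the current set (ties broken at random).  This
#' densest-first rule makes the planted truth a densely interconnected
#' subgraph -- the defining property of a disease module -- rather than a
#' spanning tree, which no connectivity-based search could be expected to
#' recover.
#'
#' @param graph An igraph object.
#' @param size Module size (at most a fifth of the graph).
#' @param seed Optional integer RNG seed.
#' @return Sorted character vector of planted genes.
#' @export
plant_module <- function(graph, size = 20L, seed = NULL) {
  n <- igraph::vcount(graph)
  if (size > n / 5) {
    stop("planted module must not exceed a fifth of the graph",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(graph)$name
  start <- sample(nodes, 1L)
  members <- start
  while (length(members) < size) {
    frontier <- setdiff(
      unique(unlist(lapply(members, function(g) {
        igraph::neighbors(graph, g)$name
      }))), members)
    if (length(frontier) == 0L) {
      stop("cannot grow a connected module of size ", size,
           " from this start", call. = FALSE)
    }
    links <- vapply(frontier, function(f) {
      length(intersect(igraph::neighbors(graph, f)$name, members))
    }, integer(1))
    best <- frontier[links == max(links)]
    nxt <- if (length(best) == 1L) best else sample(best, 1L)
    members <- c(members, nxt)
  }
  sort(members)
}

#' Generate a mutation profile with an elevated planted set
#'
#' cDNA lengths are uniform integers in `length_range`; counts are Poisson
#' with per-gene rate `base_rate * l(i)` outside the planted set and
#' `effect_fold` times that inside, so the expected length-normalized score
#' inside/outside ratio is `effect_fold`.
#'
#' @param graph An igraph object.
#' @param planted Character vector of planted genes.
#' @param base_rate Background mutation rate per base, default 0.002.
#' @param effect_fold Rate multiplier inside the planted set (>= 1).
#' @param length_range Integer pair of cDNA length bounds.
#' @param seed Optional integer RNG seed.
#' @return A [mutation_profile()].
#' @export
generate_mutation_profile <- function(graph, planted, base_rate = 0.002,
                                      effect_fold = 10,
                                      length_range = c(500L, 5000L),
                                      seed = NULL) {
  if (effect_fold < 1) stop("effect_fold must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  genes <- igraph::V(graph)$name
  l <- sample(length_range[1L]:length_range[2L], length(genes),
              replace = TRUE)
  rate <- base_rate * l
  rate[genes %in% planted] <- rate[genes %in% planted] * effect_fold
  m <- stats::rpois(length(genes), rate)
  mutation_profile(stats::setNames(as.numeric(m), genes),
                   stats::setNames(as.numeric(l), genes))
}

#' Generate a block-correlated expression matrix
#'
#' Planted genes share a latent per-sample factor giving pairwise Pearson
#' correlation approximately `within_correlation`; background genes are
#' i.i.d. standard normal noise.
#'
#' @param graph An igraph object.
#' @param planted Character vector of planted genes.
#' @param n_samples Number of samples (>= 10).
#' @param within_correlation Target pairwise correlation in \[0, 1).
#' @param seed Optional integer RNG seed.
#' @return Numeric gene x sample matrix.
#' @export
generate_expression <- function(graph, planted, n_samples = 100L,
                                within_correlation = 0.6, seed = NULL) {
  if (!(within_correlation >= 0 && within_correlation < 1)) {
    stop("within_correlation must be in [0, 1)", call. = FALSE)
  }
  if (n_samples < 10L) stop("n_samples must be >= 10", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  genes <- igraph::V(graph)$name
  expr <- matrix(stats::rnorm(length(genes) * n_samples),
                 nrow = length(genes),
                 dimnames = list(genes,
                                 sprintf("sample%03d", seq_len(n_samples))))
  inside <- genes %in% planted
  if (any(inside) && within_correlation > 0) {
    f <- stats::rnorm(n_samples)
    expr[inside, ] <- sqrt(within_correlation) *
      matrix(f, nrow = sum(inside), ncol = n_samples, byrow = TRUE) +
      sqrt(1 - within_correlation) * expr[inside, ]
  }
  expr
}

#' Generate a drug panel with proximal and concordant plants
#'
#' Proximal drugs draw their targets from the planted module and its first
#' neighbours; decoy drugs receive degree-matched random targets (matched to
#' a proximal drug's target degrees, so proximity nulls are fair).  The
#' first `n_concordant` drugs get signatures whose up set overlaps the
#' planted module; remaining signatures are random background genes.
#'
#' @param graph An igraph object.
#' @param planted Character vector of planted genes.
#' @param n_drugs Panel size.
#' @param n_proximal Number of proximal drugs (<= n_drugs).
#' @param n_concordant Number of signature-concordant drugs (<= n_drugs).
#' @param targets_per_drug Targets per drug.
#' @param signature_size Genes per signature direction.
#' @param seed Optional integer RNG seed.
#' @return List with `drugs` (list of records usable by
#'   [repurpose_screen()]) and `truth` (a `gps_synthetic_truth`).
#' @export
generate_drug_panel <- function(graph, planted, n_drugs = 12L,
                                n_proximal = 3L, n_concordant = 3L,
                                targets_per_drug = 3L,
                                signature_size = 30L, seed = NULL) {
  if (n_proximal > n_drugs || n_concordant > n_drugs) {
    stop("planted drug counts cannot exceed the panel size", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(graph)$name
  binning <- degree_binning(graph)
  pool <- union(planted,
                unlist(lapply(planted, function(g) {
                  igraph::neighbors(graph, g)$name
                })))
  drug_ids <- sprintf("drug%02d", seq_len(n_drugs))
  proximal_ids <- drug_ids[seq_len(n_proximal)]
  concordant_ids <- drug_ids[seq_len(n_concordant)]

  drugs <- lapply(seq_len(n_drugs), function(i) {
    if (i <= n_proximal) {
      targets <- sample(pool, targets_per_drug)
    } else {
      ref <- sample(pool, targets_per_drug)
      targets <- degree_matched_sample(graph, ref, binning)
    }
    if (i <= n_concordant) {
      up <- unique(c(sample(planted, min(length(planted),
                                         ceiling(signature_size / 2))),
                     sample(setdiff(nodes, planted),
                            floor(signature_size / 2))))
    } else {
      up <- sample(setdiff(nodes, planted), signature_size)
    }
    down <- sample(setdiff(nodes, up), signature_size)
    list(drug = drug_ids[i], targets = targets,
         signature = drug_signature(up, down, drug = drug_ids[i]))
  })
  truth <- structure(list(planted_module = planted,
                          proximal_drugs = proximal_ids,
                          concordant_drugs = concordant_ids,
                          params = list(n_drugs = n_drugs,
                                        n_proximal = n_proximal,
                                        n_concordant = n_concordant,
                                        targets_per_drug = targets_per_drug,
                                        signature_size = signature_size,
                                        seed = seed)),
                     class = "gps_synthetic_truth")
  list(drugs = drugs, truth = truth)
}

#' Generate a complete synthetic study
#'
#' One seeded call producing the interactome, planted module, mutation
#' profile, expression matrix and drug panel under a single RNG stream.
#'
#' @param seed Integer RNG seed for the whole study.
#' @param n_genes,mean_degree,model Passed to [generate_interactome()].
#' @param planted_size Planted module size.
#' @param base_rate,effect_fold,length_range Passed to
#'   [generate_mutation_profile()].
#' @param n_samples,within_correlation Passed to [generate_expression()].
#' @param n_drugs,n_proximal,n_concordant,targets_per_drug,signature_size
#'   Passed to [generate_drug_panel()].
#' @return List with `graph`, `planted`, `profile`, `expr`, `drugs`,
#'   `truth`.
#' @export
generate_study <- function(seed = 1L, n_genes = 500L, mean_degree = 6,
                           model = "scale-free", planted_size = 20L,
                           base_rate = 0.002, effect_fold = 10,
                           length_range = c(500L, 5000L),
                           n_samples = 100L, within_correlation = 0.6,
                           n_drugs = 12L, n_proximal = 3L,
                           n_concordant = 3L, targets_per_drug = 3L,
                           signature_size = 30L) {
  set.seed(seed)
  graph <- generate_interactome(n_genes, model = model,
                                mean_degree = mean_degree)
  planted <- plant_module(graph, planted_size)
  profile <- generate_mutation_profile(graph, planted,
                                       base_rate = base_rate,
                                       effect_fold = effect_fold,
                                       length_range = length_range)
  expr <- generate_expression(graph, planted, n_samples = n_samples,
                              within_correlation = within_correlation)
  panel <- generate_drug_panel(graph, planted, n_drugs = n_drugs,
                               n_proximal = n_proximal,
                               n_concordant = n_concordant,
                               targets_per_drug = targets_per_drug,
                               signature_size = signature_size)
  truth <- panel$truth
  truth$params$study_seed <- seed
  list(graph = graph, planted = planted, profile = profile, expr = expr,
       drugs = panel$drugs, truth = truth)
}
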