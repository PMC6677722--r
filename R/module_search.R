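# Seeded greedy growth of raw disease modules and their aggregation.
#
# A module M with m genes has score Z_m = sum_{i in M} (s(i) - mu) / sqrt(m),
# where s(i) is the smoothed mutation score and mu its mean over the gene
# universe.  Starting from a random seed, the candidate in the network
# neighbourhood Gamma_M with the largest expanded score is admitted when it
# (a) links to the module more than expected by chance (hypergeometric upper
# tail below connectivity_p), (b) is significantly co-expressed with at least
# one directly interacting module gene, and (c) strictly increases Z.  Growth
# stops when no candidate qualifies.  Raw modules from many seeds are pooled;
# genes recurring in the top-scoring modules form the final module.

#' Growth parameter record
#'
#' @param connectivity_p Connectivity-significance threshold (criterion a).
#' @param coexpression_p Co-expression p-value threshold (criterion b).
#' @param min_module_size Raw modules smaller than this are discarded before
#'   aggregation.
#' @param seeds_per_gene Expected number of times each search-network gene is
#'   drawn as a seed; total seeds = `round(seeds_per_gene * n_genes)`.
#' @param top_fraction Fraction of surviving raw modules (by score) whose
#'   genes are pooled.
#' @param confidence_threshold Genes must appear in more than this fraction
#'   of top modules (strict) to enter the final module.
#' @param rng_seed Optional integer seed for the seed-gene stream.
#' @return Object of class `gps_growth_params`.
#' @export
growth_params <- function(connectivity_p = 0.05, coexpression_p = 0.05,
                          min_module_size = 10L, seeds_per_gene = 5,
                          top_fraction = 0.01,
                          confidence_threshold = 0.005, rng_seed = NULL) {
  for (p in c(connectivity_p, coexpression_p, top_fraction,
              confidence_threshold)) {
    if (!(p > 0 && p < 1)) {
      stop("probabilities and fractions must lie in (0, 1)", call. = FALSE)
    }
  }
  if (min_module_size < 1L) stop("min_module_size must be >= 1",
                                 call. = FALSE)
  if (seeds_per_gene <= 0) stop("seeds_per_gene must be positive",
                                call. = FALSE)
  structure(list(connectivity_p = connectivity_p,
                 coexpression_p = coexpression_p,
                 min_module_size = as.integer(min_module_size),
                 seeds_per_gene = seeds_per_gene,
                 top_fraction = top_fraction,
                 confidence_threshold = confidence_threshold,
                 rng_seed = rng_seed),
            class = "gps_growth_params")
}

#' Module score
#'
#' `Z_m = sum_{i in M} (s(i) - mu) / sqrt(m)`.
#'
#' @param genes Non-empty character vector of module genes, all scored.
#' @param scores Named numeric score vector.
#' @param mu Mean score over the gene universe (see [mean_score()]).
#' @return Scalar score.
#' @export
module_score <- function(genes, scores, mu) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("module is empty", call. = FALSE)
  s <- scores[genes]
  if (anyNA(s)) {
    stop("unscored gene in module: ", genes[which(is.na(s))[1L]],
         call. = FALSE)
  }
  sum(s - mu) / sqrt(length(genes))
}

#' Connectivity significance of a candidate gene
#'
#' Hypergeometric upper-tail probability that a gene of degree `k_i` has at
#' least `k_m` of its interaction partners inside an m-gene module, when its
#' partners were drawn at random from the N-gene network:
#' `P = sum_{k = k_m}^{min(k_i, m)} C(m, k) C(N - m, k_i - k) / C(N, k_i)`.
#' The sum is accumulated in log space for numerical stability.
#'
#' @param N Total number of genes in the search network.
#' @param m Module size (m < N).
#' @param k_i Candidate degree (k_i <= N - 1).
#' @param k_m Number of module genes linked to the candidate
#'   (0 <= k_m <= min(k_i, m)).
#' @return Tail probability in (0, 1].
#' @export
connectivity_significance <- function(N, m, k_i, k_m) {
  if (m >= N || m < 0) stop("require 0 <= m < N", call. = FALSE)
  if (k_i > N - 1 || k_i < 0) stop("require 0 <= k_i <= N - 1",
                                   call. = FALSE)
  if (k_m < 0 || k_m > min(k_i, m)) {
    stop("require 0 <= k_m <= min(k_i, m)", call. = FALSE)
  }
  if (k_m == 0L) {
    return(1)  # full hypergeometric sum (Vandermonde)
  }
  lo <- max(k_m, k_i - (N - m))
  hi <- min(k_i, m)
  ks <- lo:hi
  lt <- lchoose(m, ks) + lchoose(N - m, k_i - ks) - lchoose(N, k_i)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Expanded module score
#'
#' Score the module would have after admitting `candidate`:
#' `Z_{m+1} = (sum_excess + (s(i) - mu)) / sqrt(m + 1)`.  Identical to
#' [module_score()] on the union.
#'
#' @param module A `gps_module` (from [grow_module()]).
#' @param candidate Gene identifier not already in the module.
#' @param scores,mu As in [module_score()].
#' @return Scalar expanded score.
#' @export
expanded_score <- function(module, candidate, scores, mu) {
  stopifnot(inherits(module, "gps_module"))
  if (candidate %in% module$genes) {
    stop("candidate already in module", call. = FALSE)
  }
  s <- scores[[candidate]]
  if (is.null(s) || is.na(s)) stop("unscored candidate", call. = FALSE)
  (module$sum_excess + (s - mu)) / sqrt(module$size + 1)
}

# Fast index-based search context shared by all growths.
#
# Candidates (Gamma_M) come from the interactome neighbourhood of the
# module; the connectivity significance is evaluated in the interactome
# (N = node count, k_i the interactome degree, k_m the interactome links
# into the module).  Criterion (b) uses the co-expressed network: a
# candidate qualifies when at least one of its interactome edges into the
# module is significantly co-expressed (edge p-value below coexpression_p).
# Because of (b), every admitted gene has a co-expressed edge into the
# module, so grown modules are connected in the co-expressed network.
.make_search_context <- function(net, interactome, scores, mu,
                                 coexpression_p) {
  nm <- igraph::V(interactome)$name
  n <- length(nm)
  if (!all(igraph::V(net)$name %in% nm)) {
    stop("co-expressed network is not a subgraph of the interactome",
         call. = FALSE)
  }
  s <- scores[nm]
  if (anyNA(s)) {
    stop("interactome contains unscored gene(s), e.g. ",
         nm[which(is.na(s))[1L]], call. = FALSE)
  }
  int_adj <- lapply(igraph::as_adj_list(interactome), as.integer)
  # significantly co-expressed adjacency, in interactome indices
  ep <- igraph::ends(net, igraph::E(net), names = TRUE)
  psig <- igraph::E(net)$p_value < coexpression_p
  sig_adj <- vector("list", n)
  for (i in seq_len(n)) sig_adj[[i]] <- integer(0)
  if (any(psig)) {
    se <- cbind(match(ep[psig, 1L], nm), match(ep[psig, 2L], nm))
    sp <- split(c(se[, 2L], se[, 1L]), c(se[, 1L], se[, 2L]))
    for (v in names(sp)) sig_adj[[as.integer(v)]] <- as.integer(sp[[v]])
  }
  list(n = n, names = nm, excess = as.numeric(s - mu),
       int_adj = int_adj, sig_adj = sig_adj,
       int_deg = as.integer(igraph::degree(interactome)),
       N = n)
}

# Core growth loop on the index context; returns indices in admission order.
.grow_module_idx <- function(seed_idx, ctx, params) {
  n <- ctx$n
  in_mod <- logical(n)
  k_m <- integer(n)       # links to module in the interactome
  k_m_sig <- integer(n)   # significantly co-expressed links to module
  order_idx <- integer(0)

  admit <- function(g) {
    in_mod[g] <<- TRUE
    order_idx[length(order_idx) + 1L] <<- g
    nb <- ctx$int_adj[[g]]
    if (length(nb) > 0L) k_m[nb] <<- k_m[nb] + 1L
    nbs <- ctx$sig_adj[[g]]
    if (length(nbs) > 0L) k_m_sig[nbs] <<- k_m_sig[nbs] + 1L
  }
  admit(seed_idx)
  sum_excess <- ctx$excess[seed_idx]
  m <- 1L
  z <- sum_excess

  repeat {
    cand <- which(k_m_sig > 0L & !in_mod)      # criterion (b) prefilter
    if (length(cand) == 0L) break
    z1 <- (sum_excess + ctx$excess[cand]) / sqrt(m + 1)
    ok <- z1 > z                               # criterion (c)
    cand <- cand[ok]
    if (length(cand) == 0L) break
    z1 <- z1[ok]
    ord <- order(-z1, ctx$names[cand])         # best-first, lexicographic tie
    added <- FALSE
    for (j in ord) {
      g <- cand[j]
      p_conn <- connectivity_significance(ctx$N, m, ctx$int_deg[g],
                                          min(k_m[g], m))
      if (p_conn < params$connectivity_p) {    # criterion (a)
        admit(g)
        sum_excess <- sum_excess + ctx$excess[g]
        m <- m + 1L
        z <- sum_excess / sqrt(m)
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  list(order = order_idx, sum_excess = sum_excess, score = z)
}

.as_gps_module <- function(res, ctx) {
  structure(list(genes = ctx$names[res$order],
                 seed = ctx$names[res$order[1L]],
                 size = length(res$order),
                 sum_excess = res$sum_excess,
                 score = res$score),
            class = "gps_module")
}

#' Grow one raw module from a seed gene
#'
#' Deterministic best-first growth: among the interactome neighbours of the
#' module that satisfy the three admission criteria, the one with the
#' largest expanded score is admitted (ties broken lexicographically),
#' until none qualifies.  A seed with no eligible neighbour yields a
#' singleton module.  Since criterion (b) demands a significantly
#' co-expressed edge into the module, every multi-gene module is connected
#' in the co-expressed network.
#'
#' @param seed Seed gene, present in the interactome.
#' @param net Co-expressed network from [build_coexpressed_network()].
#' @param scores Named numeric smoothed score vector.
#' @param mu Mean score over the gene universe.
#' @param params A [growth_params()] record.
#' @param interactome The full interactome: source of candidate
#'   neighbourhoods and of the connectivity significance (`net` must be its
#'   subgraph).  Defaults to `net`.
#' @return Object of class `gps_module` with elements `genes` (admission
#'   order), `seed`, `size`, `sum_excess` and `score`.
#' @export
grow_module <- function(seed, net, scores, mu, params = growth_params(),
                        interactome = net) {
  ctx <- .make_search_context(net, interactome, scores, mu,
                              params$coexpression_p)
  seed_idx <- match(seed, ctx$names)
  if (is.na(seed_idx)) {
    stop("seed gene not in the interactome: ", seed, call. = FALSE)
  }
  .as_gps_module(.grow_module_idx(seed_idx, ctx, params), ctx)
}

#' Test a candidate against the three admission criteria
#'
#' @param candidate Gene adjacent to the module in the interactome.
#' @param module A `gps_module`.
#' @inheritParams grow_module
#' @return Logical scalar; attribute `reasons` lists the failed criteria
#'   among `"connectivity"`, `"coexpression"`, `"score"`.
#' @export
candidate_eligible <- function(candidate, module, net, scores, mu,
                               params = growth_params(),
                               interactome = net) {
  stopifnot(inherits(module, "gps_module"))
  in_mod_nb <- intersect(igraph::neighbors(interactome, candidate)$name,
                         module$genes)
  if (length(in_mod_nb) == 0L) {
    stop("candidate does not interact with the module", call. = FALSE)
  }
  reasons <- character(0)
  k_m <- length(in_mod_nb)
  p_conn <- connectivity_significance(
    igraph::vcount(interactome), module$size,
    igraph::degree(interactome, candidate), min(k_m, module$size))
  if (p_conn >= params$connectivity_p) reasons <- c(reasons, "connectivity")
  coexpressed <- FALSE
  if (candidate %in% igraph::V(net)$name) {
    net_nb <- intersect(igraph::neighbors(net, candidate)$name, in_mod_nb)
    if (length(net_nb) > 0L) {
      eids <- igraph::get_edge_ids(net, rbind(rep(candidate,
                                                  length(net_nb)), net_nb))
      coexpressed <- any(igraph::E(net)$p_value[eids] <
                           params$coexpression_p)
    }
  }
  if (!coexpressed) reasons <- c(reasons, "coexpression")
  if (expanded_score(module, candidate, scores, mu) <= module$score) {
    reasons <- c(reasons, "score")
  }
  structure(length(reasons) == 0L, reasons = reasons)
}

#' Build the raw-module ensemble
#'
#' Draws `round(seeds_per_gene * n)` seed genes uniformly with replacement
#' from the n interactome genes and grows one raw module from each.
#' Growth is deterministic given the seed gene, so repeated seeds reuse
#' the grown module.
#'
#' @inheritParams grow_module
#' @return Object of class `gps_module_ensemble`: list with `raw_modules`
#'   (one per seed draw) and `seeds`.
#' @export
build_raw_modules <- function(net, scores, mu, params = growth_params(),
                              interactome = net) {
  ctx <- .make_search_context(net, interactome, scores, mu,
                              params$coexpression_p)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  n_seeds <- max(1L, as.integer(round(params$seeds_per_gene * ctx$n)))
  seed_idx <- sample.int(ctx$n, n_seeds, replace = TRUE)
  grown <- vector("list", ctx$n)
  for (i in unique(seed_idx)) {
    grown[[i]] <- .as_gps_module(.grow_module_idx(i, ctx, params), ctx)
  }
  structure(list(raw_modules = grown[seed_idx],
                 seeds = ctx$names[seed_idx]),
            class = "gps_module_ensemble")
}

#' Aggregate raw modules into the final disease module
#'
#' Discards raw modules below `min_module_size`, keeps the
#' `ceiling(top_fraction * n_surviving)` highest-scoring ones (ties broken
#' lexicographically by seed), computes per-gene confidence (fraction of top
#' modules containing the gene), keeps genes with confidence strictly above
#' `confidence_threshold`, and returns their largest connected component in
#' the co-expressed network (isolated genes are dropped).
#'
#' @param ensemble A `gps_module_ensemble`.
#' @param net The co-expressed network the modules were grown on.
#' @param params A [growth_params()] record.
#' @return Object of class `gps_final_module`: list with `genes` (the final
#'   module), `confidence` (named vector over pooled genes), `n_top`,
#'   `n_surviving` and `n_raw`.
#' @export
assemble_final_module <- function(ensemble, net, params = growth_params()) {
  stopifnot(inherits(ensemble, "gps_module_ensemble"))
  raw <- ensemble$raw_modules
  sizes <- vapply(raw, `[[`, integer(1), "size")
  surv <- raw[sizes >= params$min_module_size]
  if (length(surv) == 0L) {
    stop("all raw modules fall below min_module_size = ",
         params$min_module_size, "; consider a smaller threshold",
         call. = FALSE)
  }
  zs <- vapply(surv, `[[`, numeric(1), "score")
  seeds <- vapply(surv, `[[`, character(1), "seed")
  n_top <- ceiling(params$top_fraction * length(surv))
  top <- surv[order(-zs, seeds)][seq_len(n_top)]
  counts <- table(unlist(lapply(top, `[[`, "genes")))
  confidence <- as.numeric(counts) / n_top
  names(confidence) <- names(counts)
  keep <- names(confidence)[confidence > params$confidence_threshold]
  final <- largest_connected_component(net, keep)
  structure(list(genes = final, confidence = confidence, n_top = n_top,
                 n_surviving = length(surv), n_raw = length(raw)),
            class = "gps_final_module")
}

#' @export
print.gps_module <- function(x, ...) {
  cat("Raw module: seed", x$seed, "|", x$size, "genes | Z =",
      format(x$score, digits = 4), "\n")
  invisible(x)
}

#' @export
print.gps_final_module <- function(x, ...) {
  cat("Disease module:", length(x$genes), "genes\n")
  cat("  from", x$n_top, "top raw modules (", x$n_surviving,
      "surviving /", x$n_raw, "raw )\n")
  invisible(x)
}

#' Run the full module-identification pipeline
#'
#' Convenience wrapper: length-normalized initial scores, random walk with
#' restart smoothing over the interactome, co-expression edge filtering, raw
#' module growth and final-module aggregation.  The score mean mu is taken
#' over the interactome node set.
#'
#' @param graph Interactome igraph object.
#' @param profile A [mutation_profile()].
#' @param expr Expression matrix (genes x samples).
#' @param alpha Restart probability for smoothing.
#' @param p_thresh Co-expression edge retention threshold.
#' @param counts Logical; `TRUE` if `expr` holds raw counts.
#' @param params A [growth_params()] record.
#' @return List with `final` (a `gps_final_module`), `ensemble`, `net`,
#'   `scores` (smoothed), `s0` and `mu`.
#' @export
find_disease_module <- function(graph, profile, expr, alpha = 0.5,
                                p_thresh = 0.05, counts = FALSE,
                                params = growth_params()) {
  universe <- igraph::V(graph)$name
  s0 <- initial_scores(profile, universe)
  scores <- rwr_smooth(graph, s0, alpha = alpha)
  mu <- mean_score(scores, universe)
  net <- build_coexpressed_network(graph, expr, p_thresh = p_thresh,
                                   counts = counts)
  ensemble <- build_raw_modules(net, scores, mu, params,
                                interactome = graph)
  final <- assemble_final_module(ensemble, net, params)
  list(final = final, ensemble = ensemble, net = net, scores = scores,
       s0 = s0, mu = mu)
}
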