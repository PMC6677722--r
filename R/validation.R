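# Permutation statistics validating identified modules.
#
# All nulls preserve the degree distribution of the observed gene set via
# logarithmic degree bins.  Empirical p-values use the add-one estimator
# p = (1 + #{null >= observed}) / (1 + nPerm), which counts ties as
# successes and is therefore never exactly zero.

.permutation_result <- function(observed, null_samples, alternative) {
  n_perm <- length(null_samples)
  hits <- switch(alternative,
                 greater = sum(null_samples >= observed),
                 less = sum(null_samples <= observed),
                 stop("unknown alternative"))
  sd_null <- stats::sd(null_samples)
  z <- if (is.na(sd_null) || sd_null == 0) NA_real_ else
    (observed - mean(null_samples)) / sd_null
  structure(list(observed = observed,
                 null_samples = null_samples,
                 p_value = (1 + hits) / (1 + n_perm),
                 z_score = z,
                 n_permutations = n_perm,
                 alternative = alternative),
            class = "gps_permutation")
}

#' @export
print.gps_permutation <- function(x, ...) {
  p_floor <- 1 / (x$n_permutations + 1)
  p_txt <- if (x$p_value <= p_floor) paste0("< ", format(p_floor)) else
    format(x$p_value, digits = 3)
  cat("Permutation test (", x$alternative, "): observed = ",
      format(x$observed, digits = 4), ", p ", p_txt, ", z = ",
      format(x$z_score, digits = 3), " [", x$n_permutations,
      " permutations]\n", sep = "")
  invisible(x)
}

#' Significance of a gene set's largest connected component
#'
#' Compares the observed LCC size of `genes` against LCC sizes of
#' degree-matched random gene sets (one-sided, greater).  A significantly
#' large LCC indicates that the genes cluster into a network module rather
#' than scattering over the interactome.
#'
#' @param graph Interactome igraph object.
#' @param genes Character vector of genes (degree >= 1 required for the
#'   null sampler).
#' @param n_perm Number of permutations (>= 100).
#' @param binning Optional precomputed [degree_binning()].
#' @return A `gps_permutation` object.
#' @export
lcc_significance <- function(graph, genes, n_perm = 1000L, binning = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (is.null(binning)) binning <- degree_binning(graph)
  genes <- intersect(unique(as.character(genes)), names(binning$bin_of))
  if (length(genes) == 0L) stop("no usable genes", call. = FALSE)
  observed <- length(largest_connected_component(graph, genes))
  null <- vapply(seq_len(n_perm), function(i) {
    length(largest_connected_component(
      graph, degree_matched_sample(graph, genes, binning)))
  }, numeric(1))
  .permutation_result(observed, null, "greater")
}

#' Degree-matched overlap enrichment of a reference gene set in a module
#'
#' Observed statistic: `|moduleGenes intersect referenceGenes|`.  The null
#' replaces the reference set by degree-matched random sets (one-sided,
#' greater).  Used e.g. to test enrichment of known driver genes in an
#' identified module.
#'
#' @param graph Interactome igraph object.
#' @param module_genes,reference_genes Non-empty character vectors of genes
#'   in the graph.
#' @param n_perm Number of permutations.
#' @param binning Optional precomputed [degree_binning()].
#' @return A `gps_permutation` object.
#' @export
overlap_enrichment_permutation <- function(graph, module_genes,
                                           reference_genes,
                                           n_perm = 1000L, binning = NULL) {
  if (is.null(binning)) binning <- degree_binning(graph)
  module_genes <- unique(as.character(module_genes))
  reference_genes <- intersect(unique(as.character(reference_genes)),
                               names(binning$bin_of))
  if (length(module_genes) == 0L || length(reference_genes) == 0L) {
    stop("module and reference gene sets must be non-empty", call. = FALSE)
  }
  observed <- length(intersect(module_genes, reference_genes))
  null <- vapply(seq_len(n_perm), function(i) {
    length(intersect(module_genes,
                     degree_matched_sample(graph, reference_genes,
                                           binning)))
  }, numeric(1))
  .permutation_result(observed, null, "greater")
}

#' Jaccard similarity of two gene sets
#'
#' `|A intersect B| / |A union B|`; at least one set must be non-empty.
#'
#' @param a,b Character vectors.
#' @return Scalar in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) {
    stop("both sets are empty", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Tissue-expression z-score
#'
#' Standardizes a gene's expression in one tissue against its mean and
#' standard deviation across all considered tissues:
#' `z_E = (E(i, t) - E(i)) / sd_E(i)`.
#'
#' @param expression_in_tissue E(i, t).
#' @param mean_across_tissues Mean expression across tissues.
#' @param sd_across_tissues Standard deviation across tissues (must be > 0).
#' @return Numeric z-score (vectorized).
#' @export
tissue_expression_z <- function(expression_in_tissue, mean_across_tissues,
                                sd_across_tissues) {
  if (any(sd_across_tissues <= 0)) {
    stop("standard deviation across tissues must be positive",
         call. = FALSE)
  }
  (expression_in_tissue - mean_across_tissues) / sd_across_tissues
}

#' Tissue-expressed gene filter
#'
#' A gene counts as expressed in a tissue when its expression is at least
#' `min_value` (RPKM by default) in more than `min_fraction` of samples.
#'
#' @param expr Gene x sample expression matrix for one tissue.
#' @param min_value Expression floor, default 1.
#' @param min_fraction Minimum fraction of samples (strictly exceeded),
#'   default 0.8.
#' @return Character vector of expressed genes.
#' @export
tissue_expressed_genes <- function(expr, min_value = 1,
                                   min_fraction = 0.8) {
  rownames(expr)[rowMeans(expr >= min_value) > min_fraction]
}
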