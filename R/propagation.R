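# Length-normalized mutation scoring and random-walk-with-restart smoothing.
#
# Per-gene somatic mutation burden is sparse: most genes carry no mutation in
# a given cohort even when their pathway is recurrently hit.  The raw score
# s0(i) = m(i)/l(i) (mutation count over cDNA length, so long genes are not
# trivially favoured) is therefore diffused over the interactome with a
# random walk with restart, s_{t+1} = (1 - alpha) W s_t + alpha s0, where W
# is the column-normalized adjacency matrix W_ij = 1/k(j).

#' Mutation profile constructor
#'
#' @param mutation_count Named non-negative numeric vector: mutation counts
#'   (mutated patients or mutation events, per cancer type) per gene.
#' @param cdna_length Named positive numeric vector: cDNA length in bases.
#'   Every gene with a count must have a length.
#' @return Object of class `gps_mutation_profile`.
#' @export
mutation_profile <- function(mutation_count, cdna_length) {
  if (is.null(names(mutation_count)) || is.null(names(cdna_length))) {
    stop("mutation_count and cdna_length must be named by gene",
         call. = FALSE)
  }
  if (any(mutation_count < 0)) {
    stop("negative mutation count for gene ",
         names(mutation_count)[which(mutation_count < 0)[1L]],
         call. = FALSE)
  }
  if (any(cdna_length <= 0)) {
    stop("non-positive cDNA length for gene ",
         names(cdna_length)[which(cdna_length <= 0)[1L]], call. = FALSE)
  }
  orphan <- setdiff(names(mutation_count), names(cdna_length))
  if (length(orphan) > 0L) {
    stop("gene ", orphan[1L], " has a mutation count but no cDNA length",
         call. = FALSE)
  }
  structure(list(mutation_count = mutation_count,
                 cdna_length = cdna_length),
            class = "gps_mutation_profile")
}

#' Read a mutation table
#'
#' TSV with columns `gene`, `mutation_count`, `cdna_length`.
#'
#' @param path File path.
#' @return A [mutation_profile()] object.
#' @export
read_mutation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("gene", "mutation_count", "cdna_length")
  if (!all(req %in% names(tab))) {
    stop("mutation table must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  mutation_profile(
    stats::setNames(as.numeric(tab$mutation_count), tab$gene),
    stats::setNames(as.numeric(tab$cdna_length), tab$gene)
  )
}

#' Initial length-normalized mutation scores
#'
#' s0(i) = m(i)/l(i) over a declared gene universe; genes without mutation
#' data score 0.  Profile genes outside the universe are dropped with a
#' warning (they cannot receive smoothed scores).
#'
#' @param profile A [mutation_profile()].
#' @param universe Non-empty character vector of genes (typically the
#'   interactome node set).
#' @return Named numeric vector of scores over `universe`.
#' @export
initial_scores <- function(profile, universe) {
  stopifnot(inherits(profile, "gps_mutation_profile"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop("gene universe is empty", call. = FALSE)
  }
  s0 <- stats::setNames(numeric(length(universe)), universe)
  scored <- names(profile$mutation_count)
  outside <- setdiff(scored, universe)
  if (length(outside) > 0L) {
    warning(length(outside),
            " mutated gene(s) absent from the universe were dropped",
            call. = FALSE)
  }
  common <- intersect(scored, universe)
  s0[common] <- profile$mutation_count[common] / profile$cdna_length[common]
  s0
}

# Column-normalized sparse transfer matrix W_ij = 1/k(j); zero columns for
# isolated nodes.
.transfer_matrix <- function(graph) {
  a <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  k <- Matrix::colSums(a)
  inv <- ifelse(k > 0, 1 / k, 0)
  a %*% Matrix::Diagonal(x = inv)
}

.align_scores <- function(graph, s0) {
  nodes <- igraph::V(graph)$name
  if (is.null(names(s0))) {
    stop("score vector must be named by gene", call. = FALSE)
  }
  missing <- setdiff(nodes, names(s0))
  if (length(missing) > 0L) {
    stop("score vector lacks ", length(missing),
         " graph node(s), e.g. ", missing[1L], call. = FALSE)
  }
  s0[nodes]
}

#' Random walk with restart score smoothing (iterative)
#'
#' Iterates `s_{t+1} = (1 - alpha) W s_t + alpha s0` from `s = s0` until the
#' L1 change drops below `tol`.  Isolated nodes have a zero column in W, so
#' their fixed-point score is `alpha * s0(i)`.
#'
#' @param graph An igraph object.
#' @param s0 Named numeric vector covering all graph nodes.
#' @param alpha Restart probability in (0, 1]; 0.5 balances the degree bias
#'   of pure diffusion against the sparsity of the raw scores.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exhausting it is an error.
#' @return Named numeric vector of smoothed scores with attributes `alpha`,
#'   `iterations` and `residual`.
#' @export
rwr_smooth <- function(graph, s0, alpha = 0.5, tol = 1e-6,
                       max_iter = 1000L) {
  if (!(alpha > 0 && alpha <= 1)) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  s0 <- .align_scores(graph, s0)
  if (alpha == 1) {
    return(structure(s0, alpha = 1, iterations = 0L, residual = 0))
  }
  w <- .transfer_matrix(graph)
  s <- s0
  for (it in seq_len(max_iter)) {
    s_new <- as.numeric((1 - alpha) * (w %*% s)) + alpha * s0
    res <- sum(abs(s_new - s))
    s <- s_new
    if (res < tol) {
      return(structure(stats::setNames(s, names(s0)), alpha = alpha,
                       iterations = it, residual = res))
    }
  }
  stop("random walk did not converge in ", max_iter,
       " iterations (L1 residual ", format(res), ")", call. = FALSE)
}

#' Random walk with restart score smoothing (closed form)
#'
#' Direct solve of the fixed point `s = alpha (I - (1 - alpha) W)^{-1} s0`.
#' Guarded to graphs of at most 5000 nodes (dense solve).
#'
#' @inheritParams rwr_smooth
#' @return Named numeric vector of smoothed scores with attribute `alpha`.
#' @export
rwr_closed_form <- function(graph, s0, alpha = 0.5) {
  if (!(alpha > 0 && alpha <= 1)) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  if (n > 5000L) {
    stop("closed-form solve is guarded to <= 5000 nodes; use rwr_smooth()",
         call. = FALSE)
  }
  s0 <- .align_scores(graph, s0)
  if (alpha == 1) {
    return(structure(s0, alpha = 1))
  }
  w <- as.matrix(.transfer_matrix(graph))
  s <- alpha * solve(diag(n) - (1 - alpha) * w, s0)
  structure(stats::setNames(as.numeric(s), names(s0)), alpha = alpha)
}

#' Mean score over a gene universe
#'
#' Arithmetic mean of the scores over the declared universe; genes missing
#' from the score vector count as 0.  This is the mu subtracted from every
#' gene score in the module objective.
#'
#' @param scores Named numeric vector.
#' @param universe Non-empty character vector.
#' @return Scalar mean.
#' @export
mean_score <- function(scores, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop("gene universe is empty", call. = FALSE)
  }
  v <- scores[universe]
  v[is.na(v)] <- 0
  mean(v)
}

#' Write a smoothed-score table
#'
#' TSV with columns `gene`, `s0`, `s_smoothed`.
#'
#' @param path Output path.
#' @param s0 Named numeric vector of raw scores.
#' @param smoothed Named numeric vector of smoothed scores (same genes).
#' @param header Optional comment lines (without leading `#`) written at the
#'   top of the file.
#' @export
write_score_table <- function(path, s0, smoothed, header = character(0)) {
  genes <- names(smoothed)
  tab <- data.frame(gene = genes, s0 = as.numeric(s0[genes]),
                    s_smoothed = as.numeric(smoothed),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0L) {
    writeLines(paste0("# ", header), con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
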