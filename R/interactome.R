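# Graph data model and degree-preserving sampling.
#
# The interactome is an undirected simple igraph object with character vertex
# names (gene identifiers).  Every statistical null in the package resamples
# gene sets while preserving the degree distribution, using logarithmic
# degree bins.

#' Load an undirected interactome from an edge list
#'
#' Reads a two-column (or wider; extra columns are ignored) delimited text
#' file of gene-gene interactions and returns a simple undirected graph.
#' Lines starting with `#` are treated as comments.  Self-loops are dropped
#' (their genes are retained as isolated nodes) and duplicate edges are
#' collapsed; both events are reported via [message()].
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter, default tab.
#' @return An [igraph::igraph] object with vertex attribute `name`.
#' @export
load_edge_list <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("edge-list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0L) {
    stop("edge-list file contains no data rows: ", path, call. = FALSE)
  }
  parts <- strsplit(lines[data_idx], delimiter, fixed = TRUE)
  nfield <- vapply(parts, length, integer(1))
  if (any(nfield < 2L)) {
    stop("malformed edge-list row (fewer than 2 columns) at line ",
         data_idx[which(nfield < 2L)[1L]], " of ", path, call. = FALSE)
  }
  a <- trimws(vapply(parts, `[[`, character(1), 1L))
  b <- trimws(vapply(parts, `[[`, character(1), 2L))
  empty <- a == "" | b == ""
  if (any(empty)) {
    stop("malformed edge-list row (empty gene identifier) at line ",
         data_idx[which(empty)[1L]], " of ", path, call. = FALSE)
  }
  self <- a == b
  if (any(self)) {
    message(sum(self), " self-loop row(s) dropped")
  }
  a2 <- a[!self]
  b2 <- b[!self]
  if (length(a2) == 0L) {
    stop("no valid edges in ", path, " after removing self-loops",
         call. = FALSE)
  }
  key <- ifelse(a2 < b2, paste(a2, b2, sep = "\r"), paste(b2, a2, sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate edge row(s) collapsed")
  }
  g <- igraph::graph_from_edgelist(cbind(a2[!dup], b2[!dup]),
                                   directed = FALSE)
  # genes that only ever appeared in self-loop rows stay as isolated nodes
  solo <- setdiff(unique(c(a[self], b[self])), igraph::V(g)$name)
  if (length(solo) > 0L) {
    g <- igraph::add_vertices(g, length(solo), name = solo)
  }
  g
}

#' Write a JSON summary of a graph
#'
#' Records node count, edge count and the degree histogram.
#'
#' @param graph An igraph object.
#' @param path Output JSON path.
#' @return Invisibly, the summary list.
#' @export
write_graph_summary <- function(graph, path) {
  deg <- igraph::degree(graph)
  hist <- table(deg)
  out <- list(
    nodes = igraph::vcount(graph),
    edges = igraph::ecount(graph),
    degree_histogram = as.list(stats::setNames(as.integer(hist),
                                               names(hist)))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Largest connected component of an induced subgraph
#'
#' Returns the node set of the largest connected component of the subgraph
#' induced by `genes`.  Genes absent from the graph are dropped with a
#' warning.  Ties between equally large components are broken by the
#' lexicographically smallest member, so results are reproducible.
#'
#' @param graph An igraph object.
#' @param genes Character vector of gene identifiers.
#' @return Sorted character vector of the LCC members (empty if `genes` is
#'   empty after intersection with the graph).
#' @export
largest_connected_component <- function(graph, genes) {
  genes <- unique(as.character(genes))
  present <- genes %in% igraph::V(graph)$name
  if (any(!present)) {
    warning(sum(!present), " gene(s) absent from the graph were dropped",
            call. = FALSE)
  }
  genes <- genes[present]
  if (length(genes) == 0L) {
    return(character(0))
  }
  sub <- igraph::induced_subgraph(graph, genes)
  comp <- igraph::components(sub)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    # lexicographically smallest member breaks the tie
    mins <- vapply(big, function(ci) {
      min(igraph::V(sub)$name[comp$membership == ci])
    }, character(1))
    big <- big[order(mins)[1L]]
  }
  sort(igraph::V(sub)$name[comp$membership == big])
}

#' Multi-source shortest-path lengths
#'
#' Unweighted breadth-first hop counts from the nearest source.  Unreachable
#' nodes get `Inf`.
#'
#' @param graph An igraph object.
#' @param sources Non-empty character vector of source genes, all present in
#'   the graph.
#' @return Named numeric vector over all graph nodes.
#' @export
shortest_path_lengths <- function(graph, sources) {
  sources <- unique(as.character(sources))
  if (length(sources) == 0L) {
    stop("at least one source gene is required", call. = FALSE)
  }
  missing <- setdiff(sources, igraph::V(graph)$name)
  if (length(missing) > 0L) {
    stop("source gene(s) not in graph: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  d <- igraph::distances(graph, v = sources, to = igraph::V(graph),
                         algorithm = "unweighted")
  res <- apply(d, 2L, min)
  stats::setNames(as.numeric(res), igraph::V(graph)$name)
}

#' Logarithmic degree binning
#'
#' Assigns every node of degree >= 1 to bin `floor(log2(degree))`.  Exact
#' degree matching is infeasible in the sparse tail of heavy-tailed degree
#' distributions, so degree-preserving nulls sample within these bins.
#' Degree-0 nodes are excluded from the sampling universe.
#'
#' @param graph An igraph object.
#' @return An object of class `gps_degree_binning` with elements `bin_of`
#'   (named integer vector) and `members` (list of gene vectors per bin).
#' @export
degree_binning <- function(graph) {
  deg <- igraph::degree(graph)
  pos <- deg > 0
  bin <- floor(log2(deg[pos]))
  structure(
    list(
      bin_of = stats::setNames(as.integer(bin), names(deg)[pos]),
      members = split(names(deg)[pos], bin)
    ),
    class = "gps_degree_binning"
  )
}

#' Degree-matched random gene sample
#'
#' Replaces each input gene by a gene drawn uniformly from the same
#' logarithmic degree bin, without replacement within the sample, so that
#' the binned-degree histogram of the output equals that of the input.
#' Reproducible for a fixed RNG state (use [set.seed()]).
#'
#' @param graph An igraph object.
#' @param genes Character vector of genes, all in the graph with degree
#'   >= 1.
#' @param binning Optional precomputed [degree_binning()] of `graph`.
#' @return Character vector of the same length as `genes`.
#' @export
degree_matched_sample <- function(graph, genes, binning = NULL) {
  genes <- as.character(genes)
  if (is.null(binning)) {
    binning <- degree_binning(graph)
  }
  bins <- binning$bin_of[genes]
  if (anyNA(bins)) {
    bad <- genes[is.na(bins)]
    stop("gene(s) not in the sampling universe (absent or degree 0): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  need <- table(bins)
  out <- character(0)
  for (b in names(need)) {
    avail <- binning$members[[b]]
    n_b <- as.integer(need[[b]])
    if (length(avail) < n_b) {
      stop("degree bin ", b, " holds ", length(avail), " genes but ", n_b,
           " draws were requested; use coarser degree bins", call. = FALSE)
    }
    out <- c(out, sample(avail, n_b, replace = FALSE))
  }
  out
}
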