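# Pairwise co-expression testing and the co-expressed PPI network.
#
# Module growth operates on the subgraph of the interactome whose edges link
# significantly co-expressed gene pairs in the tumor cohort (Pearson r with
# an F-statistic p-value).  Edges with an unmeasured endpoint are dropped.

#' Read a gene x sample expression matrix
#'
#' TSV whose first column holds gene identifiers and remaining columns hold
#' samples.  Missing values are not allowed.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  if (ncol(tab) < 4L) {
    stop("expression matrix needs >= 3 sample columns", call. = FALSE)
  }
  genes <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) {
    stop("expression matrix contains missing values", call. = FALSE)
  }
  rownames(mat) <- genes
  mat
}

#' Pearson correlation with an F-statistic p-value
#'
#' Tests a gene pair's co-expression: Pearson r, with the two-sided p-value
#' of `F = r^2 (n - 2) / (1 - r^2)` on (1, n - 2) degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length n >= 3, neither constant.
#' @return List with elements `r` and `p`.
#' @export
pair_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("vectors differ in length", call. = FALSE)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  denom <- 1 - r^2
  if (denom <= .Machine$double.eps) {
    p <- 0
  } else {
    f <- r^2 * (n - 2) / denom
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p)
}

#' Build the co-expressed PPI network
#'
#' Retains the interactome edges whose endpoints are both measured in the
#' expression matrix and whose pairwise co-expression p-value is below
#' `p_thresh` (two-sided; the sign of r is not restricted).  Raw counts are
#' log2(x + 1)-transformed first, since Pearson correlation on raw counts is
#' dominated by library size.  Genes with constant expression are treated as
#' unmeasured.
#'
#' @param graph Interactome igraph object.
#' @param expr Numeric gene x sample matrix (rownames are genes).
#' @param p_thresh Edge-retention p-value threshold in (0, 1), default 0.05.
#'   No multiple-testing correction is applied at this step.
#' @param counts Logical; `TRUE` if `expr` holds raw read counts.
#' @return An igraph object whose edges carry attributes `pearson_r` and
#'   `p_value`, with graph attributes `n_dropped_unmeasured` (interactome
#'   edges with an unmeasured endpoint) and `p_thresh`.  Vertices with no
#'   retained edge are excluded.
#' @export
build_coexpressed_network <- function(graph, expr, p_thresh = 0.05,
                                      counts = FALSE) {
  if (!(p_thresh > 0 && p_thresh < 1)) {
    stop("p_thresh must be in (0, 1)", call. = FALSE)
  }
  n_samp <- ncol(expr)
  if (n_samp < 3L) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(expr)) stop("expression matrix contains NA", call. = FALSE)
  if (counts) {
    expr <- log2(expr + 1)
  }
  mu <- rowMeans(expr)
  cent <- expr - mu
  ss <- rowSums(cent^2)
  usable <- rownames(expr)[ss > 0]
  z <- cent[usable, , drop = FALSE] / sqrt(ss[usable])

  el <- igraph::as_edgelist(graph)
  measured <- el[, 1L] %in% usable & el[, 2L] %in% usable
  n_dropped <- sum(!measured)
  idx <- which(measured)
  if (length(idx) == 0L) {
    stop("no interactome edge has both endpoints measured", call. = FALSE)
  }
  r <- rowSums(z[el[idx, 1L], , drop = FALSE] *
               z[el[idx, 2L], , drop = FALSE])
  r <- pmin(1, pmax(-1, r))
  denom <- 1 - r^2
  f <- ifelse(denom <= .Machine$double.eps, Inf,
              r^2 * (n_samp - 2) / denom)
  p <- stats::pf(f, 1, n_samp - 2, lower.tail = FALSE)
  keep <- p < p_thresh
  if (!any(keep)) {
    stop("no co-expressed edges retained at p < ", p_thresh,
         "; module growth is impossible", call. = FALSE)
  }
  df <- data.frame(from = el[idx[keep], 1L], to = el[idx[keep], 2L],
                   pearson_r = r[keep], p_value = p[keep],
                   stringsAsFactors = FALSE)
  net <- igraph::graph_from_data_frame(df, directed = FALSE)
  net <- igraph::set_graph_attr(net, "n_dropped_unmeasured", n_dropped)
  igraph::set_graph_attr(net, "p_thresh", p_thresh)
}
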