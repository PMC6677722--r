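# In silico drug repurposing against a disease module.
#
# Two complementary measures: (i) closest network proximity between drug
# targets T and module genes S, standardized against a null that resamples
# both sets degree-matched; (ii) over-representation of the drug's
# amplitude-derived up/down signature genes among module genes.

#' Differential-expression amplitude
#'
#' `a = (t - c) / ((t + c) / 2)` where t and c are the scaled, thresholded
#' average-difference values of the treatment and control groups.  a = 0
#' means no differential expression; a = 0.67 corresponds to a two-fold
#' induction.  Vectorized; undefined (error) when `t + c = 0`.
#'
#' @param t,c Numeric treatment and control values.
#' @return Numeric amplitude(s).
#' @export
amplitude <- function(t, c) {
  if (any(t + c == 0)) {
    stop("amplitude undefined: t + c = 0", call. = FALSE)
  }
  (t - c) / ((t + c) / 2)
}

#' Build a drug signature from amplitudes
#'
#' Genes with amplitude strictly above `up_threshold` are the up set, those
#' strictly below `-up_threshold` the down set; `|a| <= up_threshold` is
#' excluded (so a = 0.67 at the default threshold is not a signature gene).
#'
#' @param amplitudes Named numeric vector of per-gene amplitudes.
#' @param up_threshold Positive threshold, default 0.67 (two-fold change).
#' @param drug Optional drug identifier.
#' @return Object of class `gps_signature` with `drug`, `up`, `down`.
#' @export
build_signature <- function(amplitudes, up_threshold = 0.67,
                            drug = NA_character_) {
  if (up_threshold <= 0) stop("up_threshold must be positive",
                              call. = FALSE)
  gsig <- function(genes) if (is.null(genes)) character(0) else genes
  structure(list(drug = drug,
                 up = gsig(names(amplitudes)[amplitudes > up_threshold]),
                 down = gsig(names(amplitudes)[amplitudes < -up_threshold])),
            class = "gps_signature")
}

#' Construct a signature from explicit up/down gene sets
#'
#' @param up,down Character vectors (must be disjoint).
#' @param drug Optional drug identifier.
#' @return A `gps_signature`.
#' @export
drug_signature <- function(up, down, drug = NA_character_) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0L) {
    stop("up and down signature sets overlap", call. = FALSE)
  }
  structure(list(drug = drug, up = up, down = down),
            class = "gps_signature")
}

#' Closest network distance from a module to drug targets
#'
#' `d(S, T) = mean over reachable t in T of min_{s in S} d(s, t)` using
#' unweighted shortest-path lengths.  Targets unreachable from S are
#' excluded from the average (reported via attributes) rather than assigned
#' an arbitrary large distance, keeping d finite and comparable.
#'
#' @param graph Interactome igraph object.
#' @param s_genes Module gene set S.
#' @param t_genes Drug target set T.
#' @param dist_matrix Optional precomputed all-pairs distance matrix with
#'   gene dimnames (speeds up permutation nulls).
#' @return Scalar distance with attributes `n_targets` (|T| after
#'   interactome intersection) and `n_reachable`.
#' @export
closest_distance <- function(graph, s_genes, t_genes, dist_matrix = NULL) {
  nodes <- igraph::V(graph)$name
  s_genes <- intersect(unique(as.character(s_genes)), nodes)
  t_genes <- intersect(unique(as.character(t_genes)), nodes)
  if (length(s_genes) == 0L || length(t_genes) == 0L) {
    stop("S and T must be non-empty after interactome intersection",
         call. = FALSE)
  }
  d <- if (is.null(dist_matrix)) {
    igraph::distances(graph, v = s_genes, to = t_genes,
                      algorithm = "unweighted")
  } else {
    dist_matrix[s_genes, t_genes, drop = FALSE]
  }
  mins <- apply(d, 2L, min)
  reachable <- is.finite(mins)
  if (!any(reachable)) {
    stop("no target reachable from the module", call. = FALSE)
  }
  structure(mean(mins[reachable]),
            n_targets = length(t_genes),
            n_reachable = sum(reachable))
}

#' Proximity z-score with a degree-preserving null
#'
#' Standardizes the observed closest distance d(S, T) against a reference
#' distribution obtained by resampling BOTH gene sets degree-matched
#' (`z_d = (d - mean(null)) / sd(null)`), with a two-sided add-one empirical
#' p-value.  Negative z means the drug targets sit closer to the module than
#' degree-matched chance expects.
#'
#' @inheritParams closest_distance
#' @param binning Optional precomputed [degree_binning()].
#' @param n_perm Number of permutations (>= 100; 1000 by default).
#' @return Object of class `gps_proximity`: `distance`, `null_mean`,
#'   `null_sd`, `z_score` (NA with `degenerate_null = TRUE` when the null
#'   has zero spread), `p_value`, `n_permutations`, `n_targets`,
#'   `n_reachable`.
#' @export
proximity_z <- function(graph, s_genes, t_genes, binning = NULL,
                        n_perm = 1000L, dist_matrix = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (is.null(binning)) binning <- degree_binning(graph)
  if (is.null(dist_matrix) && igraph::vcount(graph) <= 2000L) {
    dist_matrix <- igraph::distances(graph, algorithm = "unweighted")
  }
  nodes <- names(binning$bin_of)
  s_genes <- intersect(unique(as.character(s_genes)), nodes)
  t_genes <- intersect(unique(as.character(t_genes)), nodes)
  observed <- closest_distance(graph, s_genes, t_genes, dist_matrix)
  null <- vapply(seq_len(n_perm), function(i) {
    as.numeric(closest_distance(
      graph,
      degree_matched_sample(graph, s_genes, binning),
      degree_matched_sample(graph, t_genes, binning),
      dist_matrix))
  }, numeric(1))
  null_sd <- stats::sd(null)
  degenerate <- is.na(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else
    (as.numeric(observed) - mean(null)) / null_sd
  p_ge <- (1 + sum(null >= observed)) / (1 + n_perm)
  p_le <- (1 + sum(null <= observed)) / (1 + n_perm)
  structure(list(distance = as.numeric(observed),
                 null_mean = mean(null),
                 null_sd = null_sd,
                 z_score = z,
                 degenerate_null = degenerate,
                 p_value = min(1, 2 * min(p_ge, p_le)),
                 n_permutations = n_perm,
                 n_targets = attr(observed, "n_targets"),
                 n_reachable = attr(observed, "n_reachable")),
            class = "gps_proximity")
}

#' @export
print.gps_proximity <- function(x, ...) {
  cat("Network proximity: d = ", format(x$distance, digits = 4),
      " (null ", format(x$null_mean, digits = 4), " +/- ",
      format(x$null_sd, digits = 3), "), z = ",
      format(x$z_score, digits = 3), ", p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Drug-signature over-representation in a module
#'
#' Builds the 2x2 table of module membership versus drug regulation (union
#' of up and down signature genes) over a background gene universe and
#' reports the one-sided hypergeometric over-representation p-value, plus
#' up-only and down-only p-values.
#'
#' @param module_genes Module gene set (subset of `background`).
#' @param signature A `gps_signature`.
#' @param background Background gene universe.
#' @return Object of class `gps_signature_test`: `contingency` (named
#'   4-vector summing to |background|), `p_value`, `p_up`, `p_down`.
#' @export
signature_module_test <- function(module_genes, signature, background) {
  stopifnot(inherits(signature, "gps_signature"))
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  module_genes <- unique(as.character(module_genes))
  if (!all(module_genes %in% background)) {
    stop("module genes must be a subset of the background", call. = FALSE)
  }
  tail_p <- function(reg) {
    reg <- intersect(reg, background)
    if (length(reg) == 0L) return(1)
    q <- length(intersect(module_genes, reg))
    stats::phyper(q - 1, length(reg), length(background) - length(reg),
                  length(module_genes), lower.tail = FALSE)
  }
  reg <- intersect(union(signature$up, signature$down), background)
  overlap <- length(intersect(module_genes, reg))
  contingency <- c(
    module_regulated = overlap,
    module_other = length(module_genes) - overlap,
    nonmodule_regulated = length(reg) - overlap,
    nonmodule_other = length(background) - length(module_genes) -
      length(reg) + overlap
  )
  structure(list(contingency = contingency,
                 p_value = tail_p(reg),
                 p_up = tail_p(signature$up),
                 p_down = tail_p(signature$down)),
            class = "gps_signature_test")
}

#' Ranked in silico repurposing screen
#'
#' Scores every drug in a panel against a disease module by network
#' proximity (when targets are known) and by signature over-representation
#' (when a signature is known); adjusts p-values per method across the
#' panel by Benjamini-Hochberg, flags drugs significant by either method,
#' and ranks by best adjusted p then by proximity z.
#'
#' @param drugs List of drug records; each a list with `drug` (identifier)
#'   and optionally `targets` (character vector) and `signature`
#'   (`gps_signature`).
#' @param module_genes Disease-module gene set.
#' @param graph Interactome igraph object.
#' @param background Background universe for the signature test (default:
#'   all graph nodes).
#' @param binning Optional precomputed [degree_binning()].
#' @param n_perm Permutations per proximity test.
#' @param sig_alpha Adjusted-p cut for the significance flag.
#' @param dist_matrix Optional precomputed all-pairs distance matrix.
#' @return `data.frame` with one row per scorable drug, columns `drug`,
#'   `n_targets`, `distance`, `z`, `proximity_p`, `signature_p`,
#'   `adj_p_proximity`, `adj_p_signature`, `significant`; drugs with
#'   neither usable targets nor signature are listed in attribute
#'   `unscorable`.
#' @export
repurpose_screen <- function(drugs, module_genes, graph,
                             background = igraph::V(graph)$name,
                             binning = NULL, n_perm = 1000L,
                             sig_alpha = 0.05, dist_matrix = NULL) {
  if (length(drugs) == 0L) stop("empty drug panel", call. = FALSE)
  if (is.null(binning)) binning <- degree_binning(graph)
  if (is.null(dist_matrix) && igraph::vcount(graph) <= 2000L) {
    dist_matrix <- igraph::distances(graph, algorithm = "unweighted")
  }
  nodes <- names(binning$bin_of)
  module_genes <- unique(as.character(module_genes))

  rows <- lapply(drugs, function(d) {
    targets <- intersect(as.character(d$targets %||% character(0)), nodes)
    prox <- NULL
    if (length(targets) > 0L) {
      prox <- proximity_z(graph, module_genes, targets, binning, n_perm,
                          dist_matrix)
    }
    sig_p <- NA_real_
    if (!is.null(d$signature)) {
      sig_p <- signature_module_test(intersect(module_genes, background),
                                     d$signature, background)$p_value
    }
    data.frame(drug = d$drug,
               n_targets = length(targets),
               distance = if (is.null(prox)) NA_real_ else prox$distance,
               z = if (is.null(prox)) NA_real_ else prox$z_score,
               proximity_p = if (is.null(prox)) NA_real_ else prox$p_value,
               signature_p = sig_p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  scorable <- !(is.na(tab$proximity_p) & is.na(tab$signature_p))
  unscorable <- tab$drug[!scorable]
  tab <- tab[scorable, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no scorable drug in the panel", call. = FALSE)
  tab$adj_p_proximity <- stats::p.adjust(tab$proximity_p, method = "BH")
  tab$adj_p_signature <- stats::p.adjust(tab$signature_p, method = "BH")
  sig_prox <- !is.na(tab$adj_p_proximity) & tab$adj_p_proximity < sig_alpha
  sig_sig <- !is.na(tab$adj_p_signature) & tab$adj_p_signature < sig_alpha
  tab$significant <- sig_prox | sig_sig
  best <- pmin(tab$adj_p_proximity, tab$adj_p_signature, na.rm = TRUE)
  ord <- order(best, tab$z, tab$drug, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "unscorable") <- unscorable
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
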