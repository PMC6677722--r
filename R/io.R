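# Readers and writers for plain-text exchange formats (GMT, gene lists,
# drug-target tables).

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated genes.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) {
      stop("GMT line with fewer than 3 fields in ", path, call. = FALSE)
    }
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`,
                        character(1), 1L)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-column gene list
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return Character vector of genes.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Read a drug-target table
#'
#' TSV with columns `drug` and `target`.
#'
#' @param path File path.
#' @return Named list: per drug, a character vector of targets.
#' @export
read_drug_targets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("drug", "target") %in% names(tab))) {
    stop("drug-target table must have columns drug, target", call. = FALSE)
  }
  lapply(split(tab$target, tab$drug), unique)
}

#' Read drug signatures from a GMT file
#'
#' Sets named `<drug>_UP` and `<drug>_DOWN` are paired into signatures; a
#' drug may have either or both sets.
#'
#' @param path GMT path.
#' @return Named list of `gps_signature` objects.
#' @export
read_signature_gmt <- function(path) {
  sets <- read_gmt(path)
  is_up <- grepl("_UP$", names(sets))
  is_down <- grepl("_DOWN$", names(sets))
  if (any(!is_up & !is_down)) {
    stop("signature GMT sets must end in _UP or _DOWN", call. = FALSE)
  }
  drugs <- unique(sub("_(UP|DOWN)$", "", names(sets)))
  out <- lapply(drugs, function(d) {
    drug_signature(up = sets[[paste0(d, "_UP")]] %||% character(0),
                   down = sets[[paste0(d, "_DOWN")]] %||% character(0),
                   drug = d)
  })
  stats::setNames(out, drugs)
}

# Writes a TSV with "# key=value" provenance header lines.
.write_tsv_with_header <- function(tab, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0L) writeLines(paste0("# ", header), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
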