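# Tab-separated readers/writers for localization tables, term hierarchies,
# interaction edge lists, a PSI-MITAB 2.5 subset and pathway class tables.
# All files are UTF-8, tab-separated; lines starting with "#" are comments.

#' Read a protein localization table
#'
#' The table has one row per protein: `protein_id TAB term[;term...]`.
#' Duplicate protein rows are merged by the union of their terms, keeping the
#' order of first appearance. An empty terms field yields a record with zero
#' terms (the protein is excluded from the catalog downstream).
#'
#' @param path path to a TSV file.
#' @param term_delim delimiter separating terms inside field 2 (default ";").
#' @return a data.frame with columns `protein_id` (character) and `terms`
#'   (list column of character vectors).
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("P1\tnucleus;cytoplasm", "P2\tnucleus"), tf)
#' read_localization_table(tf)
read_localization_table <- function(path, term_delim = ";") {
  lines <- .read_text_lines(path)
  keep <- !.is_comment_or_blank(lines)
  rows <- .split_tsv(lines[keep])
  lineno <- which(keep)
  ids <- character(0)
  terms <- list()
  for (k in seq_along(rows)) {
    f <- rows[[k]]
    if (length(f) < 2L || !nzchar(f[1L]))
      .stopf("malformed localization row at line %d of %s", lineno[k], path)
    tt <- trimws(strsplit(f[2L], term_delim, fixed = TRUE)[[1L]])
    tt <- tt[nzchar(tt)]
    i <- match(f[1L], ids)
    if (is.na(i)) {
      ids <- c(ids, f[1L])
      terms[[length(ids)]] <- tt
    } else {
      terms[[i]] <- unique(c(terms[[i]], tt))
    }
  }
  data.frame(protein_id = ids, terms = I(terms), stringsAsFactors = FALSE)
}

#' Read a localization term hierarchy
#'
#' Two-column TSV `child_term TAB parent_term`. A term that never appears as a
#' child is a top-level term. Cycles are detected later, while ascending.
#'
#' @param path path to a TSV file.
#' @return named character vector mapping child term to parent term.
#' @export
read_hierarchy_table <- function(path) {
  lines <- .read_text_lines(path)
  rows <- .split_tsv(lines[!.is_comment_or_blank(lines)])
  lineno <- which(!.is_comment_or_blank(lines))
  child <- parent <- character(length(rows))
  for (k in seq_along(rows)) {
    f <- rows[[k]]
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L]))
      .stopf("malformed hierarchy row at line %d of %s", lineno[k], path)
    child[k] <- f[1L]
    parent[k] <- f[2L]
  }
  stats::setNames(parent, child)
}

#' Read protein-protein interactions
#'
#' Supports a plain two-column edge list (optional third column kept as a
#' source tag) and the first two columns of PSI-MITAB 2.5, whose identifiers
#' are `db:accession` pairs -- only the accession is kept (first identifier if
#' a field holds several separated by `|`). Pairs are unordered: exact
#' duplicates, regardless of orientation, collapse to one record; the number
#' collapsed is reported in the read summary. Self-interactions are kept on
#' read; their handling is decided when counting.
#'
#' @param path path to the file.
#' @param format `"edgelist"` or `"mitab"`.
#' @return a data.frame of class `ppi_edges` with columns `protein_a`,
#'   `protein_b`, `source`, carrying a `read_summary` attribute
#'   (`n_records`, `n_duplicates`, `n_skipped`).
#' @export
read_interactions <- function(path, format = c("edgelist", "mitab")) {
  format <- match.arg(format)
  lines <- .read_text_lines(path)
  rows <- .split_tsv(lines[!.is_comment_or_blank(lines)])
  a <- b <- src <- character(0)
  n_skipped <- 0L
  for (f in rows) {
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (format == "mitab") {
      pa <- .mitab_accession(f[1L])
      pb <- .mitab_accession(f[2L])
      if (is.na(pa) || is.na(pb)) {
        .warnf("skipping MITAB row with unparseable identifier: %s | %s",
               f[1L], f[2L])
        n_skipped <- n_skipped + 1L
        next
      }
      a <- c(a, pa); b <- c(b, pb); src <- c(src, NA_character_)
    } else {
      a <- c(a, f[1L]); b <- c(b, f[2L])
      src <- c(src, if (length(f) >= 3L && nzchar(f[3L])) f[3L] else NA_character_)
    }
  }
  if (!length(a)) .stopf("no valid interaction rows in %s", path)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(protein_a = a[!dup], protein_b = b[!dup],
                    source = src[!dup], stringsAsFactors = FALSE)
  class(out) <- c("ppi_edges", "data.frame")
  attr(out, "read_summary") <- list(n_records = nrow(out),
                                    n_duplicates = sum(dup),
                                    n_skipped = n_skipped)
  out
}

.mitab_accession <- function(field) {
  first <- strsplit(field, "|", fixed = TRUE)[[1L]][1L]
  if (is.na(first) || !grepl(":", first, fixed = TRUE)) return(NA_character_)
  acc <- sub("^[^:]+:", "", first)
  # MITAB occasionally quotes accessions
  acc <- gsub('"', "", acc, fixed = TRUE)
  if (!nzchar(acc)) NA_character_ else acc
}

#' Read a pathway-to-functional-class table
#'
#' Two-column TSV `pathway_id TAB class_label`.
#'
#' @param path path to a TSV file.
#' @return named character vector mapping pathway id to class label.
#' @export
read_pathway_classes <- function(path) {
  lines <- .read_text_lines(path)
  rows <- .split_tsv(lines[!.is_comment_or_blank(lines)])
  ids <- vapply(rows, `[`, "", 1L)
  cls <- vapply(rows, function(f) if (length(f) >= 2L) f[2L] else "", "")
  if (any(!nzchar(ids))) .stopf("empty pathway id in %s", path)
  stats::setNames(cls, ids)
}
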