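# KGML (KEGG Markup Language) reader and a minimal writer, plus a plain
# reaction-list TSV representation that can also hold non-PPI chains.

#' Read a KGML pathway file
#'
#' Each `relation` element between two gene-type entries becomes one PPI
#' reaction whose participant slots carry all identifiers of the respective
#' entry (KGML entry `name` attributes may hold several ids). Relations that
#' involve a non-gene entry (compound, map, ...) are dropped and counted in
#' the `n_dropped` attribute. Document order defines reaction order.
#' `reaction` elements (enzyme/compound chemistry) are ignored: the scoring
#' unit here is a protein pair.
#'
#' @param path path to a KGML XML file.
#' @return a `pathway_doc`; if no usable relation exists the document has an
#'   empty reaction list and attribute `flagged = TRUE`.
#' @export
read_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) .stopf("cannot parse KGML file %s: %s",
                                             path, conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing"))
    .stopf("%s is not a KGML document (no <pathway> root)", path)
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid) || !nzchar(pid)) pid <- basename(path)
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- ""

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")
  tokens <- strsplit(names_attr, "[[:space:]]+")
  names(tokens) <- ids
  names(types) <- ids

  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  reactions <- list()
  n_dropped <- 0L
  for (rel in rels) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    t1 <- if (!is.na(e1) && e1 %in% names(types)) types[[e1]] else NA_character_
    t2 <- if (!is.na(e2) && e2 %in% names(types)) types[[e2]] else NA_character_
    if (identical(t1, "gene") && identical(t2, "gene")) {
      reactions[[length(reactions) + 1L]] <-
        reaction(tokens[[e1]], tokens[[e2]], kind = "ppi")
    } else {
      n_dropped <- n_dropped + 1L
    }
  }
  out <- pathway_document(pid, reactions, title = title)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "flagged") <- length(reactions) == 0L
  out
}

#' Write a pathway document as minimal KGML
#'
#' Emits one gene entry per distinct participant set and one `PPrel` relation
#' per reaction. Only all-PPI documents can be expressed in KGML; documents
#' with non-PPI reactions must use [write_reaction_list()].
#'
#' @param doc a `pathway_doc` whose reactions are all `"ppi"`.
#' @param path output file path.
#' @export
write_kgml <- function(doc, path) {
  stopifnot(inherits(doc, "pathway_doc"))
  kinds <- vapply(doc$reactions, `[[`, "", "kind")
  if (any(kinds != "ppi"))
    .stopf("KGML cannot express non-ppi reactions; use write_reaction_list()")
  slot_keys <- character(0)
  entry_id_of <- function(prots) {
    key <- paste(prots, collapse = " ")
    i <- match(key, slot_keys)
    if (is.na(i)) {
      slot_keys <<- c(slot_keys, key)
      i <- length(slot_keys)
    }
    i
  }
  rel <- lapply(doc$reactions, function(r)
    c(entry_id_of(r$p1), entry_id_of(r$p2)))
  x <- xml2::xml_new_root("pathway", name = doc$pathway_id,
                          title = doc$title %||% "")
  for (i in seq_along(slot_keys))
    xml2::xml_add_child(x, "entry", id = as.character(i),
                        name = slot_keys[i], type = "gene")
  for (r in rel)
    xml2::xml_add_child(x, "relation", entry1 = as.character(r[1]),
                        entry2 = as.character(r[2]), type = "PPrel")
  xml2::write_xml(x, path)
  invisible(path)
}

#' Read pathways from a reaction-list table
#'
#' TSV columns: `pathway_id`, `reaction_index`, `kind` (`ppi`/`non-ppi`),
#' `participants1`, `participants2` (each `;`-separated, possibly empty).
#' Rows are grouped into documents by `pathway_id` in order of first
#' appearance; within a pathway rows are ordered by `reaction_index`.
#'
#' @param path path to a TSV file (a header row is detected and skipped).
#' @return list of `pathway_doc`.
#' @export
read_reaction_list <- function(path) {
  lines <- .read_text_lines(path)
  rows <- .split_tsv(lines[!.is_comment_or_blank(lines)])
  if (length(rows) && identical(rows[[1L]][1L], "pathway_id"))
    rows <- rows[-1L]
  if (!length(rows)) return(list())
  pid <- vapply(rows, `[`, "", 1L)
  docs <- list()
  for (id in unique(pid)) {
    rr <- rows[pid == id]
    idx <- as.integer(vapply(rr, `[`, "", 2L))
    rr <- rr[order(idx)]
    reactions <- lapply(rr, function(f) {
      if (length(f) < 5L)
        .stopf("reaction-list row for pathway %s has fewer than 5 fields", id)
      split_p <- function(s) {
        p <- strsplit(s, ";", fixed = TRUE)[[1L]]
        p[nzchar(p)]
      }
      reaction(split_p(f[4L]), split_p(f[5L]),
               kind = if (identical(f[3L], "non-ppi")) "non-ppi" else "ppi")
    })
    docs[[length(docs) + 1L]] <- pathway_document(id, reactions)
  }
  docs
}

#' Write pathways as a reaction-list table
#'
#' @param docs a `pathway_doc` or list of them.
#' @param path output TSV path.
#' @export
write_reaction_list <- function(docs, path) {
  if (inherits(docs, "pathway_doc")) docs <- list(docs)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("pathway_id\treaction_index\tkind\tparticipants1\tparticipants2",
             con)
  for (d in docs) {
    for (r in d$reactions) {
      writeLines(paste(d$pathway_id, r$index, r$kind,
                       paste(r$p1, collapse = ";"),
                       paste(r$p2, collapse = ";"), sep = "\t"), con)
    }
  }
  invisible(path)
}
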