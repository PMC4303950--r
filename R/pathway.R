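# Pathway documents and reactions: the unit the scoring engine consumes.

#' Construct a pathway reaction
#'
#' A reaction has two participant slots, each a (possibly multi-protein)
#' character vector. Direct protein-protein interactions (`kind = "ppi"`)
#' need both slots non-empty; non-PPI steps (conversions, state changes)
#' may carry their participants in one slot and are scored against the next
#' reaction in the pathway.
#'
#' @param p1,p2 character vectors of protein ids (either may be empty for a
#'   non-PPI reaction).
#' @param kind `"ppi"` or `"non-ppi"`.
#' @param index ordinal position within the pathway (assigned by
#'   [pathway_document()] if `NA`).
#' @return a `pw_reaction` list.
#' @export
reaction <- function(p1, p2 = character(0), kind = c("ppi", "non-ppi"),
                     index = NA_integer_) {
  kind <- match.arg(kind)
  p1 <- as.character(p1); p2 <- as.character(p2)
  if (kind == "ppi" && (!length(p1) || !length(p2)))
    .stopf("a ppi reaction needs both participant slots non-empty")
  structure(list(index = index, p1 = p1, p2 = p2, kind = kind),
            class = "pw_reaction")
}

#' Construct a pathway document
#'
#' @param pathway_id unique pathway id.
#' @param reactions list of [reaction()] objects; order is the pathway order
#'   and is preserved exactly.
#' @param title optional display title.
#' @param class_label optional functional class label.
#' @return a `pathway_doc` list.
#' @export
pathway_document <- function(pathway_id, reactions = list(), title = "",
                             class_label = NA_character_) {
  stopifnot(is.character(pathway_id), nzchar(pathway_id))
  for (q in seq_along(reactions)) reactions[[q]]$index <- q
  structure(list(pathway_id = pathway_id, title = title,
                 reactions = reactions, class_label = class_label),
            class = "pathway_doc")
}

#' @export
print.pathway_doc <- function(x, ...) {
  kinds <- vapply(x$reactions, `[[`, "", "kind")
  cat(sprintf("Pathway %s%s: %d reactions (%d ppi, %d non-ppi)\n",
              x$pathway_id,
              if (nzchar(x$title %||% "")) paste0(" [", x$title, "]") else "",
              length(x$reactions), sum(kinds == "ppi"), sum(kinds != "ppi")))
  invisible(x)
}

# all distinct proteins occurring in a document or reaction list
pathway_proteins <- function(x) {
  rx <- if (inherits(x, "pathway_doc")) x$reactions else x
  unique(unlist(lapply(rx, function(r) c(r$p1, r$p2)), use.names = FALSE))
}

# proteins of all pathways in a collection
collection_proteins <- function(docs) {
  unique(unlist(lapply(docs, pathway_proteins), use.names = FALSE))
}
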