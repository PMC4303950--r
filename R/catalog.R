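# Localization catalog: collapse annotation terms to top-level compartments
# and restrict to the analysis compartment set.

#' Build a localization catalog at the top hierarchy level
#'
#' Each protein's localization terms are replaced by their top-level ancestors
#' in the term hierarchy: annotations of nested sub-locations are added to the
#' highest-level location that contains them. A term absent from the hierarchy
#' as a child is itself top-level. Duplicated ancestors collapse to a set, so
#' a protein counts once per compartment however many nested terms point
#' there. Proteins with no terms end up with empty membership and are listed
#' in the catalog's `excluded` field.
#'
#' @param records data.frame from [read_localization_table()] (columns
#'   `protein_id`, list column `terms`).
#' @param hierarchy named character vector mapping child term to parent term
#'   (see [read_hierarchy_table()]), or `NULL` if all terms are top-level.
#' @return an object of class `loc_catalog`: list with `compartments`
#'   (ordered labels), `membership` (named list protein -> compartment set),
#'   `sizes` (named protein counts per compartment) and `excluded`
#'   (proteins with empty membership).
#' @export
collapse_to_top_level <- function(records, hierarchy = NULL) {
  stopifnot(is.data.frame(records), all(c("protein_id", "terms") %in% names(records)))
  resolve <- function(term) {
    seen <- character(0)
    while (!is.null(hierarchy) && term %in% names(hierarchy)) {
      if (term %in% seen)
        .stopf("cycle in localization hierarchy at term '%s'", term)
      seen <- c(seen, term)
      term <- unname(hierarchy[[term]])
    }
    term
  }
  membership <- lapply(records$terms, function(tt) {
    if (!length(tt)) return(character(0))
    unique(vapply(tt, resolve, "", USE.NAMES = FALSE))
  })
  names(membership) <- records$protein_id
  new_loc_catalog(membership)
}

#' @keywords internal
new_loc_catalog <- function(membership) {
  empty <- lengths(membership) == 0L
  excluded <- names(membership)[empty]
  membership <- membership[!empty]
  compartments <- unique(unlist(membership, use.names = FALSE)) %||% character(0)
  sizes <- vapply(compartments, function(L)
    sum(vapply(membership, function(m) L %in% m, NA)), 0L)
  structure(list(compartments = compartments,
                 membership = membership,
                 sizes = stats::setNames(as.integer(sizes), compartments),
                 excluded = excluded),
            class = "loc_catalog")
}

#' @export
print.loc_catalog <- function(x, ...) {
  cat(sprintf("Localization catalog: %d proteins, %d compartments\n",
              length(x$membership), length(x$compartments)))
  if (length(x$sizes)) {
    ord <- order(-x$sizes, names(x$sizes))
    print(x$sizes[ord])
  }
  if (length(x$excluded))
    cat(sprintf("%d proteins excluded (no localization)\n", length(x$excluded)))
  invisible(x)
}

#' Restrict a catalog to compartments with enough interaction-covered proteins
#'
#' A compartment is retained when strictly more than `min_proteins` of its
#' member proteins occur in at least one interaction record (any partner).
#' Memberships are restricted to retained compartments; proteins left with no
#' compartment are excluded. The selection report (attribute `selection`)
#' lists retained and dropped compartments with their covered counts.
#'
#' @param catalog a `loc_catalog`.
#' @param interactions a `ppi_edges` data.frame (or any data.frame with
#'   `protein_a`, `protein_b`).
#' @param min_proteins retention threshold; compartments must exceed it
#'   (default 200, the analysis default for a genome-scale interactome).
#' @return restricted `loc_catalog` with a `selection` attribute.
#' @export
select_compartments <- function(catalog, interactions, min_proteins = 200) {
  stopifnot(inherits(catalog, "loc_catalog"), min_proteins >= 0)
  covered <- unique(c(interactions$protein_a, interactions$protein_b))
  cov_count <- vapply(catalog$compartments, function(L)
    sum(vapply(names(catalog$membership), function(p)
      L %in% catalog$membership[[p]] && p %in% covered, NA)), 0L)
  names(cov_count) <- catalog$compartments
  retained <- catalog$compartments[cov_count > min_proteins]
  if (!length(retained))
    .stopf(paste("no compartment has more than %d interaction-covered proteins;",
                 "lower min_proteins"), min_proteins)
  membership <- lapply(catalog$membership, function(m) intersect(m, retained))
  out <- new_loc_catalog(membership)
  # preserve retained-compartment order as in the parent catalog
  out$compartments <- retained[retained %in% out$compartments]
  out$sizes <- out$sizes[out$compartments]
  out$excluded <- union(catalog$excluded, out$excluded)
  attr(out, "selection") <- list(
    retained = stats::setNames(cov_count[retained], retained),
    dropped = cov_count[setdiff(catalog$compartments, retained)],
    min_proteins = min_proteins)
  out
}
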