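# Per-reaction efficiencies and the pathway mean efficiency Eff.

#' Efficiency of one reaction
#'
#' Collects `E(la, lb)` over every protein pair `(a in p1, b in p2)` and
#' every localization pair `la` in membership(a), `lb` in membership(b),
#' then aggregates with the combine rule: `"mean"` treats the compartment
#' routes as equally likely, `"max"` scores the best available route. If no
#' value can be collected (no participant on either side has membership) the
#' reaction is skipped and `NA` is returned.
#'
#' @param p1,p2 character vectors of protein ids (the two participant slots).
#' @param matrix an `eff_matrix`.
#' @param catalog the matching `loc_catalog`.
#' @param combine `"mean"` or `"max"`.
#' @return a single efficiency in `[0, 1]`, or `NA_real_` (skip marker).
#' @export
reaction_efficiency <- function(p1, p2, matrix, catalog,
                                combine = c("mean", "max")) {
  combine <- match.arg(combine)
  stopifnot(inherits(matrix, "eff_matrix"), inherits(catalog, "loc_catalog"))
  mem_idx <- lapply(catalog$membership, function(m) match(m, matrix$labels))
  .reaction_eff_idx(as.character(p1), as.character(p2),
                    matrix$values, mem_idx, combine)
}

# internal hot path: membership already resolved to matrix row indices
.reaction_eff_idx <- function(p1, p2, E, mem_idx, combine) {
  vals <- NULL
  for (a in p1) {
    ia <- mem_idx[[a]]
    if (is.null(ia) || !length(ia) || anyNA(ia)) next
    for (b in p2) {
      ib <- mem_idx[[b]]
      if (is.null(ib) || !length(ib) || anyNA(ib)) next
      vals <- c(vals, E[ia, ib])
    }
  }
  if (is.null(vals)) return(NA_real_)
  if (combine == "mean") mean(vals) else max(vals)
}

#' Efficiency profile of a pathway
#'
#' PPI reactions are scored within-reaction (slot 1 against slot 2). A
#' non-PPI reaction `Rq` is scored between its participants and those of the
#' following reaction `Rq+1`; the last reaction of a pathway, if non-PPI,
#' contributes nothing. Lookups that return the skip marker are excluded
#' from `N`; the pathway mean efficiency `Eff` is the arithmetic mean over
#' the `N` scored reactions. A pathway with `N == 0` is flagged unusable.
#'
#' @param doc a `pathway_doc`.
#' @inheritParams reaction_efficiency
#' @return object of class `eff_profile`: list with `pathway_id`,
#'   `reaction_efficiencies` (scored values, in pathway order), `n_scored`,
#'   `n_skipped`, `mean_eff` and `usable`.
#' @export
pathway_profile <- function(doc, matrix, catalog, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  stopifnot(inherits(doc, "pathway_doc"))
  mem_idx <- lapply(catalog$membership, function(m) match(m, matrix$labels))
  .pathway_profile_idx(doc, matrix$values, mem_idx, combine)
}

.pathway_profile_idx <- function(doc, E, mem_idx, combine) {
  rx <- doc$reactions
  n <- length(rx)
  effs <- numeric(0)
  n_skipped <- 0L
  for (q in seq_len(n)) {
    r <- rx[[q]]
    if (r$kind == "ppi") {
      v <- .reaction_eff_idx(r$p1, r$p2, E, mem_idx, combine)
    } else {
      if (q == n) next # last non-ppi reaction has no successor
      nxt <- rx[[q + 1L]]
      v <- .reaction_eff_idx(unique(c(r$p1, r$p2)),
                             unique(c(nxt$p1, nxt$p2)), E, mem_idx, combine)
    }
    if (is.na(v)) n_skipped <- n_skipped + 1L else effs <- c(effs, v)
  }
  structure(list(pathway_id = doc$pathway_id,
                 class_label = doc$class_label,
                 reaction_efficiencies = effs,
                 n_scored = length(effs),
                 n_skipped = n_skipped,
                 mean_eff = if (length(effs)) mean(effs) else NA_real_,
                 usable = length(effs) > 0L),
            class = "eff_profile")
}

#' @export
print.eff_profile <- function(x, ...) {
  cat(sprintf("Pathway %s: N = %d scored reactions (%d skipped), Eff = %s\n",
              x$pathway_id, x$n_scored, x$n_skipped,
              if (x$usable) sprintf("%.4g", x$mean_eff) else "NA (unusable)"))
  invisible(x)
}

#' Score a pathway collection
#'
#' @param docs list of `pathway_doc`.
#' @inheritParams reaction_efficiency
#' @return data.frame with one row per pathway (`pathway_id`, `class_label`,
#'   `n_reactions`, `n_scored`, `n_skipped`, `mean_eff`, `usable`) in input
#'   order; attribute `profiles` holds the full `eff_profile` list and
#'   attribute `totals` the summary counts.
#' @export
score_pathways <- function(docs, matrix, catalog, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  mem_idx <- lapply(catalog$membership, function(m) match(m, matrix$labels))
  profiles <- lapply(docs, .pathway_profile_idx, E = matrix$values,
                     mem_idx = mem_idx, combine = combine)
  out <- data.frame(
    pathway_id = vapply(profiles, `[[`, "", "pathway_id"),
    class_label = vapply(profiles, function(p) p$class_label %||% NA_character_, ""),
    n_reactions = vapply(docs, function(d) length(d$reactions), 0L),
    n_scored = vapply(profiles, `[[`, 0L, "n_scored"),
    n_skipped = vapply(profiles, `[[`, 0L, "n_skipped"),
    mean_eff = vapply(profiles, `[[`, 0, "mean_eff"),
    usable = vapply(profiles, `[[`, NA, "usable"),
    stringsAsFactors = FALSE)
  attr(out, "profiles") <- profiles
  attr(out, "totals") <- list(n_pathways = nrow(out),
                              n_scored = sum(out$n_scored),
                              n_skipped = sum(out$n_skipped))
  out
}

#' Long-format table of per-reaction efficiencies
#'
#' One row per scored reaction, suitable for histogram construction and for
#' the clustering stage's file interface.
#'
#' @param profiles a profiles table from [score_pathways()], or a list of
#'   `eff_profile`.
#' @return data.frame with columns `pathway_id`, `scored_index`,
#'   `efficiency`.
#' @export
reaction_table <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- attr(profiles, "profiles")
  stopifnot(is.list(profiles))
  do.call(rbind, lapply(profiles, function(p) {
    if (!p$n_scored) return(NULL)
    data.frame(pathway_id = p$pathway_id,
               scored_index = seq_len(p$n_scored),
               efficiency = p$reaction_efficiencies,
               stringsAsFactors = FALSE)
  })) %||% data.frame(pathway_id = character(0), scored_index = integer(0),
                      efficiency = numeric(0))
}
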