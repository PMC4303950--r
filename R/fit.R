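# Front door: fit the compartment efficiency model from an interactome and
# a localization catalog, returning a classed object with the usual methods.

#' Fit a compartment efficiency model
#'
#' Runs the full estimation chain: collapse localization annotations to
#' top-level compartments, keep compartments with strictly more than
#' `min_proteins` proteins covered by the interactome, count intra/
#' inter-compartmental interactions, and form the symmetric efficiency
#' matrix `E(Li,Lj) = P(Li,Lj) / (mi * mj)` -- the observed interaction
#' frequency per protein pair, used downstream as a proxy for the efficiency
#' of a reaction between proteins located in `Li` and `Lj`.
#'
#' @param interactions `ppi_edges` data.frame (see [read_interactions()]).
#' @param localizations localization records data.frame (see
#'   [read_localization_table()]), or an existing `loc_catalog`.
#' @param hierarchy optional named child->parent term vector
#'   (see [read_hierarchy_table()]).
#' @param min_proteins compartment retention threshold (strictly-greater
#'   rule; default 200).
#' @param include_self count self-interactions on the diagonal (default
#'   `FALSE`).
#' @return an object of class `comp_eff`: list with `matrix` (an
#'   `eff_matrix`), `catalog`, `counts`, `report` (coverage and skip
#'   tallies) and `call`.
#' @seealso [predict.comp_eff()] to score pathways,
#'   [diagonal_dominance()], [enrichment_ratio()].
#' @export
#' @examples
#' sim <- simulate_interactome(c(A = 40, B = 40), p0 = 0.05,
#'                             within_enrichment = 3, seed = 1)
#' fit <- compartment_efficiency(sim$interactions, sim$localizations,
#'                               min_proteins = 5)
#' summary(fit)
compartment_efficiency <- function(interactions, localizations,
                                   hierarchy = NULL, min_proteins = 200,
                                   include_self = FALSE) {
  catalog <- if (inherits(localizations, "loc_catalog")) localizations
             else collapse_to_top_level(localizations, hierarchy)
  catalog <- select_compartments(catalog, interactions, min_proteins)
  counts <- count_interactions(interactions, catalog, include_self)
  E <- build_efficiency_matrix(counts, catalog)
  prot_ppi <- unique(c(interactions$protein_a, interactions$protein_b))
  report <- list(
    n_interactions = nrow(interactions),
    n_proteins_interactome = length(prot_ppi),
    n_proteins_catalog = length(catalog$membership),
    n_proteins_shared = sum(prot_ppi %in% names(catalog$membership)),
    skipped = counts$skipped,
    selection = attr(catalog, "selection"))
  structure(list(matrix = E, catalog = catalog, counts = counts,
                 report = report, call = match.call()),
            class = "comp_eff")
}

#' @export
print.comp_eff <- function(x, ...) {
  cat("Compartment efficiency model\n")
  cat(sprintf("  compartments: %d (%s%s)\n", length(x$matrix$labels),
              paste(utils::head(x$matrix$labels, 5), collapse = ", "),
              if (length(x$matrix$labels) > 5) ", ..." else ""))
  cat(sprintf("  proteins in catalog: %d (of %d in interactome, %d shared)\n",
              x$report$n_proteins_catalog, x$report$n_proteins_interactome,
              x$report$n_proteins_shared))
  cat(sprintf("  interactions: %d (skipped: %d no membership, %d self)\n",
              x$report$n_interactions, x$report$skipped["no_membership"],
              x$report$skipped["self"]))
  invisible(x)
}

#' @export
coef.comp_eff <- function(object, ...) object$matrix$values

#' @export
as.matrix.comp_eff <- function(x, ...) x$matrix$values

#' Summary of a compartment efficiency fit
#'
#' Reports the efficiency matrix, per-compartment diagonal dominance and the
#' within/between enrichment ratio.
#'
#' @param object a `comp_eff` fit.
#' @param ... unused.
#' @export
summary.comp_eff <- function(object, ...) {
  structure(list(matrix = object$matrix,
                 dominance = diagonal_dominance(object$matrix),
                 enrichment = enrichment_ratio(object$matrix),
                 report = object$report),
            class = "summary.comp_eff")
}

#' @export
print.summary.comp_eff <- function(x, digits = 4, ...) {
  print(x$matrix, digits = digits)
  cat("\nDiagonal dominance:\n")
  print(x$dominance, digits = digits)
  viol <- attr(x$dominance, "violations")
  if (length(viol))
    cat("Non-dominant compartments:", paste(viol, collapse = ", "), "\n")
  cat(sprintf("\nWithin/between enrichment ratio: %.3f\n", x$enrichment$ratio))
  invisible(x)
}

#' Heatmap of the efficiency matrix
#'
#' @param x a `comp_eff` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.comp_eff <- function(x, ...) {
  E <- x$matrix$values
  K <- nrow(E)
  graphics::image(seq_len(K), seq_len(K), t(E[K:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Compartment efficiency matrix", ...)
  graphics::axis(1, at = seq_len(K), labels = x$matrix$labels, las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(K), labels = rev(x$matrix$labels), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Score pathways with a fitted efficiency model
#'
#' @param object a `comp_eff` fit.
#' @param pathways a list of pathway documents (see [read_kgml()],
#'   [read_reaction_list()], [simulate_pathways()]).
#' @param combine aggregation over localization routes, `"mean"` or `"max"`.
#' @param ... unused.
#' @return the profiles table from [score_pathways()].
#' @export
predict.comp_eff <- function(object, pathways, combine = c("mean", "max"), ...) {
  score_pathways(pathways, object$matrix, object$catalog,
                 combine = match.arg(combine))
}
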