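# Synthetic-data generator: compartmentalized interactomes and pathway
# collections with known ground truth.

#' Simulate a compartmentalized interactome
#'
#' Proteins are assigned one compartment each (a fraction
#' `multi_loc_fraction` receives a second, distinct one). Every unordered
#' protein pair interacts independently: with probability
#' `within_enrichment * p0` when the pair shares at least one compartment,
#' with probability `p0` otherwise. `within_enrichment` may be a vector with
#' one value per compartment (pairs sharing several compartments use the
#' largest applicable value). The ground-truth summary records the expected
#' within/between per-pair rate ratio, which equals `within_enrichment`
#' under single localization -- the quantity [enrichment_ratio()] estimates.
#'
#' @param compartment_sizes named integer vector of proteins per compartment
#'   (unnamed vectors get labels `C01`, `C02`, ...).
#' @param p0 baseline per-pair interaction probability, in (0, 1).
#' @param within_enrichment enrichment factor `rho >= 1`, scalar or one per
#'   compartment; `max(rho) * p0` must not exceed 1.
#' @param multi_loc_fraction fraction of proteins assigned a second
#'   compartment (default 0).
#' @param seed optional integer seed; identical seeds give identical output.
#' @return list with `localizations` (records data.frame as from
#'   [read_localization_table()]), `interactions` (`ppi_edges`), and `truth`
#'   (spec echo plus `expected_enrichment`).
#' @export
simulate_interactome <- function(compartment_sizes, p0,
                                 within_enrichment = 1,
                                 multi_loc_fraction = 0, seed = NULL) {
  K <- length(compartment_sizes)
  stopifnot(K >= 1, all(compartment_sizes >= 1), p0 > 0, p0 < 1,
            all(within_enrichment >= 1),
            multi_loc_fraction >= 0, multi_loc_fraction <= 1)
  rho <- rep_len(as.numeric(within_enrichment), K)
  if (max(rho) * p0 > 1)
    .stopf("within_enrichment * p0 exceeds 1 (not a probability)")
  labs <- names(compartment_sizes)
  if (is.null(labs)) labs <- sprintf("C%02d", seq_len(K))
  n <- sum(compartment_sizes)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs * p0 * max(rho) > 1e7)
    .stopf("expected edge count above 1e7; use a smaller specification")
  if (!is.null(seed)) set.seed(seed)

  comp1 <- rep.int(seq_len(K), compartment_sizes)
  comp2 <- rep(NA_integer_, n)
  if (multi_loc_fraction > 0 && K >= 2) {
    idx <- which(stats::runif(n) < multi_loc_fraction)
    if (length(idx))
      comp2[idx] <- ((comp1[idx] - 1L +
                      sample.int(K - 1L, length(idx), replace = TRUE)) %% K) + 1L
  }
  ids <- sprintf("SP%05d", seq_len(n))

  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L))) + i
  same <- function(a, b) !is.na(a) & !is.na(b) & a == b
  # rho of the shared compartment; max over shared compartments, NA if none
  rho_pair <- pmax(ifelse(same(comp1[i], comp1[j]), rho[comp1[i]], NA),
                   ifelse(same(comp1[i], comp2[j]), rho[comp1[i]], NA),
                   ifelse(same(comp2[i], comp1[j]), rho[comp2[i]], NA),
                   ifelse(same(comp2[i], comp2[j]), rho[comp2[i]], NA),
                   na.rm = TRUE)
  p <- ifelse(is.na(rho_pair), p0, rho_pair * p0)
  keep <- stats::runif(length(i)) < p
  edges <- data.frame(protein_a = ids[i[keep]], protein_b = ids[j[keep]],
                      source = NA_character_, stringsAsFactors = FALSE)
  class(edges) <- c("ppi_edges", "data.frame")
  attr(edges, "read_summary") <- list(n_records = nrow(edges),
                                      n_duplicates = 0L, n_skipped = 0L)

  terms <- ifelse(is.na(comp2), labs[comp1],
                  paste(labs[comp1], labs[comp2], sep = ";"))
  locs <- data.frame(protein_id = ids,
                     terms = I(strsplit(terms, ";", fixed = TRUE)),
                     stringsAsFactors = FALSE)
  truth <- list(compartment_sizes = stats::setNames(as.integer(compartment_sizes), labs),
                p0 = p0, within_enrichment = stats::setNames(rho, labs),
                multi_loc_fraction = multi_loc_fraction, seed = seed,
                expected_enrichment = if (length(unique(rho)) == 1L) rho[1L] else mean(rho),
                n_proteins = n, n_edges = nrow(edges))
  list(localizations = locs, interactions = edges, truth = truth)
}

#' Simulate a pathway collection with tunable colocalization bias
#'
#' Each reaction is a protein pair drawn from the catalog: the first protein
#' uniformly, the second with odds multiplied by `colocalization_bias` for
#' proteins sharing at least one compartment with the first. With
#' `colocalization_bias = 1` the pathways are localization-blind, matching
#' the assumption of the permutation nulls.
#'
#' @param n_pathways number of pathways.
#' @param reactions_per_pathway a count, or a length-2 range sampled
#'   uniformly per pathway.
#' @param catalog a `loc_catalog` supplying the protein universe and
#'   memberships.
#' @param colocalization_bias odds multiplier `beta >= 1` (default 1).
#' @param class_labels optional labels cycled over pathways.
#' @param seed optional integer seed.
#' @param prefix id prefix (default `"SIMPW"`).
#' @return list of `pathway_doc` (all reactions `"ppi"`, single-protein
#'   slots).
#' @export
simulate_pathways <- function(n_pathways, reactions_per_pathway, catalog,
                              colocalization_bias = 1, class_labels = NULL,
                              seed = NULL, prefix = "SIMPW") {
  stopifnot(inherits(catalog, "loc_catalog"), n_pathways >= 1,
            all(reactions_per_pathway >= 1), colocalization_bias >= 1)
  pool <- names(catalog$membership)
  if (length(pool) < 2L) .stopf("catalog must contain at least 2 proteins")
  if (!is.null(seed)) set.seed(seed)
  mem <- catalog$membership
  # per-compartment membership masks over the pool, to weight colocalized draws
  comp_mask <- lapply(catalog$compartments, function(L)
    vapply(mem, function(m) L %in% m, NA))
  names(comp_mask) <- catalog$compartments
  docs <- vector("list", n_pathways)
  for (pw in seq_len(n_pathways)) {
    nr <- if (length(reactions_per_pathway) > 1L)
      sample(seq(reactions_per_pathway[1L], reactions_per_pathway[2L]), 1L)
    else reactions_per_pathway
    rx <- vector("list", nr)
    for (q in seq_len(nr)) {
      ai <- sample.int(length(pool), 1L)
      a <- pool[ai]
      w <- rep(1, length(pool))
      if (colocalization_bias > 1) {
        shares <- Reduce(`|`, comp_mask[mem[[a]]])
        w[shares] <- colocalization_bias
      }
      w[ai] <- 0
      b <- pool[sample.int(length(pool), 1L, prob = w)]
      rx[[q]] <- reaction(a, b, kind = "ppi")
    }
    cl <- if (!is.null(class_labels))
      class_labels[(pw - 1L) %% length(class_labels) + 1L] else NA_character_
    docs[[pw]] <- pathway_document(sprintf("%s%04d", prefix, pw), rx,
                                   class_label = cl)
  }
  docs
}
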