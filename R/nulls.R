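# Permutation null models and the statistical comparisons used against them.

#' Randomize reactions by independent protein replacement
#'
#' Every protein occurrence in every reaction is replaced independently by a
#' uniform draw from the pool. Reaction count, slot arities and reaction
#' kinds are preserved.
#'
#' @param reactions a `pathway_doc` or a flat list of [reaction()] objects.
#' @param pool character vector of replacement protein ids.
#' @param seed optional integer seed (reproducible given the seed).
#' @return same structure as the input with proteins replaced.
#' @export
randomize_reactions <- function(reactions, pool, seed = NULL) {
  if (!length(pool)) .stopf("replacement pool is empty")
  doc <- NULL
  if (inherits(reactions, "pathway_doc")) {
    doc <- reactions
    reactions <- doc$reactions
  }
  if (!is.null(seed)) set.seed(seed)
  arity <- vapply(reactions, function(r) length(r$p1) + length(r$p2), 0L)
  repl <- pool[sample.int(length(pool), sum(arity), replace = TRUE)]
  at <- 0L
  out <- lapply(reactions, function(r) {
    n1 <- length(r$p1); n2 <- length(r$p2)
    r$p1 <- repl[at + seq_len(n1)]
    r$p2 <- repl[at + n1 + seq_len(n2)]
    at <<- at + n1 + n2
    r
  })
  if (!is.null(doc)) {
    doc$reactions <- out
    return(doc)
  }
  out
}

#' Randomize a pathway by consistent protein substitution
#'
#' A single substitution map from the pathway's distinct proteins into the
#' pool is drawn and applied everywhere: a protein involved in several
#' reactions is replaced in all of them by the same random protein. The map
#' is injective (uniform over injections) by default, preserving the
#' pathway's distinct-protein structure; `allow_collisions = TRUE` uses
#' independent uniform draws instead.
#'
#' @param doc a `pathway_doc`.
#' @param pool character vector of replacement ids; without collisions it
#'   must be at least as large as the pathway's distinct protein set.
#' @param seed optional integer seed.
#' @param allow_collisions may two distinct proteins map to the same
#'   replacement? Default `FALSE`.
#' @return a `pathway_doc` with identical structure and substituted ids.
#' @export
randomize_pathway <- function(doc, pool, seed = NULL, allow_collisions = FALSE) {
  stopifnot(inherits(doc, "pathway_doc"))
  dp <- pathway_proteins(doc)
  if (!allow_collisions && length(pool) < length(dp))
    .stopf("pool (%d) smaller than the pathway's distinct protein set (%d)",
           length(pool), length(dp))
  if (!is.null(seed)) set.seed(seed)
  map <- pool[sample.int(length(pool), length(dp), replace = allow_collisions)]
  names(map) <- dp
  doc$reactions <- lapply(doc$reactions, function(r) {
    r$p1 <- unname(map[r$p1])
    r$p2 <- unname(map[r$p2])
    r
  })
  doc
}

#' Binned two-sample chi-square comparison
#'
#' Bins both samples on shared edges (either supplied, or pooled-quantile
#' edges) and tests the 2 x B contingency table with the chi-square
#' statistic, `df = B - 1`. Bins whose smaller expected count falls below
#' `min_expected` are merged into their right neighbour (leftward for the
#' last bin); merges are logged.
#'
#' @param sample_a,sample_b numeric samples (non-empty).
#' @param bins number of pooled-quantile bins when `edges` is `NULL`
#'   (default 20).
#' @param edges optional fixed bin edges (strictly increasing).
#' @param min_expected expected-count threshold for merging (default 5).
#' @return object of class `binned_chisq`: list with `bin_edges`,
#'   `observed_a`, `observed_b`, `statistic`, `df`, `p_value`, `merge_log`.
#' @export
chi_square_binned <- function(sample_a, sample_b, bins = 20, edges = NULL,
                              min_expected = 5) {
  if (!length(sample_a) || !length(sample_b))
    .stopf("both samples must be non-empty")
  if (is.null(edges)) {
    edges <- unique(stats::quantile(c(sample_a, sample_b),
                                    probs = seq(0, 1, length.out = bins + 1),
                                    names = FALSE, type = 7))
  }
  if (any(diff(edges) <= 0)) edges <- unique(sort(edges))
  if (length(edges) < 3L)
    .stopf("samples too small for binned test (fewer than 2 bins)")
  bin_of <- function(x) findInterval(x, edges, rightmost.closed = TRUE,
                                     all.inside = TRUE)
  oa <- tabulate(bin_of(sample_a), nbins = length(edges) - 1L)
  ob <- tabulate(bin_of(sample_b), nbins = length(edges) - 1L)
  merge_log <- character(0)
  repeat {
    B <- length(oa)
    pooled <- oa + ob
    nA <- sum(oa); nB <- sum(ob); n <- nA + nB
    expected_min <- pmin(nA, nB) * pooled / n
    bad <- which(expected_min < min_expected)
    if (!length(bad) || B <= 2L) break
    i <- bad[1L]
    j <- if (i < B) i + 1L else i - 1L
    lo <- min(i, j)
    merge_log <- c(merge_log,
                   sprintf("merged bin %d [%.6g,%.6g) into bin %d", i,
                           edges[i], edges[i + 1L], j))
    oa[lo] <- oa[lo] + oa[lo + 1L]; oa <- oa[-(lo + 1L)]
    ob[lo] <- ob[lo] + ob[lo + 1L]; ob <- ob[-(lo + 1L)]
    edges <- edges[-(lo + 1L)]
  }
  B <- length(oa)
  if (B < 2L) .stopf("samples too small for binned test (fewer than 2 bins)")
  O <- rbind(oa, ob)
  Ex <- outer(rowSums(O), colSums(O)) / sum(O)
  keep <- colSums(O) > 0
  stat <- sum((O[, keep] - Ex[, keep])^2 / Ex[, keep])
  df <- sum(keep) - 1L
  structure(list(bin_edges = edges, observed_a = oa, observed_b = ob,
                 statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 merge_log = merge_log),
            class = "binned_chisq")
}

#' @export
print.binned_chisq <- function(x, ...) {
  cat(sprintf("Binned chi-square: X2 = %.4g, df = %d, p = %.3g (%d bins%s)\n",
              x$statistic, x$df, x$p_value, length(x$observed_a),
              if (length(x$merge_log)) sprintf(", %d merges", length(x$merge_log))
              else ""))
  invisible(x)
}

#' Pearson correlation between pathway length and efficiency
#'
#' Pathway length is the scored reaction count `N`; unusable pathways
#' (`N == 0`) are excluded.
#'
#' @param profiles a profiles table from [score_pathways()].
#' @return list with `r`, `p_value`, `n`.
#' @export
length_efficiency_correlation <- function(profiles) {
  use <- profiles[profiles$n_scored > 0L, , drop = FALSE]
  if (nrow(use) < 3L)
    .stopf("need at least 3 usable pathways for a correlation")
  if (stats::sd(use$n_scored) == 0)
    .stopf("all pathway lengths identical: correlation undefined")
  ct <- stats::cor.test(use$n_scored, use$mean_eff, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(use))
}

#' Compare real pathways against permutation nulls
#'
#' Scores the real collection, then (a) `n_reaction_sets` independent-
#' replacement randomizations of every pathway's reactions, pooling the
#' resulting reaction efficiencies, and (b) `n_random` consistent-
#' substitution randomizations per pathway, collecting their mean
#' efficiencies `Eff`. Both nulls use exactly the same scoring path as the
#' real pathways (including the non-PPI consecutive-reaction rule). Child
#' seeds are derived per (pathway, draw) from the root seed, so results do
#' not depend on collection order.
#'
#' @param docs list of `pathway_doc`.
#' @param matrix an `eff_matrix`.
#' @param catalog the matching `loc_catalog`.
#' @param pool replacement pool; defaults to all proteins occurring in the
#'   collection.
#' @param n_random consistent-substitution randomizations per pathway
#'   (default 1000; 0 skips the pathway-level null).
#' @param n_reaction_sets independent-replacement randomization sets
#'   (default 1; 0 skips the reaction-level null).
#' @param seed root seed.
#' @param combine route aggregation rule.
#' @param bins bins for the chi-square comparisons.
#' @param allow_collisions passed to [randomize_pathway()].
#' @return object of class `eff_null_report`: list with the real and random
#'   reaction-efficiency samples, per-pathway real `Eff`, the
#'   pathway-by-draw matrix `random_eff`, `mean_real` / `mean_random` /
#'   `ratio` (reaction level), and the two chi-square comparisons.
#' @export
compare_real_vs_random <- function(docs, matrix, catalog, pool = NULL,
                                   n_random = 1000, n_reaction_sets = 1,
                                   seed = 1, combine = c("mean", "max"),
                                   bins = 20, allow_collisions = FALSE) {
  combine <- match.arg(combine)
  if (is.null(pool)) pool <- sort(collection_proteins(docs))
  if (!length(pool)) .stopf("empty replacement pool")
  mem_idx <- lapply(catalog$membership, function(m) match(m, matrix$labels))
  E <- matrix$values
  profiles <- lapply(docs, .pathway_profile_idx, E = E, mem_idx = mem_idx,
                     combine = combine)
  real_re <- unlist(lapply(profiles, `[[`, "reaction_efficiencies"),
                    use.names = FALSE)
  real_eff <- vapply(profiles, `[[`, 0, "mean_eff")
  names(real_eff) <- vapply(profiles, `[[`, "", "pathway_id")

  random_re <- numeric(0)
  if (n_reaction_sets > 0) {
    random_re <- unlist(lapply(seq_len(n_reaction_sets), function(s) {
      unlist(lapply(docs, function(d) {
        rd <- randomize_reactions(d, pool,
                                  seed = child_seed(seed, paste0(d$pathway_id, ":r", s)))
        .pathway_profile_idx(rd, E, mem_idx, combine)$reaction_efficiencies
      }), use.names = FALSE)
    }), use.names = FALSE)
  }

  random_eff <- NULL
  if (n_random > 0) {
    random_eff <- matrix(NA_real_, nrow = length(docs), ncol = n_random,
                         dimnames = list(names(real_eff), NULL))
    for (i in seq_along(docs)) {
      d <- docs[[i]]
      random_eff[i, ] <- vapply(seq_len(n_random), function(j) {
        rd <- randomize_pathway(d, pool,
                                seed = child_seed(seed, paste0(d$pathway_id, ":p", j)),
                                allow_collisions = allow_collisions)
        .pathway_profile_idx(rd, E, mem_idx, combine)$mean_eff
      }, 0)
    }
  }

  chisq_reactions <- if (length(random_re) && length(real_re))
    chi_square_binned(real_re, random_re, bins = bins) else NULL
  re_ok <- real_eff[!is.na(real_eff)]
  rnd_eff_vec <- if (!is.null(random_eff)) random_eff[!is.na(random_eff)] else numeric(0)
  chisq_eff <- if (length(re_ok) && length(rnd_eff_vec))
    chi_square_binned(re_ok, rnd_eff_vec, bins = bins) else NULL

  structure(list(real_reaction_eff = real_re,
                 random_reaction_eff = random_re,
                 real_eff = real_eff,
                 random_eff = random_eff,
                 mean_real = mean(real_re),
                 mean_random = if (length(random_re)) mean(random_re) else NA_real_,
                 ratio = if (length(random_re)) mean(real_re) / mean(random_re)
                         else NA_real_,
                 chisq_reactions = chisq_reactions,
                 chisq_eff = chisq_eff,
                 config = list(n_random = n_random,
                               n_reaction_sets = n_reaction_sets,
                               seed = seed, pool_size = length(pool),
                               combine = combine, bins = bins)),
            class = "eff_null_report")
}

#' @export
print.eff_null_report <- function(x, ...) {
  cat("Real vs random pathway comparison\n")
  cat(sprintf("  mean reaction efficiency: real %.4g, random %.4g (ratio %.3f)\n",
              x$mean_real, x$mean_random, x$ratio))
  if (!is.null(x$chisq_reactions)) {
    cat("  reaction-level: "); print(x$chisq_reactions)
  }
  if (!is.null(x$chisq_eff)) {
    cat("  pathway-level (Eff): "); print(x$chisq_eff)
  }
  invisible(x)
}
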