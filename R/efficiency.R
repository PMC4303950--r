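# Counting intra/inter-compartmental interactions and building the
# efficiency matrix E(Li,Lj) = P(Li,Lj) / (mi * mj).

#' Count interactions between compartments
#'
#' For every unordered interaction `{A,B}` with `A != B`, one count is added
#' to every distinct unordered compartment pair `{la,lb}` with
#' `la` in membership(A) and `lb` in membership(B). Multi-localized protein
#' pairs therefore contribute one count to every compatible label pair.
#' Interactions where either protein lacks membership are skipped and
#' tallied; self-interactions are skipped by default (with
#' `include_self = TRUE` each adds 1 to `P(l,l)` for every localization `l`
#' of the protein).
#'
#' @param interactions `ppi_edges` data.frame (unordered pairs, deduplicated
#'   at read time).
#' @param catalog a `loc_catalog` restricted to the analysis compartments.
#' @param include_self count homodimer records on the diagonal? Default
#'   `FALSE`: keeping them out makes `E <= 1` hold without qualification.
#' @return object of class `ppi_counts`: list with `labels`, symmetric
#'   integer matrix `counts`, and `skipped` tallies.
#' @export
count_interactions <- function(interactions, catalog, include_self = FALSE) {
  stopifnot(inherits(catalog, "loc_catalog"))
  labs <- catalog$compartments
  K <- length(labs)
  P <- matrix(0L, K, K, dimnames = list(labs, labs))
  mem_idx <- lapply(catalog$membership, function(m) match(m, labs))
  a <- as.character(interactions$protein_a)
  b <- as.character(interactions$protein_b)
  self <- a == b
  skipped <- c(no_membership = 0L, self = 0L)

  if (any(self)) {
    if (include_self) {
      for (p in a[self]) {
        ii <- mem_idx[[p]]
        if (is.null(ii) || !length(ii)) {
          skipped["no_membership"] <- skipped["no_membership"] + 1L
        } else {
          for (i in ii) P[i, i] <- P[i, i] + 1L
        }
      }
    } else {
      skipped["self"] <- skipped["self"] + sum(self)
    }
    a <- a[!self]; b <- b[!self]
  }

  ma <- mem_idx[a]
  mb <- mem_idx[b]
  na_side <- vapply(ma, function(x) is.null(x) || !length(x), NA) |
    vapply(mb, function(x) is.null(x) || !length(x), NA)
  skipped["no_membership"] <- skipped["no_membership"] + sum(na_side)
  ma <- ma[!na_side]; mb <- mb[!na_side]

  single <- lengths(ma) == 1L & lengths(mb) == 1L
  if (any(single)) {
    i <- unlist(ma[single], use.names = FALSE)
    j <- unlist(mb[single], use.names = FALSE)
    lo <- pmin(i, j); hi <- pmax(i, j)
    tab <- tabulate((hi - 1L) * K + lo, nbins = K * K)
    P <- P + matrix(as.integer(tab), K, K) # filled in upper triangle (lo<=hi)
  }
  for (r in which(!single)) {
    g <- expand.grid(i = ma[[r]], j = mb[[r]])
    key <- unique(cbind(pmin(g$i, g$j), pmax(g$i, g$j)))
    P[key] <- P[key] + 1L
  }
  # symmetrize: accumulation used the upper triangle only
  low <- lower.tri(P)
  P[low] <- t(P)[low]
  structure(list(labels = labs, counts = P, skipped = skipped),
            class = "ppi_counts")
}

#' Build the compartment efficiency matrix
#'
#' `E(Li,Lj) = P(Li,Lj) / (mi * mj)` with the product denominator applied
#' literally, including on the diagonal. `E` is symmetric and, under the
#' unordered-pair counting convention, bounded by `[0, 1]`.
#'
#' @param counts a `ppi_counts` object.
#' @param catalog the `loc_catalog` the counts were built from (provides
#'   the compartment sizes `mi`).
#' @return object of class `eff_matrix`: list with `labels`, `values`
#'   (symmetric numeric matrix), `counts` and `sizes`.
#' @export
build_efficiency_matrix <- function(counts, catalog) {
  stopifnot(inherits(counts, "ppi_counts"), inherits(catalog, "loc_catalog"))
  labs <- counts$labels
  m <- catalog$sizes[labs]
  bad <- is.na(m) | m == 0L
  if (any(bad & (rowSums(counts$counts) > 0)))
    .stopf("compartment '%s' has zero catalog proteins but nonzero counts",
           labs[which(bad & rowSums(counts$counts) > 0)][1L])
  if (any(bad))
    .stopf("compartment '%s' has zero catalog proteins", labs[bad][1L])
  E <- counts$counts / (as.numeric(m) %o% as.numeric(m))
  dimnames(E) <- list(labs, labs)
  structure(list(labels = labs, values = E, counts = counts$counts,
                 sizes = stats::setNames(as.integer(m), labs)),
            class = "eff_matrix")
}

#' @export
as.matrix.eff_matrix <- function(x, ...) x$values

#' @export
print.eff_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Compartment efficiency matrix (%d x %d)\n",
              length(x$labels), length(x$labels)))
  print(round(x$values, digits))
  invisible(x)
}

#' Diagonal dominance report
#'
#' For each compartment `k`, reports whether the within-compartment entry
#' `E(k,k)` is the maximum of its row, which compartment attains the row
#' maximum among off-diagonal entries, and the ratio of `E(k,k)` to the
#' largest off-diagonal entry. Interactions within one compartment are
#' typically more frequent per protein pair than across compartments; the
#' membrane compartment is the classic exception in real data.
#'
#' @param matrix an `eff_matrix` (at least 2x2).
#' @return data.frame with one row per compartment: `compartment`,
#'   `diagonal`, `max_offdiag`, `argmax`, `ratio`, `dominant`; attribute
#'   `violations` lists non-dominant compartments.
#' @export
diagonal_dominance <- function(matrix) {
  stopifnot(inherits(matrix, "eff_matrix"))
  E <- matrix$values
  K <- nrow(E)
  if (K < 2L) .stopf("diagonal dominance needs at least 2 compartments")
  out <- data.frame(compartment = matrix$labels,
                    diagonal = diag(E),
                    max_offdiag = NA_real_, argmax = NA_character_,
                    ratio = NA_real_, dominant = NA,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_len(K)) {
    off <- E[k, -k]
    out$max_offdiag[k] <- max(off)
    out$argmax[k] <- matrix$labels[-k][which.max(off)]
    out$ratio[k] <- if (out$max_offdiag[k] > 0) out$diagonal[k] / out$max_offdiag[k] else Inf
    out$dominant[k] <- out$diagonal[k] >= out$max_offdiag[k]
  }
  attr(out, "violations") <- out$compartment[!out$dominant]
  out
}

#' Within/between interaction-rate enrichment
#'
#' Ratio of the mean per-protein-pair interaction rate within compartments
#' (`P(k,k) / choose(mk, 2)`) to the mean rate between compartments
#' (`P(i,j) / (mi * mj)`, `i != j`). Unlike the raw diagonal of the
#' efficiency matrix -- whose denominator `mk^2` counts each unordered
#' within-compartment pair roughly twice -- this ratio is a consistent
#' estimator of the within-compartment enrichment factor of the underlying
#' interaction process (the simulator's `rho`).
#'
#' @param x an `eff_matrix` or a `comp_eff` fit.
#' @return list with `ratio`, `within_rates`, `between_rates`.
#' @export
enrichment_ratio <- function(x) {
  if (inherits(x, "comp_eff")) x <- x$matrix
  stopifnot(inherits(x, "eff_matrix"))
  m <- as.numeric(x$sizes)
  K <- length(m)
  if (K < 2L) .stopf("enrichment ratio needs at least 2 compartments")
  pairs_within <- m * (m - 1) / 2
  if (any(pairs_within == 0)) .stopf("compartments of size 1 have no within pairs")
  within <- diag(x$counts) / pairs_within
  up <- upper.tri(x$counts)
  between <- x$counts[up] / (m %o% m)[up]
  list(ratio = mean(within) / mean(between),
       within_rates = stats::setNames(within, x$labels),
       between_rates = between)
}
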