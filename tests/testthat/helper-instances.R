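# In-code builders and independent oracles shared across tests.

# records data.frame from a named list protein -> term vector
records_from <- function(membership) {
  data.frame(protein_id = names(membership), terms = I(unname(membership)),
             stringsAsFactors = FALSE)
}

catalog_from <- function(membership) {
  collapse_to_top_level(records_from(membership))
}

edges_from <- function(a, b) {
  out <- data.frame(protein_a = a, protein_b = b, source = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("ppi_edges", "data.frame")
  out
}

# independent brute-force oracle for the compartment count matrix:
# plain double loop over interactions and membership label pairs
brute_counts <- function(edges, catalog, include_self = FALSE) {
  labs <- catalog$compartments
  K <- length(labs)
  P <- matrix(0L, K, K, dimnames = list(labs, labs))
  for (r in seq_len(nrow(edges))) {
    A <- edges$protein_a[r]
    B <- edges$protein_b[r]
    if (A == B) {
      if (include_self) {
        for (l in catalog$membership[[A]]) {
          i <- match(l, labs)
          P[i, i] <- P[i, i] + 1L
        }
      }
      next
    }
    ma <- catalog$membership[[A]]
    mb <- catalog$membership[[B]]
    if (is.null(ma) || !length(ma) || is.null(mb) || !length(mb)) next
    seen <- character(0)
    for (la in ma) for (lb in mb) {
      key <- paste(sort(c(la, lb)), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      i <- match(la, labs)
      j <- match(lb, labs)
      P[i, j] <- P[i, j] + 1L
      if (i != j) P[j, i] <- P[j, i] + 1L
    }
  }
  P
}

# random instance with multi-localized and unlocalized proteins plus
# self-interactions, for oracle-equivalence and property sweeps
random_instance <- function(n, K = 4, p_edge = 0.03, multi = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("q%04d", seq_len(n))
  labs <- LETTERS[seq_len(K)]
  membership <- lapply(seq_len(n), function(i)
    sample(labs, 1L + (stats::runif(1) < multi)))
  membership[sample(n, max(1L, n %/% 20L))] <- list(character(0))
  names(membership) <- ids
  catalog <- catalog_from(membership)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(ut)) < p_edge
  edges <- edges_from(ids[ut[keep, 1]], ids[ut[keep, 2]])
  edges <- rbind(edges, edges_from(ids[1:3], ids[1:3])) # self-interactions
  class(edges) <- c("ppi_edges", "data.frame")
  list(catalog = catalog, edges = edges, membership = membership)
}

# small fitted model on a synthetic interactome, reused by several files
fit_small_model <- function(seed = 1, sizes = rep(80, 3), p0 = 0.03, rho = 3) {
  sim <- simulate_interactome(sizes, p0 = p0, within_enrichment = rho,
                              seed = seed)
  compartment_efficiency(sim$interactions, sim$localizations,
                         min_proteins = 5)
}

# all proteins occurring in a pathway document
pathway_proteins_seen <- function(doc) {
  unique(unlist(lapply(doc$reactions, function(r) c(r$p1, r$p2))))
}
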