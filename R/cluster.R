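# Clustering pathways by the correlation distance between their
# reaction-efficiency distributions, plus class composition and ranking.

#' Shared histogram bin edges for a pathway collection
#'
#' Default binning: `bins` equal-width bins on `[0, max reaction
#' efficiency]` over the whole collection.
#'
#' @param profiles a profiles table from [score_pathways()] (or a numeric
#'   vector of efficiencies).
#' @param bins number of bins (default 20).
#' @return numeric vector of `bins + 1` strictly increasing edges.
#' @export
default_bin_edges <- function(profiles, bins = 20) {
  vals <- if (is.numeric(profiles)) profiles
          else reaction_table(profiles)$efficiency
  upper <- if (length(vals)) max(vals) else 0
  if (upper <= 0) upper <- 1
  seq(0, upper, length.out = bins + 1)
}

#' Histogram of a pathway's reaction efficiencies
#'
#' Bins are right-open (`[a, b)`), the last bin right-closed; a value lying
#' exactly on an interior edge belongs to the bin starting there. Densities
#' are normalized counts and sum to 1.
#'
#' @param profile an `eff_profile`, or a numeric vector of reaction
#'   efficiencies.
#' @param bin_edges strictly increasing edges covering all values.
#' @param pathway_id id to attach when `profile` is a bare vector.
#' @return object of class `eff_hist`: list with `pathway_id`, `bin_edges`,
#'   `densities`.
#' @export
efficiency_histogram <- function(profile, bin_edges, pathway_id = NULL) {
  if (inherits(profile, "eff_profile")) {
    vals <- profile$reaction_efficiencies
    pathway_id <- pathway_id %||% profile$pathway_id
  } else {
    vals <- as.numeric(profile)
    pathway_id <- pathway_id %||% NA_character_
  }
  if (!length(vals))
    .stopf("pathway %s has no scored reactions (N = 0): exclude it upstream",
           pathway_id)
  if (any(diff(bin_edges) <= 0)) .stopf("bin edges must be strictly increasing")
  if (min(vals) < bin_edges[1L] || max(vals) > bin_edges[length(bin_edges)])
    .stopf("efficiencies outside the bin range for pathway %s", pathway_id)
  b <- findInterval(vals, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(b, nbins = length(bin_edges) - 1L)
  structure(list(pathway_id = pathway_id, bin_edges = bin_edges,
                 densities = counts / length(vals)),
            class = "eff_hist")
}

#' Correlation distance between two efficiency histograms
#'
#' `1 - r` where `r` is the Pearson correlation between the two density
#' vectors over shared bins, so the distance lies in `[0, 2]`. When either
#' vector has zero variance (a flat histogram) Pearson correlation is
#' undefined and the distance is fixed at 1 (uninformative).
#'
#' @param h1,h2 `eff_hist` objects with identical `bin_edges`.
#' @return a single distance in `[0, 2]`.
#' @export
correlation_distance <- function(h1, h2) {
  stopifnot(inherits(h1, "eff_hist"), inherits(h2, "eff_hist"))
  if (length(h1$bin_edges) != length(h2$bin_edges) ||
      any(abs(h1$bin_edges - h2$bin_edges) > 1e-12))
    .stopf("histograms have mismatched bin edges")
  d1 <- h1$densities; d2 <- h2$densities
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0) return(1)
  min(2, max(0, 1 - stats::cor(d1, d2)))
}

#' Pairwise correlation-distance matrix for a pathway collection
#'
#' @param histograms list of `eff_hist` with shared edges and unique ids.
#' @return object of class `pathway_dist`: list with `pathway_ids` and the
#'   symmetric `distances` matrix (zero diagonal, entries in `[0, 2]`).
#' @export
build_distance_matrix <- function(histograms) {
  if (length(histograms) < 2L) .stopf("need at least 2 histograms")
  ids <- vapply(histograms, `[[`, "", "pathway_id")
  if (anyDuplicated(ids))
    .stopf("duplicate pathway id '%s' among histograms", ids[duplicated(ids)][1L])
  n <- length(histograms)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- correlation_distance(histograms[[i]], histograms[[j]])
  }
  structure(list(pathway_ids = ids, distances = D), class = "pathway_dist")
}

#' Hierarchical clustering of pathways
#'
#' Agglomerative clustering of the correlation-distance matrix, cut to
#' exactly `k` clusters. Pathways are ordered by id before clustering and
#' cluster labels are renumbered by first appearance in id order, so the
#' result is invariant to the input ordering. The correlation distance need
#' not satisfy the triangle inequality; agglomerative linkage does not
#' require it.
#'
#' @param dist a `pathway_dist`.
#' @param k number of clusters (`1 <= k <=` number of pathways). Default 7,
#'   the number of major groups typically resolved for the full human
#'   pathway collection (8 under a finer cut; both are useful).
#' @param linkage `"average"` (UPGMA, default), `"complete"` or `"single"`.
#' @return object of class `pathway_clusters`: list with `labels` (named
#'   integer vector, contiguous labels `1..k`), `tree` (`hclust`) and `k`.
#' @export
hierarchical_clusters <- function(dist, k = 7,
                                  linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(dist, "pathway_dist"))
  n <- length(dist$pathway_ids)
  if (k < 1 || k > n) .stopf("k must be between 1 and %d", n)
  ord <- order(dist$pathway_ids)
  D <- dist$distances[ord, ord, drop = FALSE]
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  raw <- stats::cutree(tree, k = k)
  labels <- match(raw, unique(raw)) # contiguous, by first appearance in id order
  names(labels) <- dist$pathway_ids[ord]
  structure(list(labels = labels, tree = tree, k = as.integer(k),
                 linkage = linkage),
            class = "pathway_clusters")
}

#' @export
print.pathway_clusters <- function(x, ...) {
  cat(sprintf("Pathway clustering: %d pathways, k = %d (%s linkage)\n",
              length(x$labels), x$k, x$linkage))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Functional class composition of clusters
#'
#' For each (class, cluster) cell, the fraction of the class's pathways that
#' fall in the cluster; rows sum to 1. Pathways missing from `class_map`
#' are labelled `"unclassified"`.
#'
#' @param assignment a `pathway_clusters`.
#' @param class_map named character vector pathway id -> class label.
#' @return numeric matrix classes x clusters of row-normalized ratios.
#' @export
class_composition <- function(assignment, class_map) {
  stopifnot(inherits(assignment, "pathway_clusters"))
  ids <- names(assignment$labels)
  cls <- unname(class_map[ids])
  cls[is.na(cls) | !nzchar(cls)] <- "unclassified"
  tab <- table(class = cls, cluster = factor(assignment$labels,
                                             levels = seq_len(assignment$k)))
  ratios <- prop.table(tab, margin = 1)
  m <- matrix(as.numeric(ratios), nrow = nrow(ratios),
              dimnames = dimnames(ratios))
  m
}

#' Rank functional classes by mean pathway efficiency
#'
#' @param profiles a profiles table from [score_pathways()] (unusable
#'   pathways are excluded).
#' @param class_map named character vector pathway id -> class label.
#' @return data.frame (`class`, `n_pathways`, `mean_eff`, `rank`) sorted by
#'   descending mean efficiency, ties broken alphabetically; unclassified
#'   pathways are summarized in the `unclassified` attribute.
#' @export
rank_classes <- function(profiles, class_map) {
  use <- profiles[profiles$n_scored > 0L, , drop = FALSE]
  cls <- unname(class_map[use$pathway_id])
  known <- !is.na(cls) & nzchar(cls)
  if (!any(known)) .stopf("no classified pathway with a usable profile")
  agg <- stats::aggregate(use$mean_eff[known], by = list(class = cls[known]),
                          FUN = mean)
  n <- stats::aggregate(use$mean_eff[known], by = list(class = cls[known]),
                        FUN = length)
  out <- data.frame(class = agg$class, n_pathways = n$x, mean_eff = agg$x,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_eff, out$class), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "unclassified") <- list(n = sum(!known),
                                    pathway_ids = use$pathway_id[!known])
  out
}

#' Per-cluster efficiency summary with a cross-cluster test
#'
#' Summarizes the distribution of pathway mean efficiencies per cluster and
#' tests for differences across clusters with the Kruskal-Wallis rank-sum
#' test (no normality assumption on Eff).
#'
#' @param assignment a `pathway_clusters`.
#' @param profiles a profiles table covering the same pathways.
#' @return list with `table` (per-cluster `n`, `mean_eff`, `sd_eff`,
#'   `median_eff`) and `kruskal` (`statistic`, `df`, `p_value`).
#' @export
cluster_efficiency_summary <- function(assignment, profiles) {
  stopifnot(inherits(assignment, "pathway_clusters"))
  ids <- names(assignment$labels)
  i <- match(ids, profiles$pathway_id)
  if (anyNA(i)) .stopf("profiles are missing %d clustered pathways", sum(is.na(i)))
  eff <- profiles$mean_eff[i]
  cl <- factor(assignment$labels, levels = seq_len(assignment$k))
  tab <- data.frame(
    cluster = seq_len(assignment$k),
    n = as.integer(table(cl)),
    mean_eff = as.numeric(tapply(eff, cl, mean)),
    sd_eff = as.numeric(tapply(eff, cl, stats::sd)),
    median_eff = as.numeric(tapply(eff, cl, stats::median)))
  if (assignment$k < 2L || stats::sd(eff) == 0 || all(is.na(eff))) {
    kw <- list(statistic = 0, df = max(0L, assignment$k - 1L), p_value = 1)
  } else {
    ht <- stats::kruskal.test(eff, cl)
    kw <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value)
  }
  list(table = tab, kruskal = kw)
}
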