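# Matrix TSV round trip and the Newick dendrogram writer.

#' Write an efficiency matrix as TSV
#'
#' Layout: an optional `#sizes` comment line with the compartment sizes, a
#' header row of compartment labels, then one row per compartment with the
#' label in the first column. Values are printed with 15 significant digits
#' so the round trip reproduces them to at least 12.
#'
#' @param matrix an `eff_matrix`.
#' @param path output path.
#' @export
write_efficiency_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "eff_matrix"))
  labs <- matrix$labels
  if (anyDuplicated(labs)) .stopf("matrix labels must be unique")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(matrix$sizes))
    writeLines(paste(c("#sizes", matrix$sizes[labs]), collapse = "\t"), con)
  writeLines(paste(c("compartment", labs), collapse = "\t"), con)
  for (i in seq_along(labs)) {
    vals <- sprintf("%.15g", matrix$values[i, ])
    writeLines(paste(c(labs[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an efficiency matrix from TSV
#'
#' Enforces symmetry: the first violating cell pair is named in the error.
#'
#' @param path path written by [write_efficiency_matrix()].
#' @param tol symmetry tolerance.
#' @return an `eff_matrix` (the `counts` field is not round-tripped).
#' @export
read_efficiency_matrix <- function(path, tol = 1e-9) {
  lines <- .read_text_lines(path)
  sizes <- NULL
  if (length(lines) && startsWith(lines[1L], "#sizes")) {
    f <- .split_tsv(lines[1L])[[1L]]
    sizes <- as.integer(f[-1L])
    lines <- lines[-1L]
  }
  lines <- lines[!.is_comment_or_blank(lines)]
  if (length(lines) < 2L) .stopf("matrix file %s has no data rows", path)
  header <- .split_tsv(lines[1L])[[1L]][-1L]
  K <- length(header)
  E <- matrix(NA_real_, K, K, dimnames = list(header, header))
  for (i in seq_len(K)) {
    f <- .split_tsv(lines[1L + i])[[1L]]
    if (!identical(f[1L], header[i]))
      .stopf("matrix row label '%s' does not match header '%s'", f[1L], header[i])
    E[i, ] <- as.numeric(f[-1L])
  }
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (j > i && abs(E[i, j] - E[j, i]) > tol * max(1, abs(E[i, j])))
      .stopf("matrix is not symmetric at cells (%s,%s)/(%s,%s)",
             header[i], header[j], header[j], header[i])
  }
  if (!is.null(sizes)) sizes <- stats::setNames(sizes, header)
  structure(list(labels = header, values = E, counts = NULL, sizes = sizes),
            class = "eff_matrix")
}

#' Write a merge tree as Newick
#'
#' Converts a strictly binary agglomerative merge tree (an [stats::hclust()]
#' object or a clustering result from [hierarchical_clusters()]) to Newick.
#' Branch lengths are merge-height differences: a leaf's branch equals the
#' height at which it is first merged, an internal node's branch equals its
#' parent's height minus its own, so a two-leaf tree with merge height `h`
#' is written `(A:h,B:h);`.
#'
#' @param tree an `hclust` object (with unique labels) or a
#'   `pathway_clusters` result.
#' @param path output path.
#' @return the Newick string, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  if (inherits(tree, "pathway_clusters")) tree <- tree$tree
  stopifnot(inherits(tree, "hclust"))
  labs <- tree$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(tree$merge) + 1L))
  if (anyDuplicated(labs))
    .stopf("duplicate leaf label '%s' in dendrogram", labs[duplicated(labs)][1L])
  safe <- gsub("[ ,():;\\[\\]']", "_", labs)
  node <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%.10g", safe[-i], parent_h))
    h <- tree$height[i]
    sprintf("(%s,%s):%.10g", node(tree$merge[i, 1L], h),
            node(tree$merge[i, 2L], h), parent_h - h)
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  nwk <- sprintf("(%s,%s);", node(tree$merge[root, 1L], h),
                 node(tree$merge[root, 2L], h))
  writeLines(nwk, path)
  invisible(nwk)
}
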