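test_that("histograms normalize counts with right-open bins", {
  h <- efficiency_histogram(c(0.1, 0.9), bin_edges = c(0, 0.5, 1), pathway_id = "p")
  expect_equal(h$densities, c(0.5, 0.5))
  one <- efficiency_histogram(rep(0.3, 7), bin_edges = c(0, 0.5, 1))
  expect_equal(one$densities, c(1, 0))
  # a value exactly on an interior edge belongs to the right bin
  edge <- efficiency_histogram(0.5, bin_edges = c(0, 0.5, 1))
  expect_equal(edge$densities, c(0, 1))
  # the upper boundary closes the last bin
  top <- efficiency_histogram(1, bin_edges = c(0, 0.5, 1))
  expect_equal(top$densities, c(0, 1))
  expect_error(efficiency_histogram(numeric(0), c(0, 1), pathway_id = "x"),
               "N = 0")
})

test_that("histogram mass is conserved across random profiles", {
  fit <- fit_small_model(seed = 4)
  docs <- simulate_pathways(10, 12, fit$catalog, seed = 5)
  pr <- score_pathways(docs, fit$matrix, fit$catalog)
  edges <- default_bin_edges(pr, 20)
  for (p in attr(pr, "profiles")) {
    h <- efficiency_histogram(p, edges)
    expect_equal(sum(h$densities), 1, tolerance = 1e-9)
    expect_length(h$densities, length(edges) - 1)
  }
})

test_that("correlation distance spans [0,2] with the declared conventions", {
  mk <- function(d, id) structure(list(pathway_id = id, bin_edges = 0:length(d),
                                       densities = d), class = "eff_hist")
  expect_equal(correlation_distance(mk(c(1, 0), "a"), mk(c(1, 0), "b")), 0)
  expect_equal(correlation_distance(mk(c(1, 0), "a"), mk(c(0, 1), "b")), 2)
  # zero-variance histogram: distance fixed at 1
  expect_equal(correlation_distance(mk(c(0.5, 0.5), "a"), mk(c(1, 0), "b")), 1)
  expect_error(
    correlation_distance(mk(c(1, 0), "a"),
                         structure(list(pathway_id = "c", bin_edges = c(0, 1, 3),
                                        densities = c(0, 1)), class = "eff_hist")),
    "mismatched")
})

test_that("the distance matrix equals element-wise recomputation", {
  fit <- fit_small_model(seed = 6)
  docs <- simulate_pathways(6, 10, fit$catalog, seed = 7)
  pr <- score_pathways(docs, fit$matrix, fit$catalog)
  edges <- default_bin_edges(pr, 10)
  hists <- lapply(attr(pr, "profiles"), efficiency_histogram, bin_edges = edges)
  pd <- build_distance_matrix(hists)
  D <- pd$distances
  expect_equal(diag(D), rep(0, 6), ignore_attr = TRUE)
  expect_identical(D, t(D))
  expect_true(all(D >= 0 & D <= 2))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j], correlation_distance(hists[[i]], hists[[j]]))
  }
  expect_error(build_distance_matrix(hists[1]), "at least 2")
})

test_that("clustering splits well-separated groups and respects k", {
  mk <- function(d, id) structure(list(pathway_id = id, bin_edges = 0:length(d),
                                       densities = d), class = "eff_hist")
  hists <- c(lapply(1:3, function(i) mk(c(0.9, 0.1, 0, 0), sprintf("g1_%d", i))),
             lapply(1:3, function(i) mk(c(0, 0, 0.1, 0.9), sprintf("g2_%d", i))))
  pd <- build_distance_matrix(hists)
  cl <- hierarchical_clusters(pd, k = 2)
  lab <- cl$labels
  expect_length(unique(lab[paste0("g1_", 1:3)]), 1)
  expect_length(unique(lab[paste0("g2_", 1:3)]), 1)
  expect_false(lab[["g1_1"]] == lab[["g2_1"]])
  singletons <- hierarchical_clusters(pd, k = 6)
  expect_length(unique(singletons$labels), 6)
  expect_error(hierarchical_clusters(pd, k = 7), "between 1 and 6")
  expect_error(hierarchical_clusters(pd, k = 0), "between 1 and 6")
})

test_that("clustering is invariant to the input order of pathways", {
  fit <- fit_small_model(seed = 8)
  docs <- simulate_pathways(12, 10, fit$catalog, seed = 9)
  pr <- score_pathways(docs, fit$matrix, fit$catalog)
  edges <- default_bin_edges(pr, 10)
  hists <- lapply(attr(pr, "profiles"), efficiency_histogram, bin_edges = edges)
  cl1 <- hierarchical_clusters(build_distance_matrix(hists), k = 3)
  set.seed(1)
  cl2 <- hierarchical_clusters(build_distance_matrix(sample(hists)), k = 3)
  expect_identical(cl1$labels, cl2$labels)
})

test_that("class composition ratios are row-normalized", {
  mk <- function(d, id) structure(list(pathway_id = id, bin_edges = 0:length(d),
                                       densities = d), class = "eff_hist")
  hists <- c(lapply(1:4, function(i) mk(c(1, 0, 0), sprintf("a%d", i))),
             lapply(1:2, function(i) mk(c(0, 0, 1), sprintf("b%d", i))))
  cl <- hierarchical_clusters(build_distance_matrix(hists), k = 2)
  cmap <- c(a1 = "X", a2 = "X", a3 = "X", a4 = "X", b1 = "Y", b2 = "Z")
  comp <- class_composition(cl, cmap)
  expect_equal(unname(rowSums(comp)), rep(1, nrow(comp)))
  expect_true(any(comp["X", ] == 1)) # X lies entirely in one cluster
  # a class split evenly across two clusters
  cmap2 <- c(a1 = "W", a2 = "W", b1 = "W", b2 = "W")
  comp2 <- class_composition(cl, cmap2)
  expect_setequal(unname(comp2["W", ]), c(0.5, 0.5))
  expect_true("unclassified" %in% rownames(comp2))
})

test_that("class ranking averages member Effs and breaks ties alphabetically", {
  prof <- data.frame(
    pathway_id = c("p1", "p2", "p3", "p4", "p5"),
    n_scored = c(3L, 3L, 3L, 3L, 0L),
    mean_eff = c(0.4, 0.2, 0.6, 0.9, 0.99))
  cmap <- c(p1 = "beta", p2 = "alpha", p3 = "alpha", p4 = "gamma")
  rk <- rank_classes(prof, cmap)
  # gamma 0.9 > alpha mean(0.2,0.6)=0.4 == beta 0.4 -> alphabetical tie-break
  expect_equal(rk$class, c("gamma", "alpha", "beta"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$mean_eff[2], 0.4)
  expect_equal(rk$n_pathways, c(1L, 2L, 1L))
  expect_equal(attr(rk, "unclassified")$pathway_ids, character(0))
})

test_that("cluster efficiency summary tests across clusters", {
  mk <- function(d, id) structure(list(pathway_id = id, bin_edges = 0:length(d),
                                       densities = d), class = "eff_hist")
  hists <- c(lapply(1:6, function(i) mk(c(1, 0), sprintf("lo%d", i))),
             lapply(1:6, function(i) mk(c(0, 1), sprintf("hi%d", i))))
  cl <- hierarchical_clusters(build_distance_matrix(hists), k = 2)
  prof <- data.frame(pathway_id = names(cl$labels), n_scored = 5L,
                     mean_eff = ifelse(grepl("^lo", names(cl$labels)),
                                       runif(12, 0, 0.1), runif(12, 0.8, 0.9)))
  out <- cluster_efficiency_summary(cl, prof)
  expect_equal(sum(out$table$n), 12)
  expect_lt(out$kruskal$p_value, 0.01)
  # identical Eff everywhere: no separation, p about 1
  prof2 <- transform(prof, mean_eff = 0.5)
  out2 <- cluster_efficiency_summary(cl, prof2)
  expect_equal(out2$kruskal$p_value, 1)
})
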