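test_that("independent replacement preserves structure and is seeded", {
  doc <- pathway_document("pw", list(reaction(c("a", "b"), "c"),
                                     reaction("c", "d"),
                                     reaction("e", kind = "non-ppi")))
  pool <- sprintf("r%02d", 1:5)
  r1 <- randomize_reactions(doc, pool, seed = 42)
  r2 <- randomize_reactions(doc, pool, seed = 42)
  expect_identical(r1, r2)
  expect_equal(vapply(r1$reactions, function(r) length(r$p1) + length(r$p2), 0L),
               c(3L, 2L, 1L))
  expect_equal(vapply(r1$reactions, `[[`, "", "kind"),
               c("ppi", "ppi", "non-ppi"))
  expect_true(all(unlist(lapply(r1$reactions, function(r) c(r$p1, r$p2))) %in% pool))
  one <- randomize_reactions(doc, "only", seed = 1)
  expect_true(all(unlist(lapply(one$reactions, function(r) c(r$p1, r$p2))) == "only"))
})

test_that("replacement draws are uniform over the pool", {
  rx <- lapply(1:2000, function(i) reaction(c("a", "b", "c"), c("d", "e")))
  pool <- sprintf("r%d", 1:5)
  out <- randomize_reactions(rx, pool, seed = 7)
  draws <- unlist(lapply(out, function(r) c(r$p1, r$p2)))
  n <- length(draws) # 10000 replacements
  freq <- table(factor(draws, levels = pool))
  expected <- n / 5
  sigma <- sqrt(n * 0.2 * 0.8)
  expect_true(all(abs(freq - expected) < 3 * sigma))
})

test_that("consistent substitution uses one map for the whole pathway", {
  doc <- pathway_document("pw", list(reaction("p1", "p2"),
                                     reaction("p2", "p3"),
                                     reaction("p1", "p3")))
  pool <- sprintf("r%02d", 1:10)
  rd <- randomize_pathway(doc, pool, seed = 5)
  got <- lapply(rd$reactions, function(r) c(r$p1, r$p2))
  # p1 appears in reactions 1 and 3: same replacement in both
  expect_equal(got[[1]][1], got[[3]][1])
  expect_equal(got[[1]][2], got[[2]][1])
  expect_equal(got[[2]][2], got[[3]][2])
  # injectivity: three distinct proteins -> three distinct replacements
  expect_length(unique(unlist(got)), 3)
})

test_that("substitution with the pathway's own proteins is a permutation", {
  doc <- pathway_document("pw", list(reaction("p1", "p2"), reaction("p3", "p4")))
  own <- c("p1", "p2", "p3", "p4")
  for (s in 1:25) {
    rd <- randomize_pathway(doc, own, seed = s)
    expect_setequal(pathway_proteins_seen(rd), own)
  }
})

test_that("a pool smaller than the distinct protein set is an error", {
  doc <- pathway_document("pw", list(reaction("p1", "p2"), reaction("p3", "p4")))
  expect_error(randomize_pathway(doc, c("r1", "r2"), seed = 1), "smaller")
  rd <- randomize_pathway(doc, c("r1", "r2"), seed = 1, allow_collisions = TRUE)
  expect_true(all(pathway_proteins_seen(rd) %in% c("r1", "r2")))
})

test_that("identical samples give a zero statistic and p = 1", {
  x <- runif(200)
  out <- chi_square_binned(x, x)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
})

test_that("shifted distributions are detected with high power", {
  set.seed(13)
  hits <- mean(replicate(100, {
    a <- runif(1000)
    b <- runif(1000, 0.5, 1.5)
    chi_square_binned(a, b, bins = 10)$p_value < 0.001
  }))
  expect_gte(hits, 0.95)
})

test_that("low-count bins are merged and tiny samples are rejected", {
  set.seed(8)
  a <- c(runif(50), 2.5) # a lone outlier makes the last fixed bin sparse
  b <- c(runif(50), 2.6)
  out <- chi_square_binned(a, b, edges = c(0, 0.5, 1, 2, 3))
  expect_gt(length(out$merge_log), 0)
  pooled <- out$observed_a + out$observed_b
  nm <- pmin(sum(out$observed_a), sum(out$observed_b)) * pooled / sum(pooled)
  expect_true(all(nm >= 5) || length(pooled) == 2)
  expect_error(chi_square_binned(0.5, 0.5), "too small")
})

test_that("fixed edges are honoured", {
  out <- chi_square_binned(c(0.1, 0.6, 0.9), c(0.2, 0.7, 0.8),
                           edges = c(0, 0.5, 1), min_expected = 0)
  expect_equal(out$bin_edges, c(0, 0.5, 1))
  expect_equal(out$observed_a, c(1L, 2L))
  expect_equal(out$df, 1L)
})

test_that("length-efficiency correlation behaves at the boundaries", {
  prof <- data.frame(pathway_id = letters[1:5], n_scored = 1:5,
                     mean_eff = (1:5) / 10)
  out <- length_efficiency_correlation(prof)
  expect_equal(out$r, 1)
  expect_equal(out$n, 5)
  expect_error(length_efficiency_correlation(prof[1:2, ]), "at least 3")
  same_len <- transform(prof, n_scored = 3L)
  expect_error(length_efficiency_correlation(same_len), "identical")
})

test_that("the correlation is near zero when Eff is independent of length", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    prof <- data.frame(pathway_id = sprintf("pw%03d", 1:200),
                       n_scored = sample(5:50, 200, replace = TRUE),
                       mean_eff = runif(200))
    ok <- ok + (abs(length_efficiency_correlation(prof)$r) < 0.2)
  }
  expect_gte(ok, 19)
})

test_that("the null report has the promised shape and determinism", {
  fit <- fit_small_model(seed = 2)
  docs <- simulate_pathways(5, 6, fit$catalog, seed = 3)
  rep1 <- compare_real_vs_random(docs, fit$matrix, fit$catalog,
                                 n_random = 10, n_reaction_sets = 2, seed = 9)
  expect_equal(dim(rep1$random_eff), c(5L, 10L))
  expect_length(rep1$real_eff, 5)
  # reaction null preserves the total reaction count per set
  expect_length(rep1$random_reaction_eff, 2 * length(rep1$real_reaction_eff))
  rep2 <- compare_real_vs_random(docs, fit$matrix, fit$catalog,
                                 n_random = 10, n_reaction_sets = 2, seed = 9)
  expect_identical(rep1$random_eff, rep2$random_eff)
  expect_identical(rep1$ratio, rep2$ratio)
  # per-pathway child seeds: reordering the collection reorders, not changes
  rep3 <- compare_real_vs_random(rev(docs), fit$matrix, fit$catalog,
                                 n_random = 10, n_reaction_sets = 2, seed = 9)
  expect_equal(rep3$random_eff[rownames(rep1$random_eff), ], rep1$random_eff)
})
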