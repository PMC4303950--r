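# shared scoring fixture: 2 compartments with known E values
scoring_setup <- function() {
  cat <- catalog_from(list(pA = c("A", "B"), pB = "A", pC = "B",
                           pD = "A", pE = character(0)))
  E <- matrix(c(0.25, 0.5, 0.5, 0.1), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  em <- structure(list(labels = c("A", "B"), values = E, counts = NULL,
                       sizes = c(A = 3L, B = 2L)), class = "eff_matrix")
  list(cat = cat, em = em)
}

test_that("single-membership pairs read the matrix entry exactly", {
  s <- scoring_setup()
  expect_equal(reaction_efficiency("pB", "pD", s$em, s$cat), 0.25)
  expect_equal(reaction_efficiency("pC", "pC", s$em, s$cat), 0.1)
})

test_that("multi-localized routes aggregate by mean or max", {
  s <- scoring_setup()
  # pA in {A,B}, pB in {A}: routes E(A,A)=0.25 and E(B,A)=0.5
  expect_equal(reaction_efficiency("pA", "pB", s$em, s$cat, "mean"), 0.375)
  expect_equal(reaction_efficiency("pA", "pB", s$em, s$cat, "max"), 0.5)
})

test_that("reactions with no localized participant return the skip marker", {
  s <- scoring_setup()
  expect_true(is.na(reaction_efficiency("pB", "pE", s$em, s$cat)))
  expect_true(is.na(reaction_efficiency("pB", "unknown", s$em, s$cat)))
})

test_that("pathway Eff is the mean over scored reactions", {
  s <- scoring_setup()
  doc <- pathway_document("pw", list(
    reaction("pB", "pD"),  # 0.25
    reaction("pB", "pC"),  # 0.5
    reaction("pC", "pC"),  # 0.1
    reaction("pB", "pE"))) # skip
  pr <- pathway_profile(doc, s$em, s$cat)
  expect_equal(pr$reaction_efficiencies, c(0.25, 0.5, 0.1))
  expect_equal(pr$n_scored, 3L)
  expect_equal(pr$n_skipped, 1L)
  expect_equal(pr$mean_eff, mean(c(0.25, 0.5, 0.1)))
  expect_true(pr$usable)
})

test_that("consecutive non-ppi reactions score across reaction boundaries", {
  s <- scoring_setup()
  doc <- pathway_document("chain", list(
    reaction("pB", kind = "non-ppi"),
    reaction("pC", kind = "non-ppi"),
    reaction("pD", kind = "non-ppi")))
  pr <- pathway_profile(doc, s$em, s$cat)
  # R1->R2 = E(A,B) = 0.5; R2->R3 = E(B,A) = 0.5; R3 has no successor
  expect_equal(pr$reaction_efficiencies, c(0.5, 0.5))
  expect_equal(pr$n_scored, 2L)
  expect_equal(pr$n_skipped, 0L)
})

test_that("pathways where every lookup skips are flagged unusable", {
  s <- scoring_setup()
  doc <- pathway_document("dead", list(reaction("pE", "unknown")))
  pr <- pathway_profile(doc, s$em, s$cat)
  expect_equal(pr$n_scored, 0L)
  expect_false(pr$usable)
  expect_true(is.na(pr$mean_eff))
})

test_that("collections score deterministically with correct totals", {
  s <- scoring_setup()
  docs <- list(
    pathway_document("pw1", list(reaction("pB", "pD"), reaction("pB", "pC"))),
    pathway_document("pw1b", list(reaction("pB", "pD"), reaction("pB", "pC"))),
    pathway_document("pw2", list(reaction("pC", "pC"), reaction("pB", "pE"))))
  tab <- score_pathways(docs, s$em, s$cat)
  expect_equal(tab$pathway_id, c("pw1", "pw1b", "pw2"))
  expect_equal(tab$mean_eff[1], tab$mean_eff[2]) # identical pathways
  expect_equal(attr(tab, "totals")$n_scored, sum(tab$n_scored))
  expect_equal(attr(tab, "totals")$n_skipped, 1L)
  empty <- score_pathways(list(), s$em, s$cat)
  expect_equal(nrow(empty), 0L)
})

test_that("Eff is bounded by the reaction efficiencies and max dominates mean", {
  for (s_i in 1:5) {
    fit <- fit_small_model(seed = s_i)
    docs <- simulate_pathways(5, 8, fit$catalog, seed = s_i)
    pr_mean <- score_pathways(docs, fit$matrix, fit$catalog, "mean")
    pr_max <- score_pathways(docs, fit$matrix, fit$catalog, "max")
    for (k in seq_along(docs)) {
      p <- attr(pr_mean, "profiles")[[k]]
      expect_gte(p$mean_eff, min(p$reaction_efficiencies))
      expect_lte(p$mean_eff, max(p$reaction_efficiencies))
    }
    expect_true(all(pr_max$mean_eff >= pr_mean$mean_eff - 1e-12))
  }
})

test_that("efficiency depends on localization only", {
  s <- scoring_setup()
  doc <- pathway_document("pw", list(reaction("pB", "pC"), reaction("pA", "pD")))
  # replace every protein by one with identical membership
  cat2 <- catalog_from(list(xA = c("A", "B"), xB = "A", xC = "B", xD = "A"))
  doc2 <- pathway_document("pw", list(reaction("xB", "xC"), reaction("xA", "xD")))
  p1 <- pathway_profile(doc, s$em, s$cat)
  p2 <- pathway_profile(doc2, s$em, cat2)
  expect_equal(p1$reaction_efficiencies, p2$reaction_efficiencies)
  expect_equal(p1$mean_eff, p2$mean_eff)
})

test_that("the long-format reaction table matches the profiles", {
  s <- scoring_setup()
  docs <- list(pathway_document("pw1", list(reaction("pB", "pD"))),
               pathway_document("pw2", list(reaction("pE", "pE"))))
  tab <- score_pathways(docs, s$em, s$cat)
  long <- reaction_table(tab)
  expect_equal(long$pathway_id, "pw1")
  expect_equal(long$efficiency, 0.25)
})
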