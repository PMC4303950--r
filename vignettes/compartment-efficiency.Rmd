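---
title: "Estimating pathway efficiency from compartment co-localization of protein interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pathway efficiency from compartment co-localization of protein interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Signaling pathways span several subcellular compartments, and reactions
between proteins that must meet across compartment boundaries are plausibly
slower than reactions between co-localized partners. `compeff` turns this
idea into a simple, data-driven score that needs no kinetic parameters.

Let $L_1, \dots, L_K$ be the top-level compartments, $m_i$ the number of
catalog proteins localized in $L_i$, and $P(L_i, L_j)$ the number of
observed protein-protein interactions between proteins of $L_i$ and
proteins of $L_j$. The **compartment efficiency matrix** is

$$E(L_i, L_j) = \frac{P(L_i, L_j)}{m_i \, m_j},$$

the observed interaction frequency per available protein pair, taken as a
proxy for how readily a reaction between proteins located in $L_i$ and
$L_j$ proceeds. $E$ is symmetric by construction.

A pathway is an ordered list of reactions $R_1, \dots, R_Q$, each with two
participant slots $P_1, P_2$. A direct protein-protein interaction is
scored within the reaction as $E(L[P_1], L[P_2])$. A reaction that is not a
direct interaction (a conversion or state change) is scored **between
consecutive reactions**: its participants against those of $R_{q+1}$; the
final reaction of such a chain contributes nothing. The pathway summary is
the mean over the $N$ scored reactions,

$$\mathit{Eff} = \frac{1}{N} \sum_{q=1}^{N} E\!\left(L[R_q[P_1]],\, L[R_q[P_2]]\right).$$

Assumptions worth keeping in mind:

* Interaction records are an unbiased (if incomplete) sample of the real
  interactome within each compartment pair. Database coverage bias directly
  moves rows of $E$.
* Localization annotations are trustworthy at the top hierarchy level;
  nested terms are absorbed by their top-level ancestor.
* The score is an ordinal proxy. Only relative magnitudes of $E$ matter
  downstream; no rate constant is implied.

## Counting conventions

Several small choices fix the arithmetic; they are applied consistently
everywhere, including the brute-force test oracle.

* **Unordered pairs, once each.** Each deduplicated interaction `{A, B}`
  with `A != B` adds one count to every *distinct unordered* compartment
  pair formed from membership(A) x membership(B). A pair of multi-localized
  proteins therefore feeds several cells, with no fractional weighting.
* **Diagonal denominator.** The formula $P/(m_i m_j)$ is applied literally
  on the diagonal ($m_k^2$), not $\binom{m_k}{2}$. With unordered counting
  this bounds $E$ by $[0, 1]$ and preserves all relative comparisons.
  One consequence deserves a flag: because the diagonal of $E$ carries an
  extra factor $\approx 1/2$ relative to the per-pair interaction *rate*,
  the raw ratio of diagonal to off-diagonal entries understates the true
  within-compartment enrichment by a factor of about two.
  `enrichment_ratio()` therefore reports the corrected per-pair rate ratio
  $\bigl[P_{kk}/\binom{m_k}{2}\bigr] / \bigl[P_{ij}/(m_i m_j)\bigr]$, which
  is the consistent estimator of the generative enrichment factor and the
  quantity the simulation tests recover.
* **Self-interactions** (homodimer records) are excluded by default;
  `include_self = TRUE` adds one diagonal count per localization of the
  protein. Exclusion keeps $E \le 1$ without qualification.
* **Missing annotation is not inefficiency.** Reactions whose participants
  carry no membership are skipped and excluded from $N$, never scored zero.

## Tunable parameters

| Parameter | Default | Where | Rationale |
|---|---|---|---|
| `min_proteins` | 200 | `compartment_efficiency()` | compartments need a few hundred interaction-covered proteins before $E$ rows stabilize at genome scale; the rule is strictly-greater. Desk-scale analyses lower it (the fixture uses 1). |
| `combine` | `"mean"` | scoring | a multi-localized participant opens several compartment routes; the mean is the neutral expectation, `"max"` scores the best route and always dominates the mean. |
| `n_random` | 1000 | `compare_real_vs_random()` | consistent-substitution randomizations per pathway; 1000 resolves Eff-distribution tails at collection scale. |
| `bins` | 20 | chi-square, histograms | pooled-quantile bins for the two-sample test (expected counts stay near $n/20$); equal-width bins on $[0, \max E]$ for the clustering histograms. |
| `k` | 7 | `hierarchical_clusters()` | the number of major groups typically resolved for a full human pathway collection; an eight-group reading is equally defensible, so `k` stays a parameter rather than a constant. |
| `linkage` | `"average"` | clustering | UPGMA is the usual choice for correlation-type dissimilarities and makes no triangle-inequality assumption. |

## Null models

Two permutation nulls destroy localization structure while preserving
pathway topology:

1. **Independent replacement** (`randomize_reactions`): every protein
   occurrence is replaced by a uniform draw from the pool; reaction count
   and slot arities are preserved. This nulls the reaction-efficiency
   distribution.
2. **Consistent substitution** (`randomize_pathway`): one map from the
   pathway's distinct proteins into the pool is drawn and applied
   everywhere, so a hub protein keeps its hub role. The map is injective --
   uniform over injections -- preserving the distinct-protein structure;
   `allow_collisions = TRUE` switches to independent draws for users who
   prefer the laxer reading.

The replacement pool defaults to all proteins occurring in the collection,
sorted, so results do not depend on input order. All randomization derives
per-(pathway, draw) child seeds from the root seed via a fixed string hash,
which makes every draw reproducible and independent of collection order.

The two-sample comparison is a binned chi-square: both samples are binned
on shared pooled-quantile edges, bins whose smaller expected count falls
below 5 are merged into their neighbour (logged), and the 2 x B table is
tested with $df = B - 1$. The type-I error of this construction is checked
by simulation in the test suite (500 same-distribution replicates at
$\alpha = 0.05$).

## Clustering pathways

Pathways are compared by the shape of their reaction-efficiency
distributions: shared equal-width bins on $[0, \max E]$, right-open with a
closed top bin, densities summing to one. The dissimilarity is the
correlation distance $1 - r$ between density vectors, in $[0, 2]$. A flat
(zero-variance) histogram has no defined correlation; its distance is fixed
at 1, the uninformative midpoint, and flagged. The distance need not
satisfy the triangle inequality, which agglomerative linkage tolerates.
Pathways are sorted by id before `hclust`, and cut labels are renumbered by
first appearance, so clustering is permutation-equivariant with
deterministic tie-breaking. Trees export to Newick with merge-height branch
lengths (a two-leaf tree at height $h$ is `(A:h,B:h);`).

Cross-cluster differences in Eff are tested with Kruskal-Wallis: Eff is
bounded, often skewed, and cluster sizes are unequal, so a rank test is the
safe default.

## What the simulator does and does not emulate

`simulate_interactome()` draws every unordered pair independently:
probability $\rho \, p_0$ for pairs sharing a compartment, $p_0$ otherwise
($\rho$ may vary by compartment; a `multi_loc_fraction` of proteins gets a
second compartment, and "shares at least one compartment" is the within
condition, mirroring the counting convention). `simulate_pathways()` draws
reaction pairs with odds multiplied by $\beta$ for co-localized partners,
so $\beta = 1$ collections are exactly localization-blind -- the situation
the permutation nulls assume.

This captures the one signal the method measures: within-compartment
interaction enrichment and its echo in pathway construction. It does *not*
reproduce other properties of real interactomes -- degree heterogeneity
(hubs), annotation noise and incompleteness, database-specific ascertainment
bias, or correlated multi-localization patterns. Passing tests therefore
demonstrate that the estimator and the statistics behave correctly when the
modeled signal is the only signal; they do not certify robustness to
confounders that real databases add.

Study sizes used in the test suite were chosen to keep each check
well-powered at desk scale: enrichment recovery uses 5 compartments x 300
proteins at $p_0 = 0.01$ (about 13,000 edges); null-consistency replicates
use 3 x 80 proteins with 30-40 pathways of 10-15 reactions; planted-cluster
recovery uses 3 x 100 proteins with per-compartment enrichment (2, 6, 18)
and 60 pathways, giving three well-separated histogram archetypes.

## Numerical and degenerate-input choices

* Histogram bins are right-open with a right-closed last bin; a value on an
  interior edge goes to the bin starting there.
* Quantile edges that collapse (heavily tied samples) are de-duplicated; if
  fewer than two bins survive, the test refuses rather than fabricating a
  p-value.
* `Eff` of a pathway with $N = 0$ is `NA` and the pathway is flagged
  unusable; histogram construction refuses such pathways.
* Matrix files store 15 significant digits; the reader enforces symmetry
  and names the first violating cell pair.
* All seeds are kept below $2^{31}$; child seeds are reduced modulo a prime
  near that bound.

## Known limitations

* Protein identifiers are opaque exact-match strings; no cross-database
  mapping is attempted, so the interactome and the localization catalog
  must share a namespace. The fit report states the overlap.
* KGML is read at the granularity of gene-gene `relation` elements;
  `reaction` elements (enzyme/compound chemistry) are ignored, and KGML
  export is limited to all-PPI documents (non-PPI chains use the
  reaction-list table).
* Interaction confidence scores, direction, and sign are ignored.
* The efficiency score is relative: comparing matrices built from
  differently-curated interactomes compares curation as much as biology.
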