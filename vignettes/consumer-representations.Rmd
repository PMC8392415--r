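---
title: "Analysing consumer product representations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing consumer product representations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorep)
```

## The scientific problem

Social-representation theory holds that a group's shared knowledge and
beliefs about an object are organized as a *central core* — consensual,
stable elements that frame how new information is interpreted — surrounded
by peripheral elements that absorb individual variation. For a product like
dry Chenin blanc wine, two panels with different cultural histories (an
"old-world" appellation culture vs a "new-world" varietal culture) can hold
structurally different representations, and those differences should
surface both in the words the product evokes and in how the panels
categorize actual samples, with or without information about the samples'
origin.

`sensorep` implements the full analysis chain for such a design: corpus
statistics on free word associations, the prototypical (central-core)
analysis, DISTATIS on free-sorting partitions with bootstrap confidence
regions and supplementary projections, and a hypergeometric specificity
analysis of group descriptors across conditions.

## Word-association analysis

Each participant evokes four words and rates each on two anchored 7-point
scales (importance, valence). After lemmatization through a hand-built
lexicon (`lemmatize()`; matching is case- and diacritic-insensitive, and
unknown terms pass through normalized with a warning rather than failing),
the corpus is summarized by:

* **diversity index** = distinct lemmas / total tokens (1 = every token
  unique);
* **rarity index** = hapaxes / distinct lemmas;
* token counts per semantic category, with per-category mean importance and
  valence.

Two frequency semantics coexist in this literature and the package keeps
them distinct deliberately. Category tables (`category_table()`) count
*tokens* — every evoked word counts once, so the column totals equal the
corpus sizes. The prototypical analysis (`word_stats()`) counts *citing
participants* per lemma, the degree of sharing. A participant repeating a
lemma counts twice in the first and once in the second; `corpus_summary()`
exposes a `per_participant` switch for users who want the collapsed
convention in summaries too.

**Chi-square forms.** The global test is an uncorrected Pearson chi-square
of independence on the full 8 x 2 table. The per-category test compares the
two panel counts of a single category against equal expected counts
(a+b)/2, i.e. χ² = (a−b)²/(a+b) on 1 df, also uncorrected. The
equal-expected form (rather than one weighted by the slightly unequal panel
sizes, 107 vs 99) is a deliberate choice: it is the form that exactly
reproduces every published category statistic from its printed counts, and
the test suite re-verifies that equivalence. No continuity correction is
applied anywhere, and no multiple-testing correction is applied across the
eight per-category tests — this mirrors the standard presentation of such
tables and is a known limitation: with eight simultaneous tests at α =
0.05, marginal p-values near the threshold should be read cautiously.

ANOVAs on importance/valence are standard one-way decompositions
(`category_anova()`), reporting F, dfs, p and R² = SS_between/SS_total. A
corpus in which every rating is identical returns F = 0 by convention
rather than failing, since a constant corpus carries no evidence either
way.

## Prototypical analysis

Words cited by more than two participants are retained — the package reads
"frequency greater than two" literally as ≥ 3 (`min_frequency = 2`). Two
cut-offs then cross-tabulate the retained words:

* **frequency cut-off** (`frequency_cutoff()`): distinct frequencies are
  sorted in decreasing order and the cut-off is the lower frequency of the
  adjacent pair with the maximal drop. Ties are broken toward the pair at
  higher frequency, which keeps the high-frequency zone small and
  consensual. If all frequencies are equal the method is undefined and the
  function asks for a manual cut-off rather than inventing one.
* **importance cut-off** (`importance_cutoff()`): the unweighted mean of
  the per-word mean importances of the retained words. Averaging at the
  word level (not over the 8 semantic categories) is the package default;
  the two conventions can disagree, and users wanting the category-level
  variant can pass the vector of per-category mean importances directly,
  since the function accepts any numeric vector. On 1–7 anchored scales
  both land near 5 for realistic corpora.

"High" means **strictly greater than** the cut-off on both axes, so a word
sitting exactly on a cut-off is classified low — this matches the
conventional table captions (high > cut-off, low ≤ cut-off) and makes the
boundary behaviour testable. The four quadrants — central core, first
periphery (shared but secondary), contrast zone (important to a subgroup),
third periphery — always partition the retained words.

## Sorting analysis with DISTATIS

Each participant's partition becomes a 0/1 distance matrix (0 = sorted
together). DISTATIS then proceeds in fixed steps, all authored in this
package:

1. **Cross-products**: S = −½ Ξ D Ξ′ with Ξ = I − 1m′ and uniform masses
   m = 1/n (no stimulus weighting — nothing in the design privileges a
   wine), then normalization by the first eigenvalue so λ₁(S) = 1. The
   normalization is part of the method definition even where analyses
   leave it implicit: it equalizes table scales so that agreement, not
   group count, drives the weights. Binary sorting distances are
   Euclidean-embeddable, so these S are positive semidefinite; the test
   suite checks eigenvalues ≥ −1e−10 on random partitions.
2. **RV matrix and weights**: α is the first eigenvector of the RV matrix,
   sign-flipped to be nonnegative (Perron–Frobenius guarantees this for
   PSD inputs) and rescaled to sum to 1. Identical tables get weights 1/K.
3. **Compromise and scores**: S₊ = Σ αₖ Sₖ; eigendecomposition gives
   F = VΛ^½, partial scores Fₖ = SₖVΛ^−½, and Σ αₖ Fₖ = F exactly (checked
   numerically). Dimensions with eigenvalue below max(λ)·1e−12 are
   discarded as numerical noise (the last centering dimension is always
   exactly null). Each retained eigenvector is oriented so its
   largest-magnitude loading is positive, making maps reproducible across
   BLAS implementations; axis orientation is otherwise arbitrary in any
   MDS. Two display dimensions are the default everywhere, matching how
   such maps are read.
4. **Bootstrap regions** (`bootstrap_regions()`): participants are
   resampled with replacement (default 1000 replicates; fewer than 100
   warns); each replicate's RV submatrix, weights and compromise are
   recomputed, and the replicate compromise is projected onto the *fixed*
   reference eigenvectors, F_rep = S_rep V Λ^−½. Projecting instead of
   re-eigendecomposing avoids axis-flipping and axis-swapping artifacts
   that would otherwise require Procrustes alignment; the price is that
   replicate clouds cannot express rotation of the compromise itself.
   Regions are 95% normal-theory ellipses of the replicate clouds. With
   zero perceptual noise all partitions coincide and the regions collapse
   to points.
5. **Supplementary projections** (`project_descriptors()`): a descriptor's
   coordinate is the barycentre of the stimulus factor scores weighted by
   its column profile n_id/n_·d. A descriptor attached to one stimulus
   lands on it; a uniformly used descriptor lands at the origin (the
   centroid of doubly-centered scores). Origin labels are projected the
   same way (`origin_barycentres()`).

The **RV map** of conditions (`rv_map()`) eigendecomposes the RV matrix of
the per-condition *summed* distance matrices directly (the RV-map
construction of the method's own literature), rather than building a
second-order compromise of the four tables; the two constructions are
close in practice but the former is what the map's interpretation — "closer
conditions sorted more similarly" — is defined on.

No significance testing is attached to RV values, and no confidence-region
overlap test is asserted for product instability claims; the regions are
reported and plotted, and their reading is left to the analyst.

## Specificity analysis

With N descriptor tokens pooled over conditions, K of them word w, and a
condition subcorpus of n tokens containing k copies of w, the one-sided
p-value is P(X ≥ k), X ~ Hypergeometric(N, K, n), computed with `phyper`.
Only over-representation is tested by default (the question is whether a
condition *recruits* vocabulary); the under-representation tail sits
behind `tail = "under"`. p-values are raw — no multiple-testing
correction, matching the conventional presentation of specificity tables —
and the same caution as for the category chi-squares applies. Group
descriptions are tokenized on whitespace/punctuation with underscores
preserved, so multiword tags like `south_africa` survive, then lemmatized
through the same lexicon as the association corpus.

## The synthetic panel generators

No raw consumer data are distributed, so the generators are first-class
package code emulating the study conditions:

* **Associations** (`simulate_associations()`): four distinct words per
  participant. The four semantic categories are drawn first, exactly
  multinomially from the profile weights — this makes the category-share
  invariants exact rather than approximate — and then distinct words are
  drawn within each category from a Zipf-ranked choice distribution
  (rank^−z). Ratings are discretized truncated normals on 1–7 around
  per-category means (SD 1.2). The bundled `sa_panel_profile()` /
  `fr_panel_profile()` use the published panel sizes (107 / 99), the
  published category token shares as weights (Sensorial 0.59 for SA) and
  the published per-category valence means; importance means are not
  printed per category, so they were chosen once to place each panel's
  characteristic categories above the 1–7 midpoint (sensory for SA,
  viti/enology and origin for FR), which is what the published central
  cores express. The default Zipf exponent of 1 yields rarity indices near
  0.19 at these corpus sizes.
* **Sorting** (`simulate_sorting()`): stimuli live at latent 2-D points —
  an origin axis (±1 by country) scaled by `origin_weight`, a style axis
  (spread in [−1, 1] within origin) scaled by its complement — and each
  participant perceives them through Gaussian noise (default SD 0.25),
  then groups them by single-linkage clustering cut at a per-participant
  threshold drawn from [0.3, 0.8]; cuts falling outside the admissible
  group-count range [2, 10] are re-cut at the nearest admissible count.
  Single-linkage thresholding is the simplest mechanism that produces the
  graded co-occurrence structure real sorts show while making the two
  limits exact: with `origin_weight = 1` and no noise every participant
  returns the origin partition, and agreement with the origin partition is
  monotone in `origin_weight` (checked by Monte Carlo). The group-count
  range is a free design parameter — nothing in the study reports the
  distribution of group counts — and the descriptor vocabulary is keyed to
  the quadrant of each group's perceived centroid, with origin names
  (`loire`, `south_africa`) attached to origin-pure groups at a
  configurable rate to emulate informed-condition vocabularies.

**What the generators do and do not establish.** They reproduce the
*statistical contrasts* the analysis is designed to detect: a
sensory-dominant vs an origin/viti-dominant association corpus, stable vs
information-shifted sorting structures, condition-specific origin
vocabulary. They do not reproduce every marginal of real data — most
visibly, the bundled lexicon's ~90 lemmas cap the attainable diversity
index below the published 0.31/0.34 at realistic panel sizes (real panels
draw on an open vocabulary), and real sorting noise is not isotropic
Gaussian. Green tests on synthetic panels therefore validate the
*computations* and the direction and approximate size of the designed
effects, not distributional realism of every index.

## Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed and is
byte-reproducible given (inputs, seed); the pipeline records the seed and
per-file MD5 checksums in its manifest, and rerunning a configuration
reproduces identical files. The bundled demonstrations and tests use 50
participants per sorting condition, 100–500 bootstrap replicates and
20-seed Monte-Carlo loops — sizes at which the designed effects are stable
and the full suite runs in well under a minute; production analyses should
raise `n_boot` to the 1000 default.

## Known limitations

* The lexicon-driven lemmatizer does no stemming or POS tagging and no
  bilingual alignment; cross-language comparison relies on the analyst's
  category mapping, as it does in practice.
* No effect sizes beyond R², no log-linear models for the category table,
  and no multiple-testing control anywhere (documented above).
* The RV map carries no inferential statement; with four conditions its
  2-D rendering is exact only up to the retained eigenvalues.
* Bootstrap regions are normal-theory ellipses of projected replicates; a
  percentile convex-hull reading of the same clouds (`$replicates` is
  returned) may differ for small panels.
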