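---
title: "Scoring and validating tumor-immune gene-pair interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating tumor-immune gene-pair interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactmap)
```

## The model

`coactmap` treats a tumor-immune interaction as a *super-additive
co-association*: a pair of genes interacts with respect to an
immune-associated phenotype (IAP) when the phenotype level in patients
where both genes sit on their "active" side exceeds what the two
single-gene associations predict under an independence reference. This is
the same logic as drug-synergy scoring, transplanted from drug doses to
median-split expression strata.

The analysis unit is a (TAP gene, ICP gene, IAP) triple on a cohort of
patients with matched expression and phenotype data. The steps are:

1. **Phenotype scaling.** Raw IAP readouts live on arbitrary scales
   (fractions, signature z-means, counts). To make scores comparable
   across phenotypes every IAP is mapped onto $[0,1]$: values already in
   $[0,1]$ are kept (identity branch); real-valued readouts map through
   $(\tanh(x/\sigma)+1)/2$; nonnegative unbounded readouts through
   $\tanh(x/\sigma)$, with $\sigma$ the sample standard deviation
   ($n-1$ denominator; the choice of denominator is a convention — at
   cohort sizes where the method is usable the difference is negligible).
   Branch selection looks only at the observed range: any negative value
   selects the real-line branch; an input exactly filling $[0,1]$ stays on
   the identity branch. All three branches are strictly increasing, so
   rank-based statistics downstream are unaffected by the choice.

2. **Stratification.** For each pair, samples with both genes measured are
   split at each gene's median; quadrant labels LL/LH/HL/HH record
   (gene1, gene2) levels. Values exactly at the median are labeled L — a
   deterministic convention that keeps quadrants non-empty under skewed
   expression. Because only the ranks enter, the split is invariant to any
   strictly increasing transform of a gene's values; it therefore does not
   matter whether the supplied matrix is on a log scale.

3. **Median deviations.** For a configuration with baseline quadrant $B$,
   the deviation of quadrant $n$ is
   $M_n = \mathrm{med}(x^{scaled}_n) - \mathrm{med}(x^{scaled}_B)$,
   set to zero when $|M_n|$ is below
   $\mathrm{sem}(M_n) = \sqrt{\mathrm{sem}_n^2 + \mathrm{sem}_B^2}$. The
   standard error of a median is estimated with the asymptotic
   normal-theory form $1.2533\,s/\sqrt{n}$. The zeroing suppresses
   direction estimates that are within noise; the boundary case
   $|M_n| = \mathrm{sem}(M_n)$ (probability zero for continuous data) is
   zeroed, the conservative choice.

4. **Configurations and the score.** Four configurations cover the
   a-priori-unknown activating/deactivating roles: both activating
   (baseline LL, target HH), both deactivating (HH → LL), and the two
   mixed cases (LH → HL and HL → LH); the two quadrants not involved give
   the single-gene deviations $M_1, M_2$. The independence reference is
   Highest Single Agent, $M_E = \max(M_1, M_2)$, or Bliss,
   $M_E = M_1 + M_2 - M_1 M_2$; for $M_1, M_2 \in [0,1]$ HSA $\le$ Bliss,
   so Bliss is the stricter reference and its scores never exceed HSA
   scores on the same instance. The combined action score is
   $S = \mathrm{sign}(M)(M_{target} - M_E)$ when $M_{target} - M_E > 0$
   and $0$ otherwise, where $\mathrm{sign}(M)$ is the direction shared by
   the nonzero deviations. If nonzero deviations disagree in direction the
   configuration has no defined reference and yields a missing score;
   zeroed deviations are direction-neutral and do not veto (they were
   zeroed precisely because their direction is unreliable). The best of
   the four configurations is reported; ties resolve in the fixed order
   act_act, deact_deact, act_deact, deact_act so regression runs are
   reproducible. The formula is implemented literally, which means a
   configuration with $\mathrm{sign}(M) = -1$ and positive excess yields a
   negative score; the maximum is taken over signed scores, and such
   interactions surface in the network as "down" edges.

## Statistical validation

Scores are computed for every TAP-ICP pair, then filtered in three stages
(each stage only sees survivors of the previous one, matching the staged
design of the method):

* **Robustness.** The pair is re-stratified and re-scored on resampled
  partial cohorts (70% coverage drawn without replacement, 1000 resamples
  by default). $R$ is the RMSD between complete and partial scores,
  normalized by $|S_{complete}|$; $-\log R > 0$ (i.e. $R < 1$) is
  required. Resamples with missing scores are dropped; if more than half
  are missing the pair is non-robust outright. The cohort-level IAP
  scaling is *not* recomputed per resample: scaled values are per-sample
  quantities and rescaling inside the resampling loop would quietly change
  the phenotype definition mid-procedure.

* **Significance.** The target quadrant's IAP values are compared against
  each of the other three quadrants with two-sided Wilcoxon rank-sum
  (Mann-Whitney) tests; the reported p is the **maximum** of the three, so
  an interaction is only as significant as its weakest contrast. The
  rank-sum rather than signed-rank variant is used because the quadrants
  are disjoint patient groups — a paired signed-rank test is undefined
  here. Exact null distributions are used when both groups have ≤ 25
  untied observations; otherwise the tie-corrected normal approximation.
  Benjamini-Hochberg correction is applied over the robust set, threshold
  $Q < 0.1$.

* **Specificity.** For each gene of the pair, combined action scores are
  computed against partner genes sampled uniformly without replacement
  from the supplied matrix (the analysis "genome"), default 1000, reduced
  with a warning on small matrices. The add-one empirical tail
  $p = (1 + \#\{S_{null} \ge S_{obs}\})/(1 + n_{valid})$ is
  distribution-free and never exactly zero; the reported p is the larger
  of the two genes' values (the least specific side). Null scores are
  cached per focal gene per IAP — the null distribution does not depend on
  the partner under test — with the pair's other gene excluded at p-value
  time. Fewer than 50 valid null scores for either gene makes specificity
  undefined and the pair fails. BH is applied over the
  robust-and-significant set, $Q < 0.1$.

Because BH denominators shrink at each stage, staged filtering can pass a
pair that a single pooled correction would not; this is a property of the
staged design, not an implementation accident.

## Networks

Passing interactions for one IAP become edges; vertices are genes *in an
expression state* derived from the winning configuration's target quadrant
(act_act → both high, deact_act → gene1 low / gene2 high, etc.). A gene
appearing with both states becomes two vertices — the state, not the gene,
is the biological claim. Edge direction records whether the IAP rises
("up", sign +1) or falls ("down") toward the target quadrant, and edges
whose unordered pair occurs in a user-supplied ligand-receptor table are
flagged. Serialization is GraphML plus a flat edge list; rendering is left
to downstream tools.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_group_size` | 10 | samples required per quadrant; medians and their sems are unstable below this |
| `model` | `"hsa"` | additivity reference; `"bliss"` is stricter |
| `n_boot` | 1000 | robustness resamples |
| `coverage` | 0.7 | fraction of cohort per resample |
| `n_random` | 1000 | null partners per focal gene |
| `q_threshold` | 0.1 | FDR threshold for both Q stages |
| `score_cutoff` | 0 | minimum \|S\| entering validation / the network |
| `min_valid_null` | 50 | valid null scores below which specificity is undefined |

## The synthetic generator

`simulate_cohort()` emulates exactly the structure the score detects and
nothing else: per-gene i.i.d. log-normal expression (log-sd 1, per-gene
log-mean uniform on [2, 6] for a realistic dynamic range) and a raw IAP
built as planted single-gene effects on each gene's active side plus an
interaction effect in the target quadrant plus Gaussian noise. Active
sides are defined against each gene's own realized median so the planted
quadrant is the one the pipeline's stratification recovers. Defaults —
400 samples, noise sd 0.5, single effects 0.5, interaction effect 1.5
(three noise sds) — represent a mid-sized cohort with a clearly
super-additive but noise-embedded interaction.

What the generator deliberately omits: gene-gene expression correlation,
tumor purity and cell-type mixing, batch effects, and heavy-tailed or
zero-inflated phenotypes. Passing tests on these cohorts therefore
demonstrate correctness of the statistical machinery and its calibration
under the model's own assumptions, not performance on real tumor data,
where confounding (e.g. immune infiltration driving many genes at once)
is the dominant difficulty and is addressed only partially by the
specificity stage.

`evaluate_recovery()` closes the loop: rank of the planted pair among all
scores, validation outcome, and winning-configuration identity (accepting
the mirrored configuration when gene order is swapped).

## Numerical and design notes

* Degenerate inputs: constant IAPs are rejected at scaling; constant genes
  produce one-sided splits caught by `min_group_size`; all-tied rank-sum
  comparisons return p = 1; pairs whose score is 0 or missing never reach
  robustness (the ratio would be undefined at $S = 0$).
* Determinism: every stochastic step (resampling, null partner draws,
  simulation) takes an explicit seed; derived seeds are small integer
  offsets. Two runs with the same inputs and seed produce byte-identical
  result tables.
* Partial correlations (Spearman, controlling for the remaining cell-type
  columns) are computed on ranks via residualization, with a
  precision-matrix route kept as an internal cross-check; p-values use the
  t approximation with $n - 2 - k$ df and Bonferroni adjustment across
  cell types. Duplicate/collinear control columns are dropped with a
  warning.
* Survival comparisons use the standard hypergeometric-variance log-rank
  test across the four quadrants, plus an optional two-group
  target-vs-baseline contrast, since published stratifications vary
  between the two.
* Problem sizes in the test-suite simulations (e.g. 200 oracle cohorts of
  20-60 samples; 20 generator seeds at 400 samples with 200 resamples and
  200 null partners) were chosen as the smallest sizes at which the
  checked properties are stable, keeping the default run fast.

## Known limitations

* Median splits discard within-quadrant dose information; weak graded
  interactions may be invisible.
* The specificity null is drawn from the supplied matrix; with a small or
  curated matrix it is a null of "other genes on this panel", not of the
  genome.
* Negative-sign (IAP-decreasing) interactions use the literal signed
  score; comparing magnitudes across signs should be done on $|S|$.
* Mutation-status stratification and multi-IAP global FDR control are
  extension points, not implemented features.
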