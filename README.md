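# coactmap

Combined-action scoring of tumor–immune gene-pair interactions.

## What problem does this solve?

Immune evasion in tumors is rarely driven by one gene at a time: whether an
immune checkpoint (ICP) such as *CTLA4* or *CD274* matters in a given tumor
often depends on the state of tumor-associated process (TAP) genes expressed
in the same ecosystem. `coactmap` detects such **combinatorial interactions**
from bulk expression cohorts by asking whether a TAP–ICP gene pair is jointly
associated with an immune-associated phenotype (IAP) — e.g. *IFNG*
expression, leukocyte fraction, or a signature score — more strongly than
either gene alone would predict.

It is aimed at computational biologists analyzing patient cohorts
(genes × samples expression plus per-sample phenotype readouts) who want a
statistically validated, network-level map of which checkpoint/tumor gene
pairs co-associate with an immune phenotype.

## The method

For a gene pair (g₁, g₂) the cohort is stratified into four sub-cohorts
(LL, LH, HL, HH) at each gene's median expression. Each IAP is first rescaled
onto [0, 1] with a branchwise sigmoidal transform
(identity if already in [0, 1]; `(tanh(x/σ)+1)/2` for real-valued readouts;
`tanh(x/σ)` for nonnegative ones, σ = sample sd).

For each of four activating/deactivating configurations (each fixing a
baseline and a target quadrant), the median deviation of the scaled IAP from
baseline is computed per quadrant,

M_n = med(x_scaled, quadrant n) − med(x_scaled, baseline),

zeroed when |M_n| is below its standard error
`sem(M_n) = sqrt(sem_n² + sem_baseline²)`. The expected target deviation
under independent action is either the Highest Single Agent reference
M_E = max(M₁, M₂) or the Bliss independence reference
M_E = M₁ + M₂ − M₁·M₂, and the **combined action score** is

S = sign(M) · (M_target − M_E)  if M_target − M_E > 0, else 0,

where sign(M) is the shared direction of the nonzero deviations (a sign
conflict yields a missing score). The best of the four configurations is
reported per pair.

Every scored pair is then validated in three stages:

1. **Robustness** — re-stratify and re-score partial cohorts (default 70%
   coverage, 1000 resamples); R = RMSD(S_complete, S_partial)/|S_complete|;
   robust when −log(R) > 0.
2. **Significance** — two-sided Wilcoxon rank-sum tests of the target
   quadrant's IAP against each other quadrant; the reported p is the maximum
   of the three; BH-corrected over the robust set (Q < 0.1).
3. **Specificity** — each gene's score is compared to an empirical null of
   scores against randomly sampled partner genes (default 1000); the larger
   of the two add-one tail p-values is BH-corrected over the surviving set
   (Q < 0.1).

Validated interactions are assembled into a per-IAP network with gene-state
vertices (high/low), direction-of-effect edges, and ligand–receptor
annotation from a user-supplied pair table. Auxiliary statistics: Spearman
partial correlations of a gene with immune cell-type fractions (controlling
for the other cell types, Bonferroni-adjusted) and log-rank survival
comparisons of expression-stratified groups.

## Worked example

The built-in generator plants a known interaction (a both-activating pair
whose target quadrant gains three noise-sd of IAP on top of additive
single-gene effects) in an otherwise null cohort:

```r
library(coactmap)

cohort <- simulate_cohort(sim_config(seed = 42))       # 400 samples, 62 genes
iap <- scale_iap(setNames(cohort$phenotypes$sim_iap,
                          cohort$phenotypes$sample), "sim_iap")
scores    <- score_pairs(cohort$expr, iap,
                         c("TAP1", sprintf("G%03d", 1:30)), "ICP1")
validated <- validate_interactions(cohort$expr, iap, scores,
                                   n_boot = 200, n_random = 200, seed = 1)
glance(validated)
#>   n_pairs n_scored n_robust n_significant n_passed model q_threshold n_boot
#> 1      31       25       18             1        1 hsa           0.1    200

dplyr::filter(tidy(validated), passed)
#>   tap   icp   iap     config      S  sign M_target   M_E      R p_significance
#> 1 TAP1  ICP1  sim_iap act_act 0.234     1    0.475 0.241 0.0679       9.07e-34

build_network(validated)
#> <coactmap_network> IAP: sim_iap | 2 nodes, 1 edges
```

Of 31 scored pairs, 25 have a nonzero score and 18 are robust, but only the
planted pair survives significance and specificity: its winning
configuration is the planted `act_act`, its target-quadrant deviation
(0.475 on the [0, 1] IAP scale) exceeds the Highest-Single-Agent reference
(0.241) by S = 0.234, and its resampling ratio R = 0.068 means the score is
stable (−log R ≈ 2.7). `autoplot(validated)` draws the stage plot and
`autoplot(build_network(validated))` the network; `write_interaction_table()`
and `write_network()` serialize results to TSV/GraphML.

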