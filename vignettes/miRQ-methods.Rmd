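---
title: "miRQ: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRQ: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRQ)
```

## The model

`miRQ` ranks miRNAs by how strongly they appear to perturb a tumor
transcriptome, using three per-miRNA features computed from a paired
miRNA/mRNA expression cohort and a predicted-target table:

* **F1, mean expression** `a_i`: the arithmetic mean of the miRNA's
  expression over all tumor samples. The premise is that an abundant miRNA
  has more capacity to repress targets. Only tumor samples enter; normal
  samples are never used.
* **F2, mean absolute correlation** `c_i`: the mean of |Pearson r| between
  the miRNA and *every* gene in the matrix. Direct repression, indirect
  activation and transcription-factor relay all leave correlation traces of
  either sign, which is why the absolute value is averaged and why the
  average runs over all genes rather than predicted targets only.
* **F3, predicted target count** `t_i`: distinct genes paired with the
  miRNA after the union of prediction sources is deduplicated. This feature
  depends only on sequence-based predictions, so it is identical across
  cohorts.

The three features are deliberately heterogeneous (an expression level, a
correlation, a count), so they are compared on the rank scale only. Each
feature vector is turned into ranking ratios `rank/M` with average ranks on
ties, once descending (`RD`: the best value gets `1/M`) and once ascending
(`RI`). For one miRNA and one direction, the three ratios are combined into
the probability that the order statistics of three independent
Uniform(0,1) draws fall below them:

$$Q = N!\,V_N,\qquad V_0 = 1,\qquad
V_k=\sum_{i=1}^{k}(-1)^{i-1}\,\frac{V_{k-i}\;r_{(N-k+1)}^{\,i}}{i!},$$

with $N=3$ and $r_{(1)}\le r_{(2)}\le r_{(3)}$ the sorted ratios (the
recursive solution of Stuart et al., 2003). $Q_1$ (from `RD`) is small when
a miRNA ranks uniformly high; $Q_2$ (from `RI`) is small when it ranks
uniformly low. The final score adds the ascending ranking of $Q_1$ to the
descending ranking of $Q_2$, $R_Q = R_{Q1} + R_{Q2}$, ranked ascending. The
second direction exists to damp miRNAs whose good $Q_1$ rests on a single
dominant feature: such miRNAs also look "partly irrelevant" and are
penalized through $R_{Q2}$.

Properties the test suite verifies: $Q(r,\dots,r)=r^N$ exactly, the $N=1,2$
closed forms, agreement with an independent simplex-integration oracle and
with Monte-Carlo order statistics, monotonicity in each ratio, and the
dominance invariant (a miRNA weakly dominating another on all three
features never receives a worse combined rank).

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `transform` | `readExpressionMatrix()` | `"none"` | `"log2p1"` applies `log2(x+1)`, the usual choice for RNA-Seq counts. Whether correlations are computed on raw or log scale is a genuine modelling choice left to the user. |
| `weights` | `integrateAverageRatio()` | `(1,1,1)` | Baseline integrator only; the order-statistics path is weight-free by design. |
| `fraction` | `relatedGenes()` | `0.01` | Top fraction of genes by &#124;PCC&#124; (count `ceiling(fraction * G)`, ties at the cutoff included) unioned with validated targets to form a miRNA's query gene set. |
| `alpha` | `enrichGeneSets()` | `0.05` | Significance threshold on BH-adjusted q-values. |
| `fraction` | `splitExtremes()` | `0.10` | Per-tail fraction for the under/over expression groups (nearest-rank quantile, days for all times). |

## Identifier matching

All readers normalize identifiers the same way: trim whitespace,
lowercase, strip a leading `hsa-`. Mature-vs-precursor miRNA naming (e.g.
microarray vs RNA-Seq platforms) is *not* reconciled — a documented
deterministic rule was preferred over silent fuzzy matching, so users
mixing platforms must harmonize names upstream. Rows containing missing
values are dropped at load time with a count, since no imputation rule is
defensible for these features.

## Numerical choices

* Ranking ratios are `rank/M`, not `(rank-1)/M`: the best rank keeps a
  small but nonzero ratio, so $Q$ of a uniformly best miRNA is positive
  and the ratio of the worst is exactly 1.
* Ties get average ranks everywhere ranks feed the Q recursion; the final
  permutation breaks `R_Q` ties by smaller `R_Q1`, then lexicographic id,
  making output deterministic.
* Hypergeometric tails are computed in log space (`phyper(log.p = TRUE)`),
  so overlap p-values far below 1e-40 remain finite; the upper tail
  includes the observed count, `P(X ≥ x)`, the standard over-representation
  convention, which also reproduces published overlap p-values computed
  from printed counts.
* Zero-variance genes are excluded from the F2 average *globally*, so every
  miRNA is averaged over the same gene universe; a zero-variance miRNA gets
  `c = 0` with a warning rather than an error.
* The enrichment universe defaults to all genes appearing in the gene-set
  collection (overridable via `readGMT(background=)`); BH correction is
  applied per miRNA across its sets, not globally across miRNAs.
* The survival split uses nearest-rank quantiles with inclusive
  boundaries; if ties make the two extreme groups overlap, the input is
  degenerate and an error is raised instead of silently rebalancing.
* The group-difference test is the log-rank test — the survival analysis
  is specified only as Kaplan-Meier stratification, and the log-rank test
  is its universal companion.
* The DE baseline uses Welch's unequal-variance t-test, the safer default
  when normal groups are far smaller than tumor groups.

## The synthetic generator

`generateBundle()` emulates the full input bundle with planted ground
truth. Drivers carry signal in each feature channel: a mean-expression
shift of `driverExprShift` noise-SD units (F1); `driverTargetCount`
predicted targets against `backgroundTargetCount` for background miRNAs
(F3); and a per-driver Gaussian latent factor entering the driver and each
of its targets with loading `driverCorr`, the target-side sign randomized
so that only |PCC| carries the signal, mirroring the method's use of
absolute correlation (F2). Survival times are exponential with hazard
$(1/500)\cdot s^{z}$ — baseline mean 500 days, a glioblastoma-like scale —
where $z$ is the sample's mean standardized driver expression and
$s$ = `survivalEffect`; censoring is an independent exponential calibrated
to censor roughly `censorRate` (default 0.3, between the ~21% and ~48%
censoring typical of aggressive and less aggressive cohorts). All
randomness flows from one seed; the global RNG state is restored on exit.

The default configuration (100 samples, 1000 genes, 200 miRNAs, 10
drivers, shift 3, loading 0.8, targets 50 vs 5) is the strong
planted-signal condition under which the validation suite requires all ten
drivers in the top 20 in ≥95% of 50 replicates; `nullSyntheticConfig()`
removes every signal channel and recovery must drop to chance. The suite
uses cohorts of 40-200 miRNAs and up to 300 samples — comfortably past the
regime where rank integration stabilizes, while keeping the full suite
fast.

What the generator does **not** emulate: TCGA marginal distributions
(counts are Gaussian around a positive mean, not negative-binomial), batch
effects, correlated driver modules, annotation sparsity or incompleteness,
and mature/precursor naming mismatches. Passing the recovery tests
therefore shows the ranking machinery is correct and well-behaved under
its own assumptions — not that the three features suffice for any
particular real cohort.

## Known limitations

* F2 costs one correlation per miRNA-gene pair; for a 1046 x 20k cohort
  this is a single `cor()` call on dense matrices and fits easily in
  memory, but extremely large cohorts may want chunking.
* The combined score `R_Q` is a deterministic aggregate; no null
  distribution or p-value is attached to it, by design.
* With heavy ties (e.g. many miRNAs sharing a target count) the average
  ranks compress the ratio scale; ordering among fully tied miRNAs is the
  documented lexicographic convention, not evidence.
* The per-tail survival split discards the middle 80% of samples — a
  deliberate trade of power for contrast, which at small cohort sizes
  (n ≈ 100) leaves the log-rank test underpowered, as the worked example
  in the README shows.
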