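# miRQ

Prioritization of cancer-related microRNAs from paired miRNA/mRNA tumor
expression data, by order-statistics rank integration.

## The problem

miRNAs that drive tumor biology tend to leave three footprints in a tumor
cohort: they are abundantly expressed, their expression co-varies with large
parts of the transcriptome, and they have many sequence-predicted target
genes. No single footprint is reliable on its own; `miRQ` combines all
three into one ranking and provides the evaluation machinery (annotation
curves, overlap tests, pathway enrichment, survival stratification) to
judge the result. It is aimed at computational biologists with paired
tumor expression matrices (e.g. TCGA-style cohorts) and a predicted
miRNA-target table.

## The method

For each of the M miRNAs, three features are computed:

- **F1** — `a_i`: mean expression across all tumor samples,
- **F2** — `c_i`: mean absolute Pearson correlation between the miRNA and
  *all* genes in the matrix (zero-variance genes excluded globally),
- **F3** — `t_i`: number of distinct predicted target genes (duplicates
  across prediction sources removed).

Each feature is converted to ranking ratios `rank/M ∈ (0, 1]` in both
directions: descending (`RD`, large values get small ratios) and ascending
(`RI`). Per miRNA, the three ratios of a direction are integrated by the
joint cumulative distribution of uniform order statistics,

    Q = N! · V_N,   V_0 = 1,
    V_k = Σ_{i=1..k} (−1)^(i−1) · V_{k−i} · r_(N−k+1)^i / i!,

with N = 3 and the ratios sorted ascending (the Stuart et al. recursion);
`Q` is the probability that N uniform order statistics fall below the
observed ratios, so a miRNA ranking uniformly well gets a small `Q1`
(descending direction) and a large `Q2` (ascending direction). `Q1` is
ranked ascending into `R_Q1`, `Q2` descending into `R_Q2`, and the final
ranking sorts `R_Q = R_Q1 + R_Q2` ascending. Using both directions keeps a
single strong feature from dominating the result. Average-ratio, weighted
and inverse-normal baselines are included for comparison.

## Worked example

All inputs can be simulated: the generator plants "driver" miRNAs carrying
signal in all three features, plus interaction, annotation, gene-set and
clinical fixtures (see `vignette("miRQ-methods")`).

```r
library(miRQ)

bundle <- generateBundle(syntheticConfig(seed = 42))
ft  <- buildFeatureTable(bundle$dataset, bundle$interactions)
res <- integrateRanks(ft)
res
#> IntegrationResult with 200 miRNAs
#>        mirna           q1        q2 rq1 rq2 rq final_rank
#> 65  mir-0065 4.812500e-06 0.9999153   1   1  2          1
#> 128 mir-0128 1.128125e-05 0.9985036   2   2  4          2
#> 49  mir-0049 1.881250e-05 0.9841711   3   3  6          3
#> 47  mir-0047 3.612500e-05 0.9555046   5   6 11          4
#> 24  mir-0024 7.734375e-05 0.9697649   7   4 11          5
#> ...
```

Small `q1` (top ranks on all features at once) and large `q2` push a miRNA
to the top. Evaluation against the annotation list (here, the planted
drivers):

```r
top20 <- head(rankedIds(res), 20)
sum(bundle$truth %in% top20)
#> 10                         # all 10 planted drivers recovered

curve <- cumulativeRatio(rankedIds(res), bundle$annotation)
curve[c(10, 20, 50), ]
#>     k count ratio
#> 10 10    10   1.0
#> 20 20    10   0.5
#> 50 50    10   0.2

hypergeomOverlap(M = 200, K = 10, n = 20, x = curve$count[20])
#>     M  K  n  x            p   log10_p
#> 1 200 10 20 10 8.229298e-12 -11.08464
```

The cumulative ratio is the fraction of annotated miRNAs among the top k;
the overlap p-value is the upper-tail hypergeometric probability of seeing
that many annotated miRNAs in the top 20 by chance. With a larger cohort
the planted survival effect becomes visible in the extreme-expression
split:

```r
b300 <- generateBundle(syntheticConfig(nSamples = 300, seed = 42))
s <- mirnaSurvival(b300$dataset, b300$truth[1])
sprintf("%s: n_under=%d n_over=%d chisq=%.2f p=%.3g",
        s$mirna, s$n_under, s$n_over, s$statistic, s$p)
#> "mir-0024: n_under=30 n_over=30 chisq=6.74 p=0.00942"
```

The same flow runs from files via `runPipeline()` (YAML config) or the
`exec/mirq` command-line wrapper (`mirq simulate | features | integrate |
evaluate | run`).

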