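# markpatterns

Differential histone-modification analysis for three-condition designs.

`markpatterns` is for epigenomics analysts who have ChIP-seq coverage for a
repressive or activating histone mark (e.g. H3K27me3, H3K27ac) plus Input
chromatin in **three genotypes or conditions** — a healthy *reference*, a
*disease* state, and a *rescue* (e.g. a second knockout that reverts the
phenotype) — and want to know which genes or peaks gain the mark in one
state but not another, and which pathways those genes belong to.

## The statistics at the core

**Increased/Unchanged (I/U) calling.** For each unit (a gene's proximal
window, by default −5 kb of the 5′ end to +1 kb of the 3′ end including
the gene body; or a peak interval) and each condition, the per-bin CPM of
the ChIP library is compared to its Input with a one-sided Mann–Whitney
U test. The unit is **Increased (I)** in that condition iff

> p < 0.05 **and** fold-change > 1.5,

where the fold-change is the ratio of pseudocount-adjusted mean bin
intensities. Otherwise it is **Unchanged (U)**. The conjunction is strict:
no p-value rescues a fold-change at or below 1.5.

**Pattern classification.** The three per-condition letters form a code in
(reference, disease, rescue) order — one of 2³ = 8 patterns. The four
codes that change in disease relative to reference and inform the rescue
are the dynamic classes

| class | code | reading |
|---|---|---|
| GP1 / PP1 | IUI | lost in disease, restored by rescue |
| GP2 / PP2 | IUU | lost in disease, not restored |
| GP3 / PP3 | UII | gained in disease, kept in rescue |
| GP4 / PP4 | UIU | gained in disease, reverted by rescue |

(GP = gene-based, PP = peak-based); the other four codes are *static*.
Peak-based calls additionally pass a **consistency filter**: the per-bin
log2 fold-change of every I library must be stochastically greater than
that of every U library (pairwise one-sided Mann–Whitney p < 0.05), else
the peak is demoted to static.

**Gene-set enrichment.** For a pattern `pt` with genome-wide background
probability `p_b(pt)` (the fraction of all assessed genes in that class),
a gene list of size `n` containing `k` genes of that class gets

    P = P(X > k),  X ~ Binomial(n, p_b(pt))
      = 1 − Σ_{i=0..k} C(n,i) p_b^i (1−p_b)^(n−i)

computed in a numerically stable survival form.

A negative-binomial coverage simulator with planted I/U codes, disjoint
gene windows and emitted ground truth makes the whole pipeline testable
end to end without any external data.

## Worked example

```r
library(markpatterns)

ds    <- simulate_dataset(simulation_config(seed = 42, n_genes = 60,
                                            chrom_length = 1.2e6))
calls <- call_gene_patterns(ds$tracks, ds$genes)
summary(calls)
#>   class count percent
#> 1   GP1    12      25
#> 2   GP2    12      25
#> 3   GP3    12      25
#> 4   GP4    12      25
#> 5 total    48     100

evaluate_recovery(calls, ds$truth)$confusion
#>         predicted
#> truth    GP1 GP2 GP3 GP4 static
#>   GP1     12   0   0   0      0
#>   GP2      0  12   0   0      0
#>   GP3      0   0  12   0      0
#>   GP4      0   0   0  12      0
#>   static   0   0   0   0     12
```

The summary counts dynamic genes per class with integer percentages over
the dynamic total (48 of 60 simulated genes here; the 12 planted static
genes are excluded from the denominator). The confusion matrix shows that
every planted class was recovered exactly. Per-gene rows carry the code,
class, and per-condition p, fold-change, I/U call and BH-adjusted q:

```r
calls[3, c("unit_id", "code", "class", "p_reference", "fc_reference")]
#>    unit_id code class  p_reference fc_reference
#> 3 gene_003  IUI   GP1 3.548811e-10     1.954698
```

Enrichment against gene sets (GMT in, TSV out via the pipeline layer):

```r
sets <- list(gp1_like = ds$truth$gene_id[ds$truth$class == "GP1"][1:8],
             random   = ds$truth$gene_id[c(3, 9, 17, 25, 33, 41)])
head(enrich_gene_sets(calls, sets), 3)
#>        set pattern n k p_b p_value       q
#> 1 gp1_like     GP1 8 8 0.2 0.00000 0.00000
#> 2   random     GP1 6 2 0.2 0.09888 0.09888
#> 3   random     GP2 6 2 0.2 0.09888 0.19776
```

A set consisting entirely of GP1 genes has `k = n`, and the strict upper
tail `P(X > k)` is 0 — maximal enrichment under this test's convention.

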