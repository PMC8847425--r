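---
title: "Calling dynamic histone-mark patterns across three conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling dynamic histone-mark patterns across three conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markpatterns)
```

## The problem

Broad histone marks such as H3K27me3 do not lend themselves to the
sharp-peak differential tools built for transcription factors: the signal
spreads over gene bodies and flanks, and the scientific question in a
reference / disease / rescue design is not "is this site different
between two samples" but "which of the 2^3 cross-condition
presence/absence patterns does this unit follow". `markpatterns`
implements that analysis: per-condition Increased/Unchanged (I/U) calling
of a mark against Input chromatin, classification of the resulting
three-letter codes, and a binomial test for which gene sets are enriched
in each dynamic class.

## The calling model

Each unit is a genomic region: a gene's proximal window or a peak
interval (e.g. islands from a broad-domain caller, consumed as BED).
Coverage is binned at a fixed width, normalized to counts per million
(CPM) per library, and the bins overlapping the unit are extracted for
the ChIP and the Input library of each condition.

The test is a one-sided Mann–Whitney U test of the ChIP bins against the
Input bins — "is the mark's intensity stochastically higher than
background here". Rank tests suit this signal because bin intensities
are overdispersed counts with occasional extreme bins; means and
t-statistics are fragile there, ranks are not. The designation is

* **I** iff p < `alpha` (default 0.05) *and* fold-change > `fc_min`
  (default 1.5), where the fold-change is
  `(mean(chip) + c) / (mean(input) + c)` with pseudocount `c`;
* **U** otherwise.

The two thresholds play different roles: the p-value guards against rank
separation arising by chance, the fold-change guards against
statistically solid but biologically trivial shifts. The conjunction is
strict and tested as such — no p-value, however small, can rescue a
fold-change at or below `fc_min`.

No multiple-testing correction enters the designation; the raw p < 0.05
rule is the procedure being reproduced. A Benjamini–Hochberg `q_` column
is emitted alongside for transparency so a user can see how calls would
thin out under FDR control.

### Codes and classes

The per-condition letters are concatenated in the configured condition
order, reference first. Of the 8 codes, 4 describe dynamic regulation in
disease relative to reference with an informative rescue: IUI, IUU, UII,
UIU map to classes 1–4 (GP prefix for genes, PP for peaks); the rest are
static. The mapping is total and bijective on the dynamic codes, which
the tests assert by enumeration.

### The peak-mode consistency filter

Peak-based calling adds a second stage: for every (I-condition,
U-condition) pair, the per-bin log2 fold-change vector of the I library
must be stochastically greater than that of the U library (one-sided
Mann–Whitney p < `consistency_alpha`, default 0.05). A peak whose
scalar calls straddle the thresholds but whose bin-level enrichment
profile does not actually separate the I and U libraries is demoted to
static. All-I and all-U codes pass vacuously. Gene mode evaluates genes
directly and skips this filter by default (both behaviours are
overridable), mirroring the simpler gene-based procedure.

Demotion is monotone in `consistency_alpha`: tightening it can only move
peaks from dynamic to static, a property the suite checks on random
instances.

### Windows

The default gene window runs from 5 kb upstream of the 5′ end to 1 kb
downstream of the 3′ end, *including* the gene body, strand-aware, and
clipped to the chromosome. We read "the −5 kb to +1 kb neighboring
region around a gene" as body-plus-flanks because a broad repressive
mark covers the body; the alternative pure-flank reading is available by
configuring the window. Acetylation mode (`mode: acetylation` in the
pipeline config) switches to the upstream 5 kb only, the convention for
a promoter/enhancer mark, and forces the downstream flank to 0.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | — | the raw significance rule being reproduced |
| `fc_min` | 1.5 | ratio | biological-effect floor of the I call |
| `consistency_alpha` | 0.05 | — | pairwise filter threshold, peak mode |
| `pseudocount` | 0.25 | CPM | stabilizes fold-changes in sparse bins without dominating typical signals (~tens of CPM) |
| `bin_size` | 200 (simulator), 50 supported | bp | coverage-quantification granularity; results are insensitive within this range because the rank test sees tens of bins either way |
| `upstream_bp` / `downstream_bp` | 5000 / 1000 | bp | the gene-proximal window described above |
| `min_bins` | 4 | bins | below this a rank test is uninformative; such units are called U with a `low_coverage` flag rather than given a meaningless p |

## Numerical choices

* **Coordinates** are 0-based half-open everywhere internally (BED
  native); GTF input is converted on read. Chromosome names must match
  exactly across inputs — no `chr1`/`1` aliasing is attempted, a
  mismatch is an error.
* **bedGraph values** are treated as per-bp depth: a record contributes
  `value × overlap-width` mass to each bin, so total mass is conserved
  regardless of record fragmentation (tested to 1e-6 relative).
* **Boundary bins** overlapping a window are included whole; the rank
  test is insensitive to one partial bin and the contract stays simple.
* **Mann–Whitney p-values** use the exact U distribution for tie-free
  samples of moderate size and a tie-corrected normal approximation with
  continuity correction otherwise; a region where every bin value is
  identical across both libraries returns p = 1. Exactness is verified
  against full permutation enumeration for all size combinations with
  min(n1, n2) ≤ 8.
* **The enrichment tail** is `P(X > k)` — strictly greater, following
  the summation limit of the defining formula — computed via the
  binomial survival function and verified against direct term summation
  to 1e-12 relative for n ≤ 30. The strict tail makes the test
  conservative (a `k = n` list gets p = 0, and a list can never be
  "enriched" for a class it merely matches); conservatism under the null
  is confirmed by simulation.
* **The enrichment universe** is the set of genes that received a
  pattern assessment, not all annotated genes — the background
  probability is "the percentage of assessed genes in the class", so the
  two must share a denominator.
* **Percentages** in pattern summaries are rounded half away from zero;
  on the published partition (2293/786/154/66 of 3299) this prints
  70/24/5/2.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the three-condition design the analysis
assumes: one ChIP and one Input library per condition (replicates are
taken as pre-merged), negative-binomial bin counts (default dispersion
0.1 — overdispersion is the realistic stressor for a rank test, which a
Poisson model would understate), genes placed so that their windows are
disjoint (making planted truth unambiguous), uniform strands, and
planted I/U codes with the ChIP mean multiplied by the planted
fold-change (default 3, i.e. log2 1.585) inside I-state windows.
Defaults — 200 genes of 2–4 kb on a 4 Mb chromosome, 200 bp bins so each
window holds 40–50 bins, Input mean 10 counts/bin, classes 20 % each of
GP1–GP4 and static — are the study conditions for the recovery checks;
everything is deterministic in the seed, down to byte-identical bedGraph
output.

Near-threshold behaviour is exercised separately by planting
fold-changes of 1.3 and 1.6 around the 1.5 cutoff.

Real data differ in ways the simulator deliberately omits: fragment-level
artifacts, GC and mappability bias, overlapping genes and shared
domains, copy-number distortion of Input, and composition effects
(CPM normalization deflates apparent fold-changes when a large fraction
of the genome gains signal — visible even in the simulation, where a
planted 3× count ratio yields a CPM fold-change nearer 2, comfortably
above threshold but not 3). Passing recovery tests therefore show the
inference machinery is correct under the stated statistical model, not
that threshold choices are optimal for any particular real dataset.

## Problem sizes

The shipped checks run at desk scale by design: recovery on the 200-gene
default simulation (~20 000 bins × 6 tracks, under a minute end to end),
permutation-enumeration oracles up to min(n1, n2) = 8, the binomial
oracle grid at n ≤ 30, and 2000 random sets for null calibration.
Genome-scale peak counts from real experiments (tens of thousands of
islands) are out of scope for the test suite, though the code paths are
the same.

## Known limitations

* Exactly three conditions; the code/classify machinery assumes the
  2^3 design.
* No replicate-aware variance modelling or spike-in normalization; CPM
  only.
* Enhancer handling is reduced to an optional user-supplied
  enhancer-to-gene interval map consumed when assigning peaks to genes.
* Pathway results are sorted by raw binomial p (the q column is
  informational), and the binomial ignores the without-replacement
  structure of finite gene lists — both inherited from the procedure
  being reproduced.
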