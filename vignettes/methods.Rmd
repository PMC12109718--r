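---
title: "Methods: quantifying and comparing m6A methylation on two-channel arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and comparing m6A methylation on two-channel arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Aarray)
```

## The measurement model

An m6A epitranscriptomic microarray splits each RNA sample by anti-m6A
immunoprecipitation into two pools that are labeled with different dyes
and hybridized to the same array: the IP fraction (methylated copies,
Cy5) and the supernatant fraction (unmethylated copies, Cy3). For a
transcript whose copies are partly methylated, the two channel signals
estimate the methylated and unmethylated amounts, so three per-transcript
quantities follow directly:

* **m6A quantity** `= IP` — the amount of methylated copies. It is
  comparable across samples after normalization and is the variable on
  which differential methylation is called.
* **expression** `= IP + Sup` — total copies, methylated plus
  unmethylated.
* **m6A methylation level** `= IP / (IP + Sup)` — the fraction of copies
  carrying the mark, a unitless proportion in (0, 1).

These definitions make two identities structural rather than empirical:
`expression = quantity + unmethylated` and
`level = quantity / expression`. The test suite asserts both to 1e-9 on
every fixture; they can only fail through numerical error, never through
biology.

The assumptions are the platform's: channel intensities are proportional
to RNA amounts within a sample after spike-in scaling; antibody capture
efficiency is common to all transcripts (it cancels in between-sample
fold changes of quantity, but a transcript-specific capture bias would
bias levels); and probes measure their annotated transcript only.

## Spike-in normalization

Arrays drift in overall intensity (labeling yield, scanner gain). Each
array carries exogenous spike-in RNAs at fixed amounts; on the log2
scale their mean should therefore be equal across arrays. Per channel,
each sample is shifted by

```
offset_s = mean(log2 spike-ins in s) − grand mean over samples
x'_{p,s} = log2(max(x_{p,s}, 1)) − offset_s
```

The grand mean is the anchor so that normalized values stay on the
intensity scale of the experiment and are comparable across samples,
which the cross-group fold changes require. The transform is additive per
sample, hence monotone within a sample, and idempotent (a second pass
finds all offsets numerically zero). Raw intensities are floored at 1
fluorescence unit before the log so near-zero scanner noise cannot
produce huge negative logs; consequently idempotence is exact only for
signals above the floor, which spike-ins always are in practice.
Normalization refuses to run with fewer than two spike-in probes or with
a spike-in flagged absent in any sample — a drifting anchor is worse than
an explicit failure.

## Probe selection

A probe enters the analysis if it has a present (P), marginal (M) or
quality-control (QC) flag in at least one sample of either fraction;
probes absent (A) everywhere are dropped. Two consequences are worth
stating. First, the rule is deliberately permissive: one detected sample
among all arrays keeps the probe, so absent cells of retained probes
still contribute their (background-level) intensities to group means.
The generator reproduces this: dropout cells keep a small positive
intensity and are marked only by their flag, and on noisy simulations
this measurably inflates the changed-transcript counts — visible in the
`analysis/` stage logs. That is a property of flag-only filtering, not a
bug in the arithmetic, and recovery checks therefore isolate it (below).
Second, QC flags count toward selection, but spike-in probes themselves
are always excluded from the selected set: control probes must never
enter differential tables.

## Multi-probe transcripts

Transcripts with several selected probes are collapsed by the mean of
linear-scale probe intensities per channel before any ratio is taken
(ratio of means, not mean of ratios): low-intensity probes make
per-probe ratios unstable, while the linear mean keeps the conservation
identities exact. Transcripts left with no selected probe are omitted
with a message rather than an error — on real arrays this is routine,
and failing the run for it would be wrong.

## Differential classification

Per comparison (test vs reference), the per-transcript statistic is the
difference of group means of log2 quantity — the log2 fold change of
geometric means. A transcript is hypermethylated when its fold change is
at least 1.5-fold up (`log2fc ≥ log2 1.5 ≈ 0.585`), hypomethylated when
at least 1.5-fold down; the boundary is inclusive, and a 1e-9 epsilon on
the log2 cut absorbs round-off so that a fold change of exactly 1.5
is always called (log2(150) − log2(100) and log2(1.5) differ in the last
ulp). The 1.5 interpretation is the conventional platform cut-off; the
alternative reading (|log2fc| ≥ 1.5, i.e. 2.8-fold) would be described
as a different fold change altogether. The threshold is a parameter
(`fc_threshold`) in any case. No per-transcript variance test or p-value
is computed: with pooled-sample arrays and n = 3 arrays per group,
fold-change-only selection is the platform's convention, and designs
with fewer than two arrays per group are rejected outright.

Direction proportions among changed transcripts are rounded to one
decimal, with the hypo percentage computed as `100 − pct_hyper` so the
pair always sums to exactly 100.

## Reversal intersections

The scientific question of an insult/treatment design is which
transcripts the treatment pushes back. Two directional intersections
answer it: **attenuation** = (hyper in insult vs control) ∩ (hypo in
treated vs insult), and **enhancement** = the mirror. The overlap is
reported as a percentage of the **union** of the two sets — the only
denominator consistent with both published pairs this analysis is
checked against (613 / 5726 → 10.7%; 1063 / 8607 → 12.4%, to one
decimal). When tables carry an `rna_class` annotation the counts are
restricted to mRNAs, since the question is posed over mRNAs. The two
member lists are provably disjoint for a given table pair (a transcript
cannot be both hyper and hypo in the same comparison), and the
percentage is invariant under transcript relabeling; both are asserted
as properties in the tests.

## Over-representation analysis

Gene-set enrichment of a reversal list uses the upper-tail
hypergeometric test: with a universe of `N` measured mRNA symbols, a
query of `n`, a set with `K` members in the universe and `k` in the
query, `p = P(X ≥ k)`; `k = 0` gives p = 1. The universe is the
flag-passing measured mRNAs, not the genome — testing against genes the
array could never have reported inflates enrichment. Benjamini–Hochberg
q-values are computed across all sets of a collection in one pass; rows
are ordered by p, ties broken by descending overlap then set name, so
output is deterministic. Sets with no member in the universe are skipped
with a message. The implementation is checked two ways: against the
closed form `1 / C(20,5)` for a fully recovered set, and against
exhaustive enumeration of all `C(N,n)` query draws on universes up to
N = 12. Because the statistic is discrete, its null rejection rate at
p ≤ 0.05 equals the largest achievable level below 0.05 (conservative),
and the null-calibration checks compare against that achieved level
rather than the nominal one.

## The synthetic-data generator

`generate_dataset()` simulates the whole chain on the log2 scale — gene
baseline + group effect + array offset + iid noise — then exponentiates,
guaranteeing positive intensities. Defaults encode the study design the
package targets: three groups (`Ctrl`, `FS`, `FS-DBS`) × 3 arrays, 2000
genes, 8 spike-ins, baseline log2 intensity 10 ± 1.5, replicate noise
0.2 log2 units, array drift 0.3 log2 units, planted effects of 2 log2
units (4-fold, comfortably above the 0.585 cut), insult planting of 10%
hyper / 2.5% hypo (the ~80:20 direction split such studies report), half
of the insult effects reversed by treatment, 2% dropout. Per-gene
baseline methylated fractions are uniform on (0.2, 0.8). Planted genes
either shift expression together with quantity at fixed level
(`expr_coupling`) or shift the methylated fraction at fixed expression;
for the latter the baseline fraction is drawn so the shifted fraction
stays inside (0, 1), which bounds usable effect sizes at 5 log2 units.
One array-level offset is shared by both dye channels of a sample — they
are scanned from the same physical array — which is what makes the
methylation level exactly recoverable after per-channel normalization.
The Sup amount is total minus methylated, so conservation holds in the
ground truth, not just in the estimates.

What the generator does **not** emulate: probe sequence effects and
cross-hybridization, intensity-dependent (heteroskedastic) noise, dye
bias between Cy5 and Cy3 beyond the shared array offset,
transcript-specific antibody efficiency, biological pooling variance
(each real sample pools ten animals; arrays, not animals, are the unit
here), and lncRNA probes (all simulated genes are mRNA). Passing
recovery tests therefore show the arithmetic chain is correct under the
stated noise model — they do not certify performance on real arrays,
where those unmodeled effects set the error floor.

Ground-truth recovery is checked at two settings. Noise-free
(`noise_log2_sd = 0`, `dropout_rate = 0`): classification and both
reversal member lists must equal the planted truth exactly, for any
effect above the threshold. Noisy (noise 0.2, triplicates, 4-fold
effects, 2000 genes): the recovered hypermethylated count must fall in
the 99% binomial interval around the planted count. Both recovery checks
set `dropout_rate = 0` — dropout feeds background values into means by
design (see probe selection), which is a property of the flag rule, not
of the classifier under test.

## Determinism and problem sizes

A single integer seed drives the generator; identical config and seed
give bit-identical tables, and the pipeline itself draws no random
numbers. The shipped analyses and checks use 150–2000 genes with
triplicate arrays, 10 000 draws for the null calibration of the
hypergeometric test, and n = 1000 genes for the concordance checks —
sizes at which the binomial and rank-correlation tolerances above are
meaningful while the whole suite runs in seconds.

## Concordance of the three quantities

Fold changes of m6A quantity are expected to track expression fold
changes when methylation and transcription move together; the
methylation level, a within-transcript fraction, need not. Spearman rank
correlation (fold changes are heavy-tailed) over the shared transcripts
quantifies this: with fully coupled planted shifts the quantity-expression
correlation exceeds 0.8; with uncoupled shifts the level-expression
correlation sits near zero. Two caveats are inherent to the ratio
construction and worth knowing: quantity and expression share the IP
signal, so even null genes correlate positively; and the level inherits
a small negative correlation with expression through the shared
denominator. The null band of ±0.1 at n = 1000 accommodates both.

## Known limitations

The platform vendor's exact formulas for the three quantities are not
public; the definitions here are the reconstruction that makes the
conservation identities hold. Fold-change-only selection has no error
control — the changed-transcript counts are threshold exceedances, not
discoveries at a stated FDR. The reversal percentage depends on the
fold-change threshold through both set sizes, so it is comparable only
between runs with the same threshold. And the ORA implementation ignores
gene-set topology (no GO DAG propagation): collections are treated as
flat symbol sets.
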