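---
title: "Screening divergent promoter-associated noncoding RNAs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening divergent promoter-associated noncoding RNAs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many mammalian promoters are bidirectional: besides the mRNA, they produce a
divergent, antisense, poly(A)+ long noncoding RNA — a promoter-associated
noncoding RNA (pancRNA). During mouse zygotic gene activation (ZGA, mainly at
the 2-cell stage), pancRNA transcription is associated with the coordinated
upregulation and promoter demethylation of the partner mRNA. `pancscreen`
implements the computational side of such a study end to end: strand-aware
quantification of antisense transcription in promoter windows from
directional RNA-seq, a screen for pancRNA/mRNA pairs and their coordination
across stages (MII oocyte, 2-cell embryo, ESC), strand-asymmetric profiling
of a CT-rich promoter motif, CpG-island association, and bisulfite-subclone
methylation statistics — together with a synthetic-data generator that plants
every signal the analysis is supposed to find, so the whole pipeline is
testable without any sequencing data.

## Windows and quantification

All internal coordinates are 0-based half-open; GTF input is read as 1-based
inclusive and BED output written 0-based half-open. Per gene (5'-most TSS per
strand when several transcripts exist):

* **Promoter window**: −1000..−1 relative to the TSS. The pancRNA is
  quantified as reads whose 5′ end falls in this window **on the strand
  opposite to the gene**. A promoter is excluded when it overlaps the span
  of any other gene (either strand) — otherwise read-through from a
  neighbouring gene would masquerade as a pancRNA — or when it does not fit
  inside the chromosome. Excluded windows are dropped rather than truncated
  so that all windows stay length-comparable; windows are likewise never
  clipped when a neighbour is close but not overlapping.
* **Motif windows**: promoter −500..−1 and gene body +1..+500, oriented by
  the gene.
* **Motif-discovery input**: −200..−1, written in mRNA orientation.

Read assignment uses the 5′ end only, not any-overlap: for short single-end
reads this is unambiguous at window boundaries and cannot double-count a
read between promoter and gene body. RPKM is
`count / ((length/1000) · (total/10^6))` with the exonic length for mRNAs
and the window length (1 kb) for pancRNAs; the per-sample total is the
number of mapped reads in the sample. Reads are not deduplicated.

Two QC statistics mirror what one would report for a directional library:
the strandedness (fraction of reads in exactly one gene span that match the
annotated strand) and pairwise Pearson correlation of replicates on
log2(RPKM+1). The +1 pseudocount bounds the influence of high expressors.

## The screen

* **Candidates**: genes whose mean pancRNA RPKM across replicates is ≥ 1 at
  a stage (`min_rpkm`, exposed as a parameter). The value mirrors the
  "RPKM > 1" convention used for the follow-up criteria; the threshold
  behind the original candidate counts is not recoverable, so it is a
  documented default, not a calibrated constant.
* **Co-expression**: pancRNA and mRNA both above 0.5 RPKM
  (`expressed_thresh`); 0.5 complements the "RPKM < 0.5" silence criterion
  below.
* **Groups A/B/C**: expressed mRNAs without an expressed pancRNA (A), and
  mRNAs partnered with the 100 most weakly (B) / strongly (C) expressed
  pancRNAs among co-expressed pairs. Ties at the group boundary are broken
  by `gene_id` so membership is deterministic. C is compared to A and B
  with one-sided Mann–Whitney tests.
* **Coordination**: per-pair `log2((RPKM_to + 0.5) / (RPKM_from + 0.5))`
  for pancRNA and mRNA, with Pearson correlation and the count of pairs up
  on both sides. The 0.5 RPKM pseudocount keeps fold changes of
  stage-silent features finite. Because many pancRNAs are entirely absent
  in MII, the correlation over *all* co-expressed pairs is diluted by
  pseudocount-dominated fold changes; the pipeline therefore also reports
  the correlation over pairs detected at both stages, where fold changes
  are level-driven. Both are written to `coordination_summary.tsv`, along
  with a ≥2-fold-upregulated subset, since it is ambiguous which set the
  headline correlation of such a study uses.
* **Follow-up candidates**: pancRNA RPKM < 0.5 in MII, > 1 in 2-cell and
  ESC, ranked by ESC expression (ties by `gene_id`).
* **Differential test**: the original tooling's differential machinery is
  out of scope; the replacement is a Welch t-test on log2(RPKM+1) with
  Benjamini–Hochberg adjustment. When both sides have zero variance, p is
  1 for equal means and 0 otherwise. This is deliberately simple, exactly
  testable, and holds its nominal size on null negative-binomial data
  (checked at 4-vs-4 replicates over 2000 features).

## Motif scanning and CpG islands

`scan_pwm()` scores every window with log2 PWM probabilities and converts
the score to a **min-max identity**: `(s − s_min)/(s_max − s_min)` over the
extreme achievable window scores — the semantics behind a "90% identity to
the PWM" threshold. A uniform background is assumed (none was specified);
identity is invariant to constant shifts of the log scores, so this choice
only matters through the per-column probability ratios. Hits are collected
on both strands (minus strand via the reverse complement) and overlapping
hits are all kept, since the downstream statistic is per-region presence,
which no masking policy can change. Windows containing N are skipped.

The region/strand profile classifies hits of the CT-rich motif into
promoter-sense, promoter-antisense, body-sense and body-antisense (sense =
mRNA direction) and reports per-gene presence fractions; raw hit counts are
written alongside because aggregating genes or hits is an open choice.

CpG islands follow the classical sliding-window definition: 200-bp windows
(1-bp step) with G+C ≥ 0.5 and observed/expected CpG ≥ 0.6
(`obs/exp = n_CpG · L / (n_C · n_G)`), merged when overlapping, with island
statistics recomputed on the merged interval. A promoter is CpGi-type iff an
island overlaps its −1000..−1 window by ≥ 1 bp.

## What the generator emulates

`sim_config()` holds every knob; the seed fully determines all outputs
(each generator stage derives its own sub-seed, so stages are individually
reproducible). Defaults: 2 chromosomes × 500 kb, 400 genes, stages
MII/2-cell/ESC × 4 replicates, 200k reads per sample, NB dispersion 0.1,
strand-flip rate 0.02 — a full pipeline run takes well under a minute.

* **Background genome**: first-order Markov chain with uniform base
  composition (GC 0.5) and C→G transitions depleted to 8% of the uniform
  rate, giving genome-wide obs/exp CpG ≈ 0.2 as in vertebrate genomes. The
  depletion is essential: on an i.i.d. uniform sequence obs/exp CpG ≈ 1,
  the classical definition calls the entire genome an island, and the
  CpGi/non-CpGi contrast collapses. The transition matrix is doubly
  stochastic and reverse-complement symmetric, so composition stays uniform
  and the background is strand-symmetric.
* **Annotation**: non-overlapping genes with ≥ 1 kb upstream clearance; a
  configured fraction gets a small "decoy" gene written inside its promoter
  window to exercise the exclusion rule. Decoys sit on the target gene's
  strand, so at zero noise no simulated read can be counted toward a
  foreign feature and the closed-loop truth comparison stays exact. The
  truth table records exclusions computed by independent interval
  arithmetic.
* **Expression**: bimodal per stage — a feature is silent (exactly 0 RPKM)
  or "on" with a lognormal level, emulating the on/off character of ZGA.
  mRNA levels of partnered genes are tied to the partner pancRNA level on
  the log scale (slope 0.5), planting the group C > A effect; for pairs on
  at both MII and 2-cell, (pancRNA, mRNA) log2 fold changes are bivariate
  normal with correlation 0.7 (the planted coordination). True RPKMs are
  rescaled per stage so that `sum(rpkm · length_kb) = 10^6`: true
  expression is then self-consistent with the library size and measured
  RPKM converges to the recorded truth. Like all relative measures, this
  induces a compositional shift between stages (a constant added to every
  log2 fold change), which leaves correlations untouched but lowers the
  up/up pair count at default settings.
* **Reads**: per feature and replicate, counts are NB with
  `var = μ + α·μ²` (α = `dispersion`; α = 0 gives deterministic
  `round(μ)`, the regime for exact closed-loop tests). 5′ positions are
  uniform within the feature (no 5′/3′ bias model), on the feature's
  strand, flipped with the strand-flip rate.
* **Motif and CpG islands**: the CT-rich consensus (CTCTCTCC) is written
  into motif windows at per-category rates (defaults follow the observed
  asymmetry: promoter-sense and body-antisense for partnered genes,
  antisense-only for lacking genes), reverse-complemented for minus-strand
  placements, with collision-free positions and every occurrence recorded;
  the generating PWM is emitted in JASPAR format. CpG-rich segments
  (≈ 0.79 GC, obs/exp ≈ 1.8) are planted in promoters at class-specific
  rates (0.7 partnered / 0.3 lacking).
* **Bisulfite clones**: per clone and CpG, M with the stage's true level
  (defaults high in MII/sperm/1-cell, 0.1 at 2-cell), with a 2% missing
  rate.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: alignment artefacts and mapping ambiguity,
sequencing errors and PCR duplicates, 5′/3′ coverage bias, isoform
structure, spatially varying GC content, and any dependence between
neighbouring CpG calls within a bisulfite clone. One emergent artefact is
realistic and worth knowing: with ~1 kb gaps, divergent neighbours' promoter
windows can overlap, and strand-flipped pancRNA reads then leak into the
neighbour's pancRNA count — at the default 2% flip rate this inflates the
candidate list slightly, just as imperfect strandedness would in a real
library.

## Statistics

`mann_whitney_u()` computes U from midranks. For n+m ≤ 12 it enumerates all
`choose(n+m, n)` labelings of the pooled data — ties included — so the
p-value is exact even with tied per-clone fractions (at most 924 labelings,
instant). Larger samples use the normal approximation with tie-corrected
variance and a 0.5 continuity correction; two-sided p is `min(1, 2·min`
tail`)`, which returns exactly 1 for perfectly balanced data. The
observation unit for methylation comparisons is the per-clone methylated
fraction, clones being the independent sequencing units; missing calls are
excluded, never imputed. The exact and approximate modes agree to within
0.02 at the size boundary for continuous data; with heavy ties the
approximation is known to be cruder, which is why the exact mode covers the
typical clone-count regime.

## Numerical choices and degenerate inputs

* Identity comparisons in `scan_pwm()` use a 1e-9 tolerance so windows
  exactly at the threshold are kept regardless of summation order.
* Zero-variance replicate vectors yield NA correlations (flagged), not
  errors; zero-variance differential tests follow the degenerate rule
  above.
* Tie-breaking is by `gene_id` lexical order after every numeric sort key,
  making every ranked output deterministic.
* Gene bodies shorter than 500 bp give truncated, flagged body windows;
  sequences shorter than 200 bp yield no CpG islands; empty gene sets are
  an error for profiling.
* `run_pipeline()` writes a JSON manifest with the package version, the
  full configuration echo, every analysis threshold and md5 checksums of
  all outputs; apart from the manifest's timestamp, two runs with the same
  seed are byte-identical.

## Problem sizes used in the tests

Unit tests run the generator at 60 genes / 2 × 120 kb / 30k reads per
sample; the closed-loop and calibration checks run the default scale (400
genes, 200k reads); the coordination-recovery check sizes the simulation to
≥ 500 truth pairs (2300 genes across 11 chromosomes); the null-size check
uses 2000 simulated features. These sizes are the package's own choices to
keep the full suite fast while leaving every statistical check adequately
powered.

## Known limitations

* RPKM is the only expression unit (as in the study this mirrors); no TPM.
* The candidate threshold stands in for an unpublished cutoff; absolute
  candidate counts are not comparable to any published count.
* The PWM scanner has no Markov background model and no motif discovery —
  the PWM is an input (the generator emits its planted one).
* BAM input is not parsed directly; alignments are expected as a 5′-end
  read table (chrom, pos, strand, sample), which a one-line awk/samtools
  command produces from a BAM, with the strand convention of the protocol
  applied there.
* Methylation analysis covers subclone call strings, not read-level
  bisulfite alignment or conversion-efficiency estimation.
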