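# pancscreen

Strand-aware discovery and characterization of **pancRNAs** — promoter-
associated noncoding RNAs transcribed divergently (antisense) from the
promoters of their partner mRNAs. The package implements the computational
core of a directional RNA-seq study of mouse zygotic gene activation (ZGA):
at the 2-cell stage, many promoters start producing an antisense lncRNA
together with — and predictive of — the upregulation and demethylation of
the partner gene. It is written for genomicists who want a tested, fully
reproducible reference implementation of this analysis style, exercised end
to end on synthetic data with a known ground truth.

## What it computes

* **pancRNA quantification.** For each gene (5′-most TSS), the promoter
  window −1000..−1; a read counts toward the pancRNA iff its 5′ end lies in
  the window on the strand opposite the gene. Promoters overlapping another
  gene's span are excluded to keep mRNA read-through out of the pancRNA
  pool. Expression is RPKM: `count / ((L/10³)·(N/10⁶))` with L the exonic
  length (mRNA) or window length (pancRNA) and N the sample's mapped reads.
  QC: strandedness of the library and replicate correlation on
  log₂(RPKM+1).
* **The screen.** Candidate pancRNAs per stage (mean RPKM ≥ 1),
  pancRNA/mRNA co-expression (both > 0.5 RPKM), expression groups
  (A: mRNAs without pancRNA; B/C: partners of the 100 weakest/strongest
  pancRNAs, compared by one-sided Mann–Whitney tests), fold-change
  coordination `log₂((RPKM_2cell+0.5)/(RPKM_MII+0.5))` with Pearson r,
  follow-up candidates (RPKM < 0.5 in MII, > 1 in 2-cell and ESC), and a
  Welch + Benjamini–Hochberg differential test over replicates.
* **Motif asymmetry.** PWM scanning at ≥ 90% min-max identity
  `(s−s_min)/(s_max−s_min)` on both strands; per-gene presence of the
  CT-rich motif in promoter (−500..−1) and gene-body (+1..+500) windows,
  split by sense/antisense relative to the mRNA; association with
  CpG-island-type promoters (classical definition: ≥ 200 bp, GC ≥ 0.5,
  obs/exp CpG ≥ 0.6); FASTA export of −200..−1 sequences of ≥ 10-fold
  upregulated pancRNAs for motif discovery.
* **Methylation.** Bisulfite subclone call strings → per-CpG/per-clone/
  overall methylation levels, text lollipop rendering, and Mann–Whitney U
  tests between stages (exact by full enumeration for n+m ≤ 12, ties
  included; tie-corrected normal approximation beyond).
* **Synthetic data.** A deterministic generator (genome with CpG-depleted
  Markov background, gene annotation with planted exclusion cases, NB
  stranded reads with planted on/off expression and correlated fold
  changes, planted CT-rich motif and CpG islands, bisulfite clones) plus
  truth tables, so every stage closes the loop in tests.

## Worked example

The analysis is organised as numbered drivers over the package functions;
each writes its tables under `results/run/` and prints what it found:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify.R
Rscript analysis/03_screen.R
Rscript analysis/04_motif.R
Rscript analysis/05_methylation.R
```

Output of a run at seed 1 (abridged):

```
genes: 400 targets + 21 decoys inside promoters (exclusion-rule cases)
pancRNA-partnered: 254 genes; promoters excluded by the overlap rule: 53
promoters: 368 usable, 53 excluded ( overlaps_gene 53 )
strandedness: 97.8% of gene-span reads on the correct strand
replicate correlation at 2cell: min r = 0.974
2cell: 266 candidate pancRNAs (mean RPKM >= 1)
co-expression: 244 of 266 2-cell pancRNAs have an expressed mRNA
group medians (mRNA RPKM): A=411.6 B=305.7 C=1372.6; C>A p=1.14e-08
coordination: r=0.31 over 129 pairs detected at both stages
follow-up: 57 pancRNAs silent in MII, active in 2-cell and ESC
partnered (n=266): prom-sense 53%, prom-antisense 8%, body-sense 4%, body-antisense 43%
lacking   (n=102): prom-sense 4%, prom-antisense 29%, body-sense 7%, body-antisense 38%
CpGi association: motif in 54.1% of CpGi-type vs 46.8% of non-CpGi promoters
locus01: 1cell 76%, 2cell 8%, MII 88%, sperm 80%
MII vs 2-cell demethylation: max p = 6.21e-08 over 3 loci
```

Reading the numbers: the library passes QC (97.8% strandedness with the
configured 2% strand-flip rate; replicate r > 0.97). The screen recovers
the planted architecture — most 2-cell pancRNAs are co-expressed with
their mRNA, genes with the strongest pancRNAs have clearly higher mRNA
levels (group C vs A), pancRNA and mRNA fold changes correlate positively,
and the motif shows the planted switch at the TSS: promoter-**sense** in
pancRNA-partnered genes versus promoter-**antisense** in pancRNA-lacking
genes, with enrichment in CpG-island promoters. Methylation collapses from
~85% to ~10% at the 2-cell stage at every locus.

The same end-to-end run is available as one call:

```r
library(pancscreen)
res <- run_pipeline(sim_config(seed = 1), "results/run")
```

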