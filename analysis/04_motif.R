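#!/usr/bin/env Rscript
# Stage 4: CT-rich motif asymmetry and CpG-island association.
#
# Scans promoter (-500..-1) and gene-body (+1..+500) windows with the
# supplied PWM at 90% min-max identity, splits hits by strand relative to
# the mRNA, and contrasts pancRNA-partnered genes (2-cell candidates) with
# pancRNA-lacking genes. Also tests whether the motif is enriched in
# CpG-island-type promoters and emits the -200..-1 sequences of strongly
# upregulated pancRNAs for de novo motif discovery.

suppressMessages(library(pancscreen))

simdir <- "results/run/sim"
qdir <- "results/run/quantify"
sdir <- "results/run/screen"
outdir <- "results/run/motif"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome(file.path(simdir, "genome.fa"))
genes <- parse_gene_models(file.path(simdir, "genes.gtf"))
sizes <- readr::read_tsv(file.path(simdir, "chrom_sizes.tsv"),
                         col_types = "ci")
promoters <- define_promoters(genes,
                              stats::setNames(sizes$length, sizes$chrom))
pwm <- read_jaspar(file.path(simdir, "pwm_ct_rich.jaspar"))
cat("PWM:", ncol(pwm), "bp, consensus", pwm_consensus(pwm), "\n")

cand2 <- readr::read_tsv(file.path(sdir, "candidates_2cell.tsv"),
                         col_types = "cd")$gene_id
partnered <- genes[genes$gene_id %in% cand2, ]
lacking <- genes[genes$gene_id %in%
                   setdiff(promoters$gene_id[!promoters$excluded], cand2), ]
prof_p <- region_strand_profile(partnered, genome, pwm)
prof_l <- region_strand_profile(lacking, genome, pwm)
prof <- dplyr::bind_rows(
  dplyr::mutate(prof_p$fractions, gene_set = "panc_partnered"),
  dplyr::mutate(prof_l$fractions, gene_set = "panc_lacking"))
readr::write_tsv(prof, file.path(outdir, "motif_region_profile.tsv"))
show <- function(fr, what) {
  cat(sprintf(
    "%s: prom-sense %.0f%%, prom-antisense %.0f%%, body-sense %.0f%%, body-antisense %.0f%%\n",
    what, 100 * fr$fraction[1], 100 * fr$fraction[2],
    100 * fr$fraction[3], 100 * fr$fraction[4]))
}
show(prof_p$fractions, sprintf("partnered (n=%d)", nrow(partnered)))
show(prof_l$fractions, sprintf("lacking   (n=%d)", nrow(lacking)))

islands <- detect_cpg_islands_genome(genome)
write_bed6(islands, file.path(outdir, "cpg_islands.bed"))
assoc <- motif_cpgi_association(genes, promoters, genome, pwm, islands)
readr::write_tsv(assoc$fractions,
                 file.path(outdir, "motif_cpgi_association.tsv"))
fr <- assoc$fractions
cat(sprintf(
  "CpGi association: motif in %.1f%% of CpGi-type vs %.1f%% of non-CpGi promoters\n",
  100 * fr$frac_with_motif[1], 100 * fr$frac_with_motif[2]))

features <- readr::read_tsv(file.path(qdir, "features.tsv"),
                            col_types = "ccci")
samples <- readr::read_tsv(file.path(qdir, "samples.tsv"),
                           col_types = "ccii")
read_mat <- function(f) {
  d <- readr::read_tsv(file.path(qdir, f), col_types = readr::cols())
  m <- as.matrix(d[, -1]); rownames(m) <- d$feature_id; m
}
expr <- expr_table(features, samples, read_mat("counts.tsv"),
                   read_mat("rpkm.tsv"))
search <- select_motif_search_set(expr, genes, genome, min_fold = 10,
                                  fasta = file.path(outdir,
                                                    "motif_search_set.fa"))
cat(nrow(search), "genes with >= 10-fold pancRNA upregulation;",
    "-200..-1 sequences written for motif discovery\n")
cat("outputs under", outdir, "\n")
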