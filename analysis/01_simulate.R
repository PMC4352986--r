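#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data set.
#
# Emulates a directional RNA-seq study of zygotic gene activation: MII
# oocytes, 2-cell embryos and ESCs, four replicates each, with divergent
# pancRNA/mRNA transcription from shared promoters, a planted CT-rich motif,
# CpG-island-type promoters and bisulfite clones. Everything downstream
# (02-05) consumes only the plain-text files written here.

suppressMessages(library(pancscreen))

cfg <- sim_config(seed = 1)
sim <- simulate_all(cfg, outdir = "results/run/sim")

genes <- sim$genes
cat("genome:", length(sim$genome), "chromosomes x",
    format(cfg$chrom_length, big.mark = ","), "bp\n")
cat("genes:", sum(!genes$is_decoy), "targets +", sum(genes$is_decoy),
    "decoys inside promoters (exclusion-rule cases)\n")
cat("pancRNA-partnered:", sum(genes$partnered), "genes;",
    "promoters excluded by the overlap rule:",
    sum(genes$promoter_excluded), "\n")
cat("reads:", format(nrow(sim$reads), big.mark = ","), "across",
    nrow(sim$sample_sheet), "samples (strand-flip rate",
    cfg$strand_flip, ")\n")
cat("bisulfite: ", cfg$n_meth_loci, " loci x ",
    length(cfg$meth_stages), " stages x ", cfg$n_clones, " clones\n", sep = "")
cat("outputs under results/run/sim/\n")
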