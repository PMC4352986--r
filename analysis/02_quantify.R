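#!/usr/bin/env Rscript
# Stage 2: annotation windows, strand-aware quantification and library QC.
#
# Reads the simulated files, derives promoter windows with the exclusion
# rule, counts pancRNA (promoter-antisense) and mRNA (span-sense) reads by
# their 5' ends, computes RPKM, and reports the two library QC statistics:
# strandedness and replicate correlation.

suppressMessages(library(pancscreen))

simdir <- "results/run/sim"
outdir <- "results/run/quantify"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genes <- parse_gene_models(file.path(simdir, "genes.gtf"))
sizes <- readr::read_tsv(file.path(simdir, "chrom_sizes.tsv"),
                         col_types = "ci")
chrom_sizes <- stats::setNames(sizes$length, sizes$chrom)
promoters <- define_promoters(genes, chrom_sizes)
write_bed6(dplyr::transmute(promoters, chrom, start, end, name = gene_id,
                            score = 0L, strand = panc_strand),
           file.path(outdir, "promoters.bed"))
readr::write_tsv(promoters[promoters$excluded, ],
                 file.path(outdir, "promoter_exclusions.tsv"))
cat("promoters:", sum(!promoters$excluded), "usable,",
    sum(promoters$excluded), "excluded (",
    paste(names(table(promoters$reason)), table(promoters$reason),
          collapse = ", "), ")\n")

reads <- read_reads(file.path(simdir, "reads.tsv"))
sheet <- readr::read_tsv(file.path(simdir, "sample_sheet.tsv"),
                         col_types = "cci")
expr <- quantify_pairs(reads, promoters, genes, sheet,
                       known_chroms = names(chrom_sizes))
readr::write_tsv(tibble::as_tibble(expr$counts, rownames = "feature_id"),
                 file.path(outdir, "counts.tsv"))
readr::write_tsv(tibble::as_tibble(expr$rpkm, rownames = "feature_id"),
                 file.path(outdir, "rpkm.tsv"))
readr::write_tsv(expr$samples, file.path(outdir, "samples.tsv"))
readr::write_tsv(expr$features, file.path(outdir, "features.tsv"))

qc <- strandedness_qc(reads, genes, by_sample = TRUE)
readr::write_tsv(qc, file.path(outdir, "qc_strandedness.tsv"))
cat(sprintf("strandedness: %.1f%% of gene-span reads on the correct strand\n",
            100 * mean(qc$fraction)))

for (s in unique(sheet$stage)) {
  r <- replicate_correlation(expr, s)
  cat(sprintf("replicate correlation at %s: min r = %.3f\n",
              s, min(r[upper.tri(r)])))
}
cat("outputs under", outdir, "\n")
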