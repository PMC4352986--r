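#!/usr/bin/env Rscript
# Stage 5: bisulfite subclone methylation analysis.
#
# Per-locus, per-stage methylation levels from subclone call strings, a text
# lollipop rendering, and two-sided Mann-Whitney U tests (exact for small
# clone counts) between all stage pairs.

suppressMessages(library(pancscreen))

simdir <- "results/run/sim"
outdir <- "results/run/methylation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

clones <- parse_bisulfite_clones(file.path(simdir, "bisulfite_clones.tsv"))
levels <- methylation_summary(clones)
readr::write_tsv(levels, file.path(outdir, "methylation_levels.tsv"))
for (locus in unique(levels$locus_id)) {
  lv <- levels[levels$locus_id == locus, ]
  cat(locus, ": ",
      paste(sprintf("%s %.0f%%", lv$stage, 100 * lv$overall),
            collapse = ", "), "\n", sep = "")
}

tests <- methylation_stage_tests(clones)
readr::write_tsv(tests, file.path(outdir, "methylation_tests.tsv"))
drop <- tests[tests$stage_a == "MII" & tests$stage_b == "2cell", ]
cat(sprintf("MII vs 2-cell demethylation: max p = %.2e over %d loci\n",
            max(drop$p), nrow(drop)))

lines <- unlist(lapply(split(clones, clones$locus_id), function(d) {
  c(paste0("# ", d$locus_id[1]),
    unlist(lapply(split(d, d$stage), function(s) {
      c(paste0("## ", s$stage[1]), render_lollipop(s$calls))
    })))
}))
writeLines(lines, file.path(outdir, "methylation_lollipop.txt"))
cat("outputs under", outdir, "\n")
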