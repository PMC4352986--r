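#!/usr/bin/env Rscript
# Stage 3: the pancRNA screen.
#
# Candidate pancRNAs per stage, pancRNA/mRNA co-expression at the 2-cell
# stage, expression-level groups (A: no pancRNA, B/C: weakest/strongest 100
# partner pancRNAs), fold-change coordination between MII and 2-cell,
# follow-up candidates silent in MII but active later, and a replicate-based
# Welch + BH differential test.

suppressMessages(library(pancscreen))

simdir <- "results/run/sim"
qdir <- "results/run/quantify"
outdir <- "results/run/screen"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

features <- readr::read_tsv(file.path(qdir, "features.tsv"),
                            col_types = "ccci")
samples <- readr::read_tsv(file.path(qdir, "samples.tsv"),
                           col_types = "ccii")
read_mat <- function(f) {
  d <- readr::read_tsv(file.path(qdir, f), col_types = readr::cols())
  m <- as.matrix(d[, -1])
  rownames(m) <- d$feature_id
  m
}
expr <- expr_table(features, samples, read_mat("counts.tsv"),
                   read_mat("rpkm.tsv"))

for (s in unique(samples$stage)) {
  cand <- call_panc_candidates(expr, s, min_rpkm = 1)
  readr::write_tsv(cand$candidates,
                   file.path(outdir, sprintf("candidates_%s.tsv", s)))
  cat(sprintf("%s: %d candidate pancRNAs (mean RPKM >= 1)\n",
              s, nrow(cand$candidates)))
}

pairs <- classify_coexpression(expr, "2cell", expressed_thresh = 0.5)
readr::write_tsv(pairs, file.path(outdir, "pair_status.tsv"))
cand2 <- call_panc_candidates(expr, "2cell")$candidates$gene_id
cat(sprintf("co-expression: %d of %d 2-cell pancRNAs have an expressed mRNA\n",
            sum(pairs$mrna_expressed[match(cand2, pairs$gene_id)]),
            length(cand2)))

groups <- group_by_panc_level(pairs, expr, "2cell", n = 100)
readr::write_tsv(groups$groups, file.path(outdir, "expression_groups.tsv"))
readr::write_tsv(groups$tests, file.path(outdir, "expression_group_tests.tsv"))
med <- tapply(groups$groups$mrna_rpkm, groups$groups$group, median)
cat(sprintf("group medians (mRNA RPKM): A=%.1f B=%.1f C=%.1f; C>A p=%.2e\n",
            med["A"], med["B"], med["C"],
            groups$tests$p[groups$tests$comparison == "C_vs_A"]))

coord <- coordination_stats(pairs[pairs$coexpressed, ], expr, "MII", "2cell",
                            min_fold = 2)
pairs_mii <- classify_coexpression(expr, "MII")
both <- intersect(pairs$gene_id[pairs$coexpressed],
                  pairs_mii$gene_id[pairs_mii$coexpressed])
coord_both <- coordination_stats(both, expr, "MII", "2cell")
readr::write_tsv(coord$per_pair, file.path(outdir, "coordination_pairs.tsv"))
cat(sprintf("coordination: r=%.2f over %d pairs detected at both stages\n",
            coord_both$r, coord_both$n_pairs))

followup <- select_followup_candidates(expr)
readr::write_tsv(followup, file.path(outdir, "followup_candidates.tsv"))
cat(sprintf("follow-up: %d pancRNAs silent in MII, active in 2-cell and ESC;",
            nrow(followup)),
    "top 3:", paste(utils::head(followup$gene_id, 3), collapse = ", "), "\n")

diff <- differential_table(expr, "2cell", "MII")
readr::write_tsv(diff, file.path(outdir, "differential_2cell_vs_MII.tsv"))
cat(sprintf("differential (Welch + BH): %d of %d features at q < 0.05\n",
            sum(diff$q < 0.05), nrow(diff)))
cat("outputs under", outdir, "\n")
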