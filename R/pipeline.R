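#' Run the full pancRNA analysis pipeline on a synthetic data set
#'
#' Orchestrates every stage end to end: simulation (written to
#' `outdir/sim/`), annotation (gene models parsed back from the emitted GTF,
#' promoter definition with exclusions, CpG-island detection), strand-aware
#' quantification with QC (strandedness, replicate correlation), the pancRNA
#' screen (candidates per stage, co-expression, expression-level groups,
#' coordination, follow-up selection, replicate-based differential test),
#' motif profiling (region/strand asymmetry, CpGi association, motif-search
#' set) and bisulfite methylation analysis. All tables are written under
#' `outdir/results/` along with a JSON run manifest (package version, config
#' echo, parameters, file checksums). Outputs are a deterministic function of
#' the configuration; only the manifest carries a timestamp.
#'
#' @param config [sim_config()].
#' @param outdir run directory (created if missing).
#' @param min_rpkm candidate cutoff, RPKM (see [call_panc_candidates()]).
#' @param expressed_thresh co-expression cutoff, RPKM.
#' @param pseudo fold-change pseudocount, RPKM.
#' @param coord_min_fold secondary mRNA fold filter for the coordination
#'   summary.
#' @param motif_min_fold pancRNA fold cutoff for the motif-search set.
#' @param min_identity PWM identity threshold.
#' @param group_n size of expression-level groups B and C.
#' @return (invisibly) list of all stage results plus the manifest.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         min_rpkm = 1.0, expressed_thresh = 0.5,
                         pseudo = 0.5, coord_min_fold = 2.0,
                         motif_min_fold = 10, min_identity = 0.9,
                         group_n = 100L) {
  simdir <- file.path(outdir, "sim")
  resdir <- file.path(outdir, "results")
  dir.create(resdir, recursive = TRUE, showWarnings = FALSE)
  rp <- function(f) file.path(resdir, f)

  sim <- simulate_all(config, outdir = simdir)

  # ---- annotation: consume the emitted files, not the in-memory objects
  genome <- read_genome(file.path(simdir, "genome.fa"))
  sizes_df <- readr::read_tsv(file.path(simdir, "chrom_sizes.tsv"),
                              col_types = "ci")
  chrom_sizes <- stats::setNames(sizes_df$length, sizes_df$chrom)
  genes <- parse_gene_models(file.path(simdir, "genes.gtf"))
  promoters <- define_promoters(genes, chrom_sizes,
                                upstream_len = config$promoter_len)
  islands <- detect_cpg_islands_genome(genome)

  write_bed6(dplyr::transmute(promoters, .data$chrom, .data$start, .data$end,
                              name = .data$gene_id, score = 0L,
                              strand = .data$panc_strand),
             rp("promoters.bed"))
  readr::write_tsv(promoters[promoters$excluded,
                             c("gene_id", "chrom", "start", "end", "reason")],
                   rp("promoter_exclusions.tsv"))
  write_bed6(islands, rp("cpg_islands.bed"))

  # ---- quantification + QC
  reads <- read_reads(file.path(simdir, "reads.tsv"))
  sample_sheet <- readr::read_tsv(file.path(simdir, "sample_sheet.tsv"),
                                  col_types = "cci")
  expr <- quantify_pairs(reads, promoters, genes, sample_sheet,
                         known_chroms = names(chrom_sizes))
  qc_strand <- strandedness_qc(reads, genes, by_sample = TRUE)
  qc_cor <- lapply(stats::setNames(nm = config$stages), function(s) {
    replicate_correlation(expr, s)
  })
  counts_df <- tibble::as_tibble(expr$counts, rownames = "feature_id")
  rpkm_df <- tibble::as_tibble(expr$rpkm, rownames = "feature_id")
  readr::write_tsv(counts_df, rp("counts.tsv"))
  readr::write_tsv(rpkm_df, rp("rpkm.tsv"))
  readr::write_tsv(qc_strand, rp("qc_strandedness.tsv"))
  cor_long <- dplyr::bind_rows(lapply(names(qc_cor), function(s) {
    m <- qc_cor[[s]]
    tibble::tibble(stage = s,
                   sample_a = rownames(m)[row(m)[upper.tri(m)]],
                   sample_b = colnames(m)[col(m)[upper.tri(m)]],
                   r = m[upper.tri(m)])
  }))
  readr::write_tsv(cor_long, rp("qc_replicate_correlation.tsv"))

  # ---- screen
  stage_to <- if (length(config$stages) >= 2) config$stages[2] else
    config$stages[1]
  stage_from <- config$stages[1]
  candidates <- lapply(stats::setNames(nm = config$stages), function(s) {
    call_panc_candidates(expr, s, min_rpkm = min_rpkm)
  })
  for (s in config$stages) {
    readr::write_tsv(candidates[[s]]$candidates,
                     rp(sprintf("candidates_%s.tsv", s)))
  }
  pairs <- classify_coexpression(expr, stage_to,
                                 expressed_thresh = expressed_thresh)
  readr::write_tsv(pairs, rp("pair_status.tsv"))
  groups <- group_by_panc_level(pairs, expr, stage_to, n = group_n,
                                expressed_thresh = expressed_thresh)
  readr::write_tsv(groups$groups, rp("expression_groups.tsv"))
  readr::write_tsv(groups$tests, rp("expression_group_tests.tsv"))
  coord <- coordination_stats(pairs[pairs$coexpressed, ], expr,
                              stage_from, stage_to, pseudo = pseudo,
                              min_fold = coord_min_fold)
  readr::write_tsv(coord$per_pair, rp("coordination_pairs.tsv"))
  # pairs detected at both stages: fold changes are level-driven, not
  # pseudocount-driven, so this set carries the coordination signal
  pairs_from <- classify_coexpression(expr, stage_from,
                                      expressed_thresh = expressed_thresh)
  both_ids <- intersect(pairs$gene_id[pairs$coexpressed],
                        pairs_from$gene_id[pairs_from$coexpressed])
  coord_both <- coordination_stats(both_ids, expr, stage_from, stage_to,
                                   pseudo = pseudo)
  coord_summary <- tibble::tibble(
    set = c("all_coexpressed", sprintf("mrna_fold_ge_%g", coord_min_fold),
            "coexpressed_both_stages"),
    n_pairs = c(coord$n_pairs, coord$filtered$n_pairs, coord_both$n_pairs),
    r = c(coord$r, coord$filtered$r, coord_both$r),
    n_up_up = c(coord$n_up_up, coord$filtered$n_up_up, coord_both$n_up_up)
  )
  readr::write_tsv(coord_summary, rp("coordination_summary.tsv"))
  followup <- select_followup_candidates(expr)
  readr::write_tsv(followup, rp("followup_candidates.tsv"))
  diff <- differential_table(expr, stage_to, stage_from)
  readr::write_tsv(diff, rp(sprintf("differential_%s_vs_%s.tsv",
                                    stage_to, stage_from)))

  # ---- motif analysis (gene sets defined by the pipeline's own calls)
  pwm <- read_jaspar(file.path(simdir, "pwm_ct_rich.jaspar"))
  cand_ids <- candidates[[stage_to]]$candidates$gene_id
  partnered_set <- genes[genes$gene_id %in% cand_ids, , drop = FALSE]
  lacking_ids <- setdiff(
    promoters$gene_id[!promoters$excluded], cand_ids)
  lacking_set <- genes[genes$gene_id %in% lacking_ids, , drop = FALSE]
  prof_partnered <- region_strand_profile(partnered_set, genome, pwm,
                                          min_identity = min_identity)
  prof_lacking <- region_strand_profile(lacking_set, genome, pwm,
                                        min_identity = min_identity)
  prof <- dplyr::bind_rows(
    dplyr::mutate(prof_partnered$fractions, gene_set = "panc_partnered"),
    dplyr::mutate(prof_lacking$fractions, gene_set = "panc_lacking")
  )
  readr::write_tsv(prof, rp("motif_region_profile.tsv"))
  assoc <- motif_cpgi_association(genes, promoters, genome, pwm, islands,
                                  min_identity = min_identity)
  readr::write_tsv(assoc$fractions, rp("motif_cpgi_association.tsv"))
  search_set <- select_motif_search_set(
    expr, genes, genome, min_fold = motif_min_fold, pseudo = pseudo,
    stage_from = stage_from, stage_to = stage_to,
    fasta = rp("motif_search_set.fa"))

  # ---- methylation
  clones <- parse_bisulfite_clones(file.path(simdir, "bisulfite_clones.tsv"))
  meth_levels <- methylation_summary(clones)
  meth_tests <- methylation_stage_tests(clones)
  readr::write_tsv(meth_levels, rp("methylation_levels.tsv"))
  readr::write_tsv(meth_tests, rp("methylation_tests.tsv"))
  lolli <- unlist(lapply(split(clones, clones$locus_id), function(d) {
    c(paste0("# ", d$locus_id[1]),
      unlist(lapply(split(d, d$stage), function(s) {
        c(paste0("## ", s$stage[1]), render_lollipop(s$calls))
      })))
  }))
  writeLines(lolli, rp("methylation_lollipop.txt"))

  # ---- manifest
  params <- list(min_rpkm = min_rpkm, expressed_thresh = expressed_thresh,
                 pseudo = pseudo, coord_min_fold = coord_min_fold,
                 motif_min_fold = motif_min_fold,
                 min_identity = min_identity, group_n = group_n)
  manifest <- run_manifest(config, params, c(
    list.files(simdir, full.names = TRUE),
    setdiff(list.files(resdir, full.names = TRUE),
            rp("run_manifest.json"))
  ))
  jsonlite::write_json(manifest, rp("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    sim = sim, genes = genes, promoters = promoters, islands = islands,
    expr = expr, qc_strandedness = qc_strand, qc_correlation = qc_cor,
    candidates = candidates, pairs = pairs, groups = groups, coord = coord,
    coord_both = coord_both,
    followup = followup, differential = diff,
    motif_profile = list(partnered = prof_partnered, lacking = prof_lacking),
    motif_cpgi = assoc, motif_search_set = search_set,
    methylation = list(levels = meth_levels, tests = meth_tests),
    manifest = manifest
  ))
}

#' Build a run manifest
#'
#' @param config [sim_config()].
#' @param params named list of analysis parameters.
#' @param files paths to checksum.
#' @return list with version, seed, config echo, parameters, md5 checksums
#'   and a timestamp.
#' @export
run_manifest <- function(config, params, files) {
  sums <- tools::md5sum(files)
  list(
    tool = "pancscreen",
    version = as.character(utils::packageVersion("pancscreen")),
    seed = config$seed,
    config = unclass(config),
    params = params,
    checksums = as.list(stats::setNames(unname(sums), basename(files))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}
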