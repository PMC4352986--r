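#' Run every generator stage and (optionally) write the data set to disk
#'
#' Chains genome background, gene placement, CpG-island planting, motif
#' planting, expression truth, stranded reads and bisulfite clones. With
#' `outdir` set, writes the complete plain-text data set: `genome.fa`,
#' `genes.gtf`, `chrom_sizes.tsv`, `reads.tsv`, `sample_sheet.tsv`,
#' `pwm_ct_rich.jaspar`, `bisulfite_clones.tsv`, the truth tables and a JSON
#' echo of the configuration. Identical config and seed give byte-identical
#' files.
#'
#' @param config [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @return (invisibly) a list with all in-memory objects: `config`, `genome`,
#'   `chrom_sizes`, `genes`, `exons`, `truth`, `cpgi_truth`, `motif_truth`,
#'   `pwm`, `reads`, `sample_sheet`, `counts`, `bisulfite`.
#' @export
simulate_all <- function(config, outdir = NULL) {
  g <- simulate_genome(config)
  ann <- simulate_annotation(config, g$chrom_sizes)
  cpgi <- plant_cpg_islands(config, g$genome, ann$genes)
  mot <- plant_motif(config, cpgi$genome, ann$genes)
  truth <- simulate_expression(config, ann$genes)
  rd <- simulate_reads(config, ann$genes, truth)
  bis <- simulate_bisulfite(config)

  res <- list(
    config = config,
    genome = mot$genome,
    chrom_sizes = g$chrom_sizes,
    genes = ann$genes,
    exons = ann$exons,
    truth = truth,
    cpgi_truth = cpgi$cpgi_truth,
    motif_truth = mot$motif_truth,
    pwm = mot$pwm,
    reads = rd$reads,
    sample_sheet = rd$sample_sheet,
    counts = rd$counts,
    bisulfite = bis
  )
  if (!is.null(outdir)) write_simulation(res, outdir)
  invisible(res)
}

write_simulation <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  ss <- Biostrings::DNAStringSet(res$genome)
  Biostrings::writeXStringSet(ss, p("genome.fa"))
  readr::write_tsv(
    tibble::tibble(chrom = names(res$chrom_sizes),
                   length = unname(res$chrom_sizes)),
    p("chrom_sizes.tsv"))
  write_gtf(res$genes, res$exons, p("genes.gtf"))
  readr::write_tsv(res$reads, p("reads.tsv"))
  readr::write_tsv(res$sample_sheet[, c("sample_id", "stage", "replicate")],
                   p("sample_sheet.tsv"))
  write_jaspar(res$pwm, p("pwm_ct_rich.jaspar"), name = "ct_rich")
  readr::write_tsv(res$bisulfite$clones, p("bisulfite_clones.tsv"))
  readr::write_tsv(res$truth, p("truth_genes.tsv"))
  readr::write_tsv(res$cpgi_truth, p("truth_cpgi.tsv"))
  readr::write_tsv(res$motif_truth, p("truth_motif.tsv"))
  readr::write_tsv(res$bisulfite$truth, p("truth_methylation.tsv"))
  cfg <- unclass(res$config)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Read a genome FASTA as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Read a stranded read table
#'
#' @param path TSV with columns `chrom`, `pos` (0-based 5'-end), `strand`,
#'   `sample_id`.
#' @return tibble.
#' @export
read_reads <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    strand = readr::col_character(), sample_id = readr::col_character()
  ))
}
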