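#' Strand/region motif profile for a gene set
#'
#' For every gene, scans the promoter (-flank..-1) and gene-body (+1..+flank)
#' windows with the PWM and records presence of at least one hit in each of
#' four categories: promoter-sense, promoter-antisense, body-sense and
#' body-antisense, where sense/antisense is relative to the mRNA direction
#' (a hit is "sense" when its strand equals the gene strand). Fractions are
#' aggregated over the gene set; raw hit counts are reported alongside since
#' genes and hits can be aggregated either way.
#'
#' @param genes tibble from [parse_gene_models()] (the gene set to profile;
#'   must be non-empty).
#' @param genome named character vector of chromosome sequences.
#' @param pwm `pwm` object.
#' @param min_identity identity threshold (default 0.9).
#' @param flank window size in bp (default 500).
#' @return list with `fractions` (tibble `category`, `fraction`, `n_genes`),
#'   `hit_counts` (tibble `category`, `n_hits`) and `per_gene` (logical
#'   presence per gene per category).
#' @export
region_strand_profile <- function(genes, genome, pwm, min_identity = 0.9,
                                  flank = 500L) {
  if (nrow(genes) == 0) stop("empty gene set")
  sizes <- vapply(genome, nchar, integer(1))
  win <- motif_windows(genes, flank = flank, chrom_sizes = sizes)

  cats <- c("promoter_sense", "promoter_antisense",
            "body_sense", "body_antisense")
  pres <- matrix(FALSE, nrow(genes), 4, dimnames = list(genes$gene_id, cats))
  nhit <- stats::setNames(numeric(4), cats)
  skipped <- character(0)

  for (i in seq_len(nrow(genes))) {
    g <- win[i, ]
    seqs <- tryCatch(
      list(prom = seq_extract(genome, g$chrom, g$prom_start, g$prom_end),
           body = seq_extract(genome, g$chrom, g$body_start, g$body_end)),
      error = function(e) NULL
    )
    if (is.null(seqs)) {
      skipped <- c(skipped, g$gene_id)
      next
    }
    for (region in c("prom", "body")) {
      hits <- scan_pwm(seqs[[region]], pwm, min_identity)
      if (nrow(hits) == 0) next
      sense <- hits$strand == g$strand
      rn <- if (region == "prom") "promoter" else "body"
      pres[i, paste0(rn, "_sense")] <- any(sense)
      pres[i, paste0(rn, "_antisense")] <- any(!sense)
      nhit[paste0(rn, "_sense")] <- nhit[paste0(rn, "_sense")] + sum(sense)
      nhit[paste0(rn, "_antisense")] <-
        nhit[paste0(rn, "_antisense")] + sum(!sense)
    }
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " gene(s) with missing sequence: ",
            paste(utils::head(skipped, 3), collapse = ", "))
    pres <- pres[!rownames(pres) %in% skipped, , drop = FALSE]
  }
  list(
    fractions = tibble::tibble(
      category = cats,
      fraction = colMeans(pres),
      n_genes = nrow(pres)
    ),
    hit_counts = tibble::tibble(category = cats, n_hits = unname(nhit)),
    per_gene = tibble::as_tibble(pres, rownames = "gene_id")
  )
}

#' Motif frequency in CpGi-type versus non-CpGi-type promoters
#'
#' Promoters (non-excluded) are classified as CpGi-type when a detected CpG
#' island overlaps their -1000..-1 window; motif presence is then assessed in
#' the -500..-1 promoter window on either strand. Returns the 2x2 count table
#' and the per-class fraction of promoters with at least one hit (NA when a
#' class is empty).
#'
#' @param genes tibble from [parse_gene_models()].
#' @param promoters tibble from [define_promoters()].
#' @param genome named character vector of chromosome sequences.
#' @param pwm `pwm` object.
#' @param islands tibble from [detect_cpg_islands_genome()].
#' @param min_identity identity threshold (default 0.9).
#' @return list with `table` (2x2 matrix CpGi x motif) and `fractions`
#'   (tibble `class`, `n`, `frac_with_motif`).
#' @export
motif_cpgi_association <- function(genes, promoters, genome, pwm, islands,
                                   min_identity = 0.9) {
  kept <- promoters[!promoters$excluded, , drop = FALSE]
  if (nrow(kept) == 0) stop("no non-excluded promoters")
  cpgi <- classify_promoter_cpgi(kept, islands)

  g <- genes[match(kept$gene_id, genes$gene_id), , drop = FALSE]
  sizes <- vapply(genome, nchar, integer(1))
  win <- motif_windows(g, flank = 500L, chrom_sizes = sizes)
  has_motif <- vapply(seq_len(nrow(win)), function(i) {
    s <- seq_extract(genome, win$chrom[i], win$prom_start[i], win$prom_end[i])
    nrow(scan_pwm(s, pwm, min_identity)) > 0
  }, logical(1))

  tab <- table(
    cpgi = factor(cpgi, levels = c(TRUE, FALSE),
                  labels = c("CpGi", "non_CpGi")),
    motif = factor(has_motif, levels = c(TRUE, FALSE),
                   labels = c("motif", "no_motif"))
  )
  fractions <- tibble::tibble(
    class = c("CpGi", "non_CpGi"),
    n = c(sum(cpgi), sum(!cpgi)),
    frac_with_motif = c(
      if (sum(cpgi) > 0) mean(has_motif[cpgi]) else NA_real_,
      if (sum(!cpgi) > 0) mean(has_motif[!cpgi]) else NA_real_
    )
  )
  list(table = unclass(tab), fractions = fractions)
}

#' Select strongly upregulated pancRNAs and emit their promoter sequences
#'
#' Keeps genes whose pancRNA fold change between two stages (with
#' pseudocount) is at least `min_fold`, and extracts the -`window`..-1
#' promoter sequence oriented in the mRNA direction (reverse-complemented for
#' minus-strand genes), the input for de novo motif discovery.
#'
#' @param expr [expr_table()].
#' @param genes tibble from [parse_gene_models()].
#' @param genome named character vector of chromosome sequences.
#' @param min_fold fold-change cutoff (default 10).
#' @param pseudo pseudocount in RPKM (default 0.5).
#' @param stage_from,stage_to stage names.
#' @param window upstream window length in bp (default 200).
#' @param fasta optional path; when set, sequences are written as FASTA.
#' @return tibble `gene_id`, `log2fc_panc`, `seq`, ordered by descending fold
#'   change (ties by `gene_id`).
#' @export
select_motif_search_set <- function(expr, genes, genome, min_fold = 10,
                                    pseudo = 0.5, stage_from = "MII",
                                    stage_to = "2cell", window = 200L,
                                    fasta = NULL) {
  from <- mean_rpkm(expr, stage_from, "pancRNA")
  to <- mean_rpkm(expr, stage_to, "pancRNA")
  lfc <- log2((to + pseudo) / (from[names(to)] + pseudo))
  sel <- names(lfc)[lfc >= log2(min_fold)]
  g <- genes[match(sel, genes$gene_id), , drop = FALSE]

  seqs <- vapply(seq_len(nrow(g)), function(i) {
    if (g$strand[i] == "+") {
      seq_extract(genome, g$chrom[i], g$tss[i] - window, g$tss[i])
    } else {
      revcomp(seq_extract(genome, g$chrom[i], g$tss[i] + 1L,
                          g$tss[i] + 1L + window))
    }
  }, character(1))

  out <- tibble::tibble(gene_id = sel, log2fc_panc = unname(lfc[sel]),
                        seq = seqs) |>
    dplyr::arrange(dplyr::desc(.data$log2fc_panc), .data$gene_id)
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(out$seq)
    names(ss) <- out$gene_id
    Biostrings::writeXStringSet(ss, fasta)
  }
  out
}
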