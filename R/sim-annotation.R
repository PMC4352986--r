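# split a span of length L into k exons separated by introns, all blocks
# >= min_block; returns 0-based half-open exon offsets within the span
split_exons <- function(L, k, min_block = 60L) {
  n_block <- 2L * k - 1L
  if (L < n_block * min_block) k <- 1L
  if (k == 1L) return(tibble::tibble(off_start = 0L, off_end = L))
  n_block <- 2L * k - 1L
  # random composition of the slack over the blocks
  slack <- L - n_block * min_block
  cuts <- sort(sample.int(slack + n_block - 1L, n_block - 1L))
  sizes <- diff(c(0L, cuts, slack + n_block)) - 1L + min_block
  ends <- cumsum(sizes)
  starts <- c(0L, ends[-n_block])
  odd <- seq(1L, n_block, by = 2L)
  tibble::tibble(off_start = starts[odd], off_end = ends[odd])
}

#' Simulate a gene annotation with planted exclusion cases
#'
#' Places non-overlapping genes with at least 1 kb of upstream clearance so
#' promoters are normally usable; a configured fraction of genes gets a small
#' "decoy" gene written inside its promoter window (on the gene's own strand)
#' so that the promoter-exclusion rule fires. Gene-level truth flags
#' (partnered, CpGi-type promoter, promoter exclusion with reason) are
#' recorded; exclusion truth is computed by direct interval arithmetic
#' against all gene spans.
#'
#' @param config [sim_config()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return list with `genes` (generator gene table: coordinates, `tss`,
#'   `exon_len`, `panc_strand`, promoter interval, `is_decoy`, `partnered`,
#'   `cpgi`, `promoter_excluded`, `excl_reason`) and `exons` (tibble
#'   `gene_id`, `chrom`, `start`, `end`).
#' @export
simulate_annotation <- function(config, chrom_sizes) {
  set.seed(derive_seed(config$seed, 202L))
  n <- config$n_genes
  if (n == 0L) {
    return(list(genes = empty_sim_genes(), exons = tibble::tibble(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer())))
  }
  chroms <- names(chrom_sizes)
  chrom_of <- rep(chroms, length.out = n)[order(rep(seq_along(chroms),
                                                    length.out = n))]

  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 n, replace = TRUE)
  gaps <- sample(seq(config$gap_range[1], config$gap_range[2]),
                 n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  start <- integer(n)
  end <- integer(n)
  for (ch in chroms) {
    ix <- which(chrom_of == ch)
    if (length(ix) == 0) next
    pos <- cumsum(gaps[ix] + lens[ix]) - lens[ix]
    start[ix] <- pos
    end[ix] <- pos + lens[ix]
    tail_clear <- chrom_sizes[[ch]] - (pos[length(ix)] + lens[ix][length(ix)])
    if (tail_clear < config$gap_range[1]) {
      stop("genome too small for ", length(ix), " genes on ", ch)
    }
  }

  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chrom_of,
    strand = strand,
    start = start,
    end = end,
    is_decoy = FALSE,
    partnered = stats::runif(n) < config$frac_panc_partnered
  )

  # decoy genes inside the promoter windows of a planted-excluded fraction
  excl_ix <- which(stats::runif(n) < config$frac_promoter_excluded)
  decoys <- lapply(seq_along(excl_ix), function(k) {
    i <- excl_ix[k]
    plen <- config$promoter_len
    ps <- if (genes$strand[i] == "+") genes$start[i] - plen else genes$end[i] + 1L
    dlen <- sample(150:250, 1L)
    off <- sample.int(plen - dlen + 1L, 1L) - 1L
    tibble::tibble(
      gene_id = sprintf("decoy%03d", k),
      chrom = genes$chrom[i],
      strand = genes$strand[i],   # same strand: panc reads can never hit it
      start = ps + off,
      end = ps + off + dlen,
      is_decoy = TRUE,
      partnered = FALSE
    )
  })
  genes <- dplyr::bind_rows(genes, decoys)
  ng <- nrow(genes)

  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$panc_strand <- opposite_strand(genes$strand)
  plen <- config$promoter_len
  genes$promoter_start <- ifelse(genes$strand == "+",
                                 genes$tss - plen, genes$tss + 1L)
  genes$promoter_end <- genes$promoter_start + plen

  # exclusion truth by brute interval arithmetic against all other spans
  clen <- unname(chrom_sizes[genes$chrom])
  oob <- genes$promoter_start < 0L | genes$promoter_end > clen
  ovl <- vapply(seq_len(ng), function(i) {
    same <- genes$chrom == genes$chrom[i] & seq_len(ng) != i
    any(intervals_overlap(genes$promoter_start[i], genes$promoter_end[i],
                          genes$start[same], genes$end[same]))
  }, logical(1))
  genes$promoter_excluded <- oob | ovl
  genes$excl_reason <- dplyr::case_when(
    oob ~ "out_of_bounds",
    ovl ~ "overlaps_gene",
    TRUE ~ NA_character_
  )

  genes$cpgi <- !genes$is_decoy &
    stats::runif(ng) < ifelse(genes$partnered, config$cpgi_rate_partnered,
                              config$cpgi_rate_lacking)

  exons <- lapply(seq_len(ng), function(i) {
    L <- genes$end[i] - genes$start[i]
    k <- if (genes$is_decoy[i]) 1L else sample(1:3, 1L, prob = c(0.5, 0.3, 0.2))
    ex <- split_exons(L, k)
    tibble::tibble(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                   start = genes$start[i] + ex$off_start,
                   end = genes$start[i] + ex$off_end)
  })
  exons <- dplyr::bind_rows(exons)
  genes$exon_len <- as.integer(
    tapply(exons$end - exons$start, exons$gene_id, sum)[genes$gene_id])

  list(genes = genes, exons = exons)
}

empty_sim_genes <- function() {
  tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), is_decoy = logical(),
    partnered = logical(), tss = integer(), panc_strand = character(),
    promoter_start = integer(), promoter_end = integer(),
    promoter_excluded = logical(), excl_reason = character(),
    cpgi = logical(), exon_len = integer()
  )
}

#' Write a generator annotation as GTF
#'
#' Emits one `gene` row and its `exon` rows per gene, 1-based inclusive
#' coordinates, attributes `gene_id` and `transcript_id`.
#'
#' @param genes,exons tables from [simulate_annotation()].
#' @param path output file.
#' @export
write_gtf <- function(genes, exons, path) {
  attr_of <- function(id) {
    sprintf('gene_id "%s"; transcript_id "%s.t1";', id, id)
  }
  gene_rows <- sprintf("%s\tpancscreen_sim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       genes$chrom, genes$start + 1L, genes$end,
                       genes$strand, attr_of(genes$gene_id))
  g <- genes[match(exons$gene_id, genes$gene_id), ]
  exon_rows <- sprintf("%s\tpancscreen_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
                       exons$chrom, exons$start + 1L, exons$end,
                       g$strand, attr_of(exons$gene_id))
  ord <- order(c(genes$chrom, exons$chrom),
               c(genes$start, exons$start),
               c(rep(0L, nrow(genes)), rep(1L, nrow(exons))))
  writeLines(c(gene_rows, exon_rows)[ord], path)
  invisible(path)
}
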