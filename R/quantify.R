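#' Strand-aware 5'-end read counting over intervals
#'
#' A read is counted for an interval iff its 5' end lies inside the half-open
#' interval AND its strand equals the interval's strand. A read may count
#' toward several overlapping intervals. Using the 5' end only (rather than
#' any overlap) makes assignment unambiguous at window boundaries for short
#' single-end reads.
#'
#' @param reads tibble with `chrom`, `pos` (0-based 5'-end position),
#'   `strand`, `sample_id`.
#' @param intervals tibble with `id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param samples optional character vector fixing the sample columns (and
#'   their order) of the result; defaults to the sorted samples present in
#'   `reads`.
#' @param known_chroms optional character vector of valid chromosome names;
#'   reads on other chromosomes are skipped with a warning.
#' @return integer matrix intervals x samples, dimnames `id` x sample.
#' @export
count_stranded_reads <- function(reads, intervals, samples = NULL,
                                 known_chroms = NULL) {
  stopifnot(all(intervals$end > intervals$start))
  if (!is.null(known_chroms)) {
    bad <- !(reads$chrom %in% known_chroms)
    if (any(bad)) {
      warning("skipping ", sum(bad), " read(s) on unknown chromosome(s): ",
              paste(utils::head(unique(reads$chrom[bad]), 3), collapse = ", "))
      reads <- reads[!bad, , drop = FALSE]
    }
  }
  if (is.null(samples)) samples <- sort(unique(reads$sample_id))
  out <- matrix(0L, nrow = nrow(intervals), ncol = length(samples),
                dimnames = list(intervals$id, samples))
  if (nrow(reads) == 0 || nrow(intervals) == 0) return(out)

  # keep only reads on chromosomes that carry intervals (others cannot hit)
  reads <- reads[reads$chrom %in% unique(intervals$chrom), , drop = FALSE]
  if (nrow(reads) == 0) return(out)

  read_gr <- as_granges0(reads$chrom, reads$pos, reads$pos + 1L, reads$strand)
  iv_gr <- as_granges0(intervals$chrom, intervals$start, intervals$end,
                       intervals$strand)
  hits <- GenomicRanges::findOverlaps(iv_gr, read_gr, ignore.strand = FALSE)
  if (length(hits) > 0) {
    tab <- table(
      factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(intervals))),
      factor(reads$sample_id[S4Vectors::subjectHits(hits)], levels = samples)
    )
    out[] <- as.integer(tab)
  }
  out
}

#' Reads per kilobase of feature per million mapped reads
#'
#' `rpkm = count / ((length_bp/1000) * (total_reads/1e6))`. mRNA features use
#' the exonic length, pancRNA features the promoter window length.
#'
#' @param count non-negative read count (vectorized).
#' @param length_bp feature length in bp (>= 1).
#' @param total_reads total mapped reads in the sample (>= 1).
#' @return numeric RPKM values.
#' @export
compute_rpkm <- function(count, length_bp, total_reads) {
  if (any(length_bp < 1)) stop("feature length must be >= 1 bp")
  if (any(total_reads < 1)) stop("total mapped reads must be >= 1")
  if (any(count < 0)) stop("counts must be non-negative")
  count / ((length_bp / 1000) * (total_reads / 1e6))
}

#' Library strandedness QC
#'
#' Among reads whose 5' end falls within exactly one gene span, the fraction
#' whose strand equals that gene's annotated strand. Reads in zero or
#' multiple gene spans are ignored as ambiguous.
#'
#' @param reads read tibble (see [count_stranded_reads()]).
#' @param genes gene tibble from [parse_gene_models()].
#' @param by_sample if TRUE, return one row per sample.
#' @return list with `fraction` and `n` (eligible reads); with
#'   `by_sample = TRUE` a tibble `sample_id`, `fraction`, `n`.
#' @export
strandedness_qc <- function(reads, genes, by_sample = FALSE) {
  read_gr <- as_granges0(reads$chrom, reads$pos, reads$pos + 1L)
  span_gr <- as_granges0(genes$chrom, genes$start, genes$end)
  cnt <- GenomicRanges::countOverlaps(read_gr, span_gr, ignore.strand = TRUE)
  elig <- which(cnt == 1L)
  if (length(elig) == 0) stop("no reads fall within exactly one gene span")
  hits <- GenomicRanges::findOverlaps(read_gr[elig], span_gr,
                                      ignore.strand = TRUE)
  correct <- reads$strand[elig][S4Vectors::queryHits(hits)] ==
    genes$strand[S4Vectors::subjectHits(hits)]
  if (!by_sample) {
    return(list(fraction = mean(correct), n = length(correct)))
  }
  tibble::tibble(
    sample_id = reads$sample_id[elig][S4Vectors::queryHits(hits)],
    correct = correct
  ) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(fraction = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop")
}

#' Pairwise replicate correlation at one stage
#'
#' Pearson correlation of log2(RPKM + 1) between all replicate pairs of a
#' stage. Zero-variance replicates yield NA entries (off-diagonal) with a
#' warning.
#'
#' @param expr [expr_table()].
#' @param stage stage name.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(expr, stage) {
  ids <- stage_samples(expr, stage)
  if (length(ids) < 2) stop("need >= 2 replicates at stage ", stage)
  if (nrow(expr$features) < 3) stop("need >= 3 features")
  m <- log2(expr$rpkm[, ids, drop = FALSE] + 1)
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  if (any(sds == 0)) {
    warning("zero-variance replicate(s): ",
            paste(ids[sds == 0], collapse = ", "),
            "; correlations reported as NA")
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Quantify pancRNA/mRNA feature pairs from stranded reads
#'
#' For each gene, the pancRNA feature counts reads whose 5' end lies in the
#' promoter window on the pancRNA (antisense) strand; the mRNA feature counts
#' reads on the gene strand over the gene span. Genes with an excluded
#' promoter get no pancRNA feature. RPKM uses the promoter length for
#' pancRNAs and the exonic length for mRNAs; the per-sample total is the
#' number of reads in the read table for that sample.
#'
#' @param reads read tibble (see [count_stranded_reads()]).
#' @param promoters tibble from [define_promoters()].
#' @param genes tibble from [parse_gene_models()].
#' @param sample_sheet tibble with `sample_id`, `stage`, `replicate`.
#' @param known_chroms optional valid chromosome names for read screening.
#' @return [expr_table()].
#' @export
quantify_pairs <- function(reads, promoters, genes, sample_sheet,
                           known_chroms = NULL) {
  extra <- setdiff(unique(reads$sample_id), sample_sheet$sample_id)
  if (length(extra) > 0) {
    stop("sample(s) in reads absent from sample sheet: ",
         paste(extra, collapse = ", "))
  }
  kept <- promoters[!promoters$excluded, , drop = FALSE]
  panc_len <- kept$end - kept$start
  gene_ix <- match(kept$gene_id, genes$gene_id)

  features <- tibble::tibble(
    feature_id = c(paste0("panc_", kept$gene_id),
                   paste0("mrna_", genes$gene_id)),
    kind = rep(c("pancRNA", "mRNA"), c(nrow(kept), nrow(genes))),
    gene_id = c(kept$gene_id, genes$gene_id),
    length_bp = as.integer(c(panc_len, genes$exon_len))
  )
  intervals <- tibble::tibble(
    id = features$feature_id,
    chrom = c(kept$chrom, genes$chrom),
    start = c(kept$start, genes$start),
    end = c(kept$end, genes$end),
    strand = c(kept$panc_strand, genes$strand)
  )

  samples <- sample_sheet[order(sample_sheet$sample_id), , drop = FALSE]
  counts <- count_stranded_reads(reads, intervals,
                                 samples = samples$sample_id,
                                 known_chroms = known_chroms)
  totals <- table(factor(reads$sample_id, levels = samples$sample_id))
  samples$total_reads <- as.integer(totals)
  rpkm <- compute_rpkm(
    counts,
    matrix(features$length_bp, nrow(counts), ncol(counts)),
    matrix(samples$total_reads, nrow(counts), ncol(counts), byrow = TRUE)
  )
  dimnames(rpkm) <- dimnames(counts)
  expr_table(features, samples, counts, rpkm)
}
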