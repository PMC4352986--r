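#' Parse gene models from a GTF file
#'
#' Reads a GTF (1-based inclusive coordinates) and derives one gene model per
#' `gene_id`: the transcript span, the 5'-most TSS on the gene's strand, and
#' the total exonic length (union of exons) used for mRNA RPKM. All returned
#' coordinates are 0-based half-open.
#'
#' @param path path to a GTF file with exon features carrying a `gene_id`
#'   attribute.
#' @return tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span), `tss` (0-based position) and `exon_len`.
#' @export
parse_gene_models <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0) return(parse_gene_models_empty())
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfields < 8)) {
    stop("GTF parse error in '", path, "': malformed line ",
         body[which(nfields < 8)[1]], call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0) {
    return(tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), tss = integer(),
      exon_len = integer()
    ))
  }
  ids <- as.character(S4Vectors::mcols(gr)$gene_id)
  types <- as.character(S4Vectors::mcols(gr)$type)
  exons <- gr[types == "exon"]
  exon_ids <- ids[types == "exon"]

  all_ids <- unique(ids)
  no_exon <- setdiff(all_ids, unique(exon_ids))
  if (length(no_exon) > 0) {
    warning("skipping ", length(no_exon), " gene(s) with no exons: ",
            paste(utils::head(no_exon, 5), collapse = ", "))
  }
  if (length(exons) == 0) {
    return(parse_gene_models_empty())
  }

  by_gene <- S4Vectors::split(exons, factor(exon_ids, levels = unique(exon_ids)))
  red <- GenomicRanges::reduce(by_gene)
  exon_len <- sum(GenomicRanges::width(red))
  span <- unlist(range(by_gene))
  strand <- as.character(GenomicRanges::strand(span))
  if (any(!strand %in% c("+", "-"))) {
    stop("gene(s) without a defined strand: ",
         paste(names(span)[!strand %in% c("+", "-")], collapse = ", "))
  }
  start0 <- GenomicRanges::start(span) - 1L  # 1-based inclusive -> 0-based
  end0 <- GenomicRanges::end(span)           # inclusive end == half-open end
  tibble::tibble(
    gene_id = names(span),
    chrom = as.character(GenomicRanges::seqnames(span)),
    strand = strand,
    start = start0,
    end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    exon_len = as.integer(exon_len[names(span)])
  )
}

parse_gene_models_empty <- function() {
  tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), tss = integer(), exon_len = integer()
  )
}

#' Define strand-aware promoter windows for pancRNA quantification
#'
#' The promoter window is the region -`upstream_len`..-1 relative to the TSS,
#' on the gene's own coordinate system; the pancRNA strand is the strand
#' opposite to the gene. A window is excluded (with a machine-readable
#' reason) when it does not fit inside the chromosome (`out_of_bounds`) or
#' when it overlaps the span of any other gene on either strand
#' (`overlaps_gene`), so that read-through from neighbouring genes cannot
#' contaminate the pancRNA pool.
#'
#' @param genes tibble from [parse_gene_models()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param upstream_len promoter length in bp (default 1000).
#' @return tibble with `gene_id`, `chrom`, `start`, `end` (0-based half-open,
#'   length `upstream_len` always), `panc_strand`, `excluded`, `reason`.
#' @export
define_promoters <- function(genes, chrom_sizes, upstream_len = 1000L) {
  stopifnot(all(genes$chrom %in% names(chrom_sizes)))
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream_len, genes$tss + 1L)
  end <- start + upstream_len
  panc_strand <- opposite_strand(genes$strand)

  clen <- unname(chrom_sizes[genes$chrom])
  oob <- start < 0L | end > clen

  # overlap with the span of any OTHER gene, either strand
  overlaps <- rep(FALSE, nrow(genes))
  ok <- which(!oob)
  if (length(ok) > 0 && nrow(genes) > 1) {
    prom_gr <- as_granges0(genes$chrom[ok], start[ok], end[ok])
    span_gr <- as_granges0(genes$chrom, genes$start, genes$end)
    hits <- GenomicRanges::findOverlaps(prom_gr, span_gr, ignore.strand = TRUE)
    self <- genes$gene_id[ok][S4Vectors::queryHits(hits)] ==
      genes$gene_id[S4Vectors::subjectHits(hits)]
    overlaps[ok] <- tabulate(S4Vectors::queryHits(hits)[!self],
                             nbins = length(ok)) > 0
  }

  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = as.integer(start),
    end = as.integer(end),
    panc_strand = panc_strand,
    excluded = oob | overlaps,
    reason = dplyr::case_when(
      oob ~ "out_of_bounds",
      overlaps ~ "overlaps_gene",
      TRUE ~ NA_character_
    )
  )
}

#' Motif-analysis windows around the TSS
#'
#' Returns the promoter (-`flank`..-1) and gene-body (+1..+`flank`) windows
#' in genomic coordinates, following gene orientation: for minus-strand genes
#' the promoter window lies to the right of the TSS. A gene body shorter than
#' `flank` yields a body window truncated to the span, flagged `truncated`.
#' Windows are clipped to the chromosome when `chrom_sizes` is supplied.
#'
#' @param genes tibble from [parse_gene_models()].
#' @param flank window size in bp (default 500).
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   clipping.
#' @return tibble with promoter and body intervals (0-based half-open) and a
#'   `body_truncated` flag.
#' @export
motif_windows <- function(genes, flank = 500L, chrom_sizes = NULL) {
  plus <- genes$strand == "+"
  span_len <- genes$end - genes$start
  body_len <- pmin(span_len, flank)

  prom_start <- ifelse(plus, genes$tss - flank, genes$tss + 1L)
  prom_end <- prom_start + flank
  body_start <- ifelse(plus, genes$start, genes$end - body_len)
  body_end <- ifelse(plus, genes$start + body_len, genes$end)

  if (!is.null(chrom_sizes)) {
    clen <- unname(chrom_sizes[genes$chrom])
    prom_start <- pmax(prom_start, 0L)
    prom_end <- pmin(prom_end, clen)
  }

  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    strand = genes$strand,
    prom_start = as.integer(prom_start),
    prom_end = as.integer(prom_end),
    body_start = as.integer(body_start),
    body_end = as.integer(body_end),
    body_truncated = span_len < flank
  )
}
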