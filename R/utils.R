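#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a subsequence from a genome in 0-based half-open coordinates
#'
#' @param genome named character vector, one element per chromosome.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return character scalar.
#' @export
seq_extract <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  n <- nchar(genome[[chrom]])
  if (start < 0 || end > n || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, n))
  }
  substr(genome[[chrom]], start + 1L, end)
}

# half-open interval overlap, vectorized
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# GRanges from 0-based half-open tibble columns
as_granges0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}

opposite_strand <- function(strand) ifelse(strand == "+", "-", "+")

# derive a stage-specific sub-seed from a base seed; keep well under 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 2000000L) * 1000L + as.integer(offset)
}

#' Write intervals as BED6 (0-based half-open)
#'
#' @param df tibble with columns chrom, start, end and optionally name,
#'   score, strand.
#' @param path output file.
#' @export
write_bed6 <- function(df, path) {
  bed <- tibble::tibble(
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0L,
    strand = if ("strand" %in% names(df)) df$strand else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
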