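#' Detect CpG islands in a DNA sequence
#'
#' Classical sliding-window definition: every `min_len`-bp window (1-bp step)
#' with G+C fraction >= `min_gc` and observed/expected CpG >= `min_oe` is a
#' seed; overlapping seed windows are merged into maximal islands, whose GC
#' fraction and obs/exp CpG are then recomputed over the merged interval.
#' Obs/exp CpG for a window of length L is `n_CpG * L / (n_C * n_G)`. Windows
#' containing N are never seeds, so runs of N break islands.
#'
#' @param seq DNA string (ACGTN, case-insensitive).
#' @param min_len minimum island (and window) length, bp.
#' @param min_gc minimum G+C fraction.
#' @param min_oe minimum observed/expected CpG ratio.
#' @param chrom optional chromosome name to stamp on the output.
#' @return tibble with `chrom`, `start`, `end` (0-based half-open), `length`,
#'   `gc_fraction`, `obs_exp_cpg`. Empty when the sequence is shorter than
#'   `min_len` or no window passes.
#' @export
detect_cpg_islands <- function(seq, min_len = 200L, min_gc = 0.5,
                               min_oe = 0.6, chrom = NA_character_) {
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    length = integer(), gc_fraction = numeric(), obs_exp_cpg = numeric()
  )
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  L <- as.integer(min_len)
  if (n < L) return(empty)

  is_c <- ch == "C"
  is_g <- ch == "G"
  is_n <- !(ch %in% c("A", "C", "G", "T"))
  is_cpg <- c(is_c[-n] & is_g[-1], FALSE)

  cs_c <- c(0, cumsum(is_c))
  cs_g <- c(0, cumsum(is_g))
  cs_n <- c(0, cumsum(is_n))
  cs_cpg <- c(0, cumsum(is_cpg))

  starts <- seq_len(n - L + 1L)                    # 1-based window starts
  wc <- cs_c[starts + L] - cs_c[starts]
  wg <- cs_g[starts + L] - cs_g[starts]
  wn <- cs_n[starts + L] - cs_n[starts]
  # CpG dinucleotides fully inside the window start at starts..starts+L-2
  wcpg <- cs_cpg[starts + L - 1L] - cs_cpg[starts]

  gc <- (wc + wg) / L
  oe <- ifelse(wc > 0 & wg > 0, wcpg * L / (wc * wg), 0)
  pass <- wn == 0 & gc >= min_gc & oe >= min_oe
  if (!any(pass)) return(empty)

  merged <- IRanges::reduce(IRanges::IRanges(start = starts[pass], width = L))
  s1 <- IRanges::start(merged)                      # 1-based
  e1 <- IRanges::end(merged)
  len <- e1 - s1 + 1L
  ic <- cs_c[e1 + 1L] - cs_c[s1]
  ig <- cs_g[e1 + 1L] - cs_g[s1]
  icpg <- cs_cpg[e1] - cs_cpg[s1]                   # dinucs inside island
  tibble::tibble(
    chrom = chrom,
    start = s1 - 1L,
    end = e1,
    length = len,
    gc_fraction = (ic + ig) / len,
    obs_exp_cpg = ifelse(ic > 0 & ig > 0, icpg * len / (ic * ig), 0)
  )
}

#' Detect CpG islands on every chromosome of a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @inheritParams detect_cpg_islands
#' @return tibble as in [detect_cpg_islands()], rows over all chromosomes.
#' @export
detect_cpg_islands_genome <- function(genome, min_len = 200L, min_gc = 0.5,
                                      min_oe = 0.6) {
  dplyr::bind_rows(lapply(names(genome), function(chr) {
    detect_cpg_islands(genome[[chr]], min_len, min_gc, min_oe, chrom = chr)
  }))
}

#' Classify promoters as CpG-island type
#'
#' A promoter is CpGi-type iff any detected island overlaps its window by at
#' least 1 bp (half-open intervals).
#'
#' @param promoters tibble from [define_promoters()].
#' @param islands tibble from [detect_cpg_islands_genome()].
#' @return logical vector along `promoters` rows.
#' @export
classify_promoter_cpgi <- function(promoters, islands) {
  if (nrow(islands) == 0 || nrow(promoters) == 0) {
    return(rep(FALSE, nrow(promoters)))
  }
  prom_gr <- as_granges0(promoters$chrom, promoters$start, promoters$end)
  isl_gr <- as_granges0(islands$chrom, islands$start, islands$end)
  GenomicRanges::countOverlaps(prom_gr, isl_gr, ignore.strand = TRUE) > 0
}
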