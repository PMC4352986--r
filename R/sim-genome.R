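#' Simulate a background genome
#'
#' First-order Markov background with uniform base composition (GC fraction
#' 0.5 in expectation) and depleted C->G transitions (`cpg_depletion` of the
#' uniform rate), giving a genome-wide observed/expected CpG around 0.2 as in
#' vertebrate genomes. The depletion matters: without it every 200-bp window
#' has obs/exp CpG near 1 and the classical island definition would classify
#' the entire genome as island, leaving no non-CpGi promoter class. The
#' transition matrix is doubly stochastic and invariant under
#' reverse-complement, so the background is strand-symmetric. CpG islands and
#' motifs are planted by later generator steps once gene positions are known.
#'
#' @param config [sim_config()].
#' @param cpg_depletion C->G transition probability as a fraction of the
#'   uniform 0.25 (default 0.08).
#' @return list with `genome` (named character vector) and `chrom_sizes`
#'   (named integer vector).
#' @export
simulate_genome <- function(config, cpg_depletion = 0.08) {
  set.seed(derive_seed(config$seed, 101L))
  chroms <- paste0("chr", seq_len(config$n_chrom))
  genome <- vapply(chroms, function(ch) {
    markov_chrom(config$chrom_length, q = 0.25 * cpg_depletion)
  }, character(1))
  list(genome = genome,
       chrom_sizes = stats::setNames(rep(config$chrom_length,
                                         config$n_chrom), chroms))
}

# CpG-depleted, uniform-composition, strand-symmetric Markov sequence.
# Row C: ->G with prob q, ->A/C/T with (1-q)/3 each; rows A/G/T: ->G with
# (1-q)/3, ->A/C/T with (1-(1-q)/3)/3 each. Doubly stochastic, so the
# stationary distribution is uniform.
markov_chrom <- function(n, q = 0.02) {
  p_c_c <- (1 - q) / 3             # P(next = C | cur = C)
  p_c_n <- (1 - (1 - q) / 3) / 3   # P(next = C | cur != C)
  u <- stats::runif(n)
  is_c <- logical(n)
  is_c[1] <- u[1] < 0.25
  for (i in 2:n) {
    is_c[i] <- u[i] < (if (is_c[i - 1]) p_c_c else p_c_n)
  }
  # fill non-C letters given whether the previous base is C
  letters <- character(n)
  letters[is_c] <- "C"
  prev_c <- c(FALSE, is_c[-n])
  v <- stats::runif(n)
  fill <- !is_c
  # after a C: (A,G,T) ~ ((1-q)/3, q, (1-q)/3) / (1 - (1-q)/3)
  pa1 <- ((1 - q) / 3) / (1 - p_c_c)
  pg1 <- q / (1 - p_c_c)
  # after a non-C: (A,G,T) ~ (p_c_n, (1-q)/3, p_c_n) / (1 - p_c_n)
  pa2 <- p_c_n / (1 - p_c_n)
  pg2 <- ((1 - q) / 3) / (1 - p_c_n)
  pa <- ifelse(prev_c, pa1, pa2)
  pg <- ifelse(prev_c, pg1, pg2)
  out <- ifelse(v < pa, "A", ifelse(v < pa + pg, "G", "T"))
  # first base: uniform over A/G/T when not C
  letters[fill] <- out[fill]
  paste(letters, collapse = "")
}

# GC- and CpG-rich segment: concatenated units CG/C/G/A/T with weights
# giving ~0.79 GC fraction and obs/exp CpG ~1.8
cpgi_segment <- function(len) {
  units <- sample(c("CG", "C", "G", "A", "T"), size = len,
                  replace = TRUE, prob = c(0.4, 0.15, 0.15, 0.15, 0.15))
  substr(paste(units, collapse = ""), 1L, len)
}

#' Plant CpG islands in promoters flagged CpGi-type
#'
#' Writes a GC/CpG-rich segment at a uniform position inside the promoter
#' window of every gene whose truth row has `cpgi = TRUE`.
#'
#' @param config [sim_config()].
#' @param genome named character vector (modified copy returned).
#' @param genes generator gene table (from [simulate_annotation()]).
#' @return list with `genome` and `cpgi_truth` (tibble `gene_id`, `chrom`,
#'   `start`, `end`).
#' @export
plant_cpg_islands <- function(config, genome, genes) {
  set.seed(derive_seed(config$seed, 303L))
  rows <- which(genes$cpgi)
  rec <- vector("list", length(rows))
  L <- config$cpgi_length
  for (k in seq_along(rows)) {
    i <- rows[k]
    room <- (genes$promoter_end[i] - genes$promoter_start[i]) - L
    off <- if (room > 0) sample.int(room + 1L, 1L) - 1L else 0L
    s <- genes$promoter_start[i] + off
    seg <- cpgi_segment(L)
    substr(genome[[genes$chrom[i]]], s + 1L, s + L) <- seg
    rec[[k]] <- tibble::tibble(gene_id = genes$gene_id[i],
                               chrom = genes$chrom[i],
                               start = s, end = s + L)
  }
  list(genome = genome, cpgi_truth = dplyr::bind_rows(rec))
}

#' Plant the CT-rich motif with strand-asymmetric placement
#'
#' For every non-decoy gene and each of the four placement categories
#' (promoter_sense, promoter_antisense, body_sense, body_antisense), the
#' consensus is written with the per-category probability of the gene's class
#' (partnered vs lacking). "Sense" means the motif lies on the gene's strand;
#' minus-strand placements write the reverse complement into the plus-strand
#' genome. Positions are drawn uniformly inside the -500..-1 or +1..+500
#' window; a position colliding with an earlier planting is re-drawn (20
#' tries), then skipped and recorded as unplanted. The generating PWM (built
#' from the consensus) is returned for closed-loop scanning.
#'
#' @param config [sim_config()].
#' @param genome named character vector (modified copy returned).
#' @param genes generator gene table.
#' @return list with `genome`, `motif_truth` (tibble `gene_id`, `category`,
#'   `chrom`, `start`, `strand`, `planted`) and `pwm`.
#' @export
plant_motif <- function(config, genome, genes) {
  set.seed(derive_seed(config$seed, 404L))
  consensus <- toupper(config$motif_consensus)
  w <- nchar(consensus)
  pwm <- build_pwm(rep(consensus, 10L), pseudocount = 0.5)

  sizes <- vapply(genome, nchar, integer(1))
  targets <- genes[!genes$is_decoy, , drop = FALSE]
  win <- motif_windows(targets, flank = 500L, chrom_sizes = sizes)
  cats <- c("promoter_sense", "promoter_antisense",
            "body_sense", "body_antisense")

  occupied <- stats::setNames(vector("list", length(genome)), names(genome))
  rec <- list()
  for (i in seq_len(nrow(targets))) {
    rates <- if (targets$partnered[i]) config$motif_rates_partnered
             else config$motif_rates_lacking
    for (cat in cats) {
      if (stats::runif(1) >= rates[[cat]]) next
      in_prom <- startsWith(cat, "promoter")
      ws <- if (in_prom) win$prom_start[i] else win$body_start[i]
      we <- if (in_prom) win$prom_end[i] else win$body_end[i]
      strand <- if (endsWith(cat, "_sense")) targets$strand[i]
                else opposite_strand(targets$strand[i])
      if (we - ws < w) next
      chrom <- targets$chrom[i]
      placed <- FALSE
      for (try in seq_len(20L)) {
        s <- ws + sample.int(we - ws - w + 1L, 1L) - 1L
        occ <- occupied[[chrom]]
        if (!is.null(occ) &&
            any(intervals_overlap(s, s + w, occ$start, occ$end))) next
        text <- if (strand == "+") consensus else revcomp(consensus)
        substr(genome[[chrom]], s + 1L, s + w) <- text
        occupied[[chrom]] <- dplyr::bind_rows(
          occ, tibble::tibble(start = s, end = s + w))
        rec[[length(rec) + 1]] <- tibble::tibble(
          gene_id = targets$gene_id[i], category = cat, chrom = chrom,
          start = s, strand = strand, planted = TRUE)
        placed <- TRUE
        break
      }
      if (!placed) {
        rec[[length(rec) + 1]] <- tibble::tibble(
          gene_id = targets$gene_id[i], category = cat, chrom = chrom,
          start = NA_integer_, strand = strand, planted = FALSE)
      }
    }
  }
  motif_truth <- if (length(rec) > 0) dplyr::bind_rows(rec) else
    tibble::tibble(gene_id = character(), category = character(),
                   chrom = character(), start = integer(),
                   strand = character(), planted = logical())
  list(genome = genome, motif_truth = motif_truth, pwm = pwm)
}
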