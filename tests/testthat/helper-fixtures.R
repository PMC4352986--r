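# Shared fixtures, all built in code at test time.

# small simulation config that keeps unit tests fast
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 2L, chrom_length = 120000L,
         n_genes = 60L, depth = 30000L),
    list(...))
  do.call(sim_config, args)
}

# hand-built gene table in 0-based half-open coordinates
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(5000L, 9000L, 2000L),
    end = c(7000L, 10000L, 2300L),
    tss = c(5000L, 9999L, 2000L),
    exon_len = c(2000L, 1000L, 300L)
  )
}

toy_chrom_sizes <- c(chr1 = 20000L, chr2 = 20000L)

# build an expr_table directly from an RPKM matrix (counts set equal)
toy_expr <- function(rpkm, kind, gene_id, stages) {
  features <- tibble::tibble(
    feature_id = rownames(rpkm), kind = kind, gene_id = gene_id,
    length_bp = 1000L
  )
  samples <- tibble::tibble(
    sample_id = colnames(rpkm),
    stage = stages,
    replicate = as.integer(stats::ave(seq_along(stages), stages,
                                      FUN = seq_along)),
    total_reads = 1000000L
  )
  expr_table(features, samples, round(rpkm), rpkm)
}

# expr_table for a set of genes x stages with given per-stage panc/mrna RPKM
# (replicated identically across n_rep replicates unless noise_sd > 0)
pair_expr <- function(panc, mrna, stages, n_rep = 2, noise_sd = 0) {
  genes <- rownames(panc)
  sample_ids <- as.vector(outer(stages, seq_len(n_rep),
                                function(s, r) paste0(s, "_r", r)))
  stage_of <- rep(stages, n_rep)
  mk <- function(m, prefix) {
    out <- matrix(0, nrow(m), length(sample_ids),
                  dimnames = list(paste0(prefix, genes), sample_ids))
    for (j in seq_along(sample_ids)) {
      out[, j] <- pmax(m[, stage_of[j]] + stats::rnorm(nrow(m), 0, noise_sd), 0)
    }
    out
  }
  rpkm <- rbind(mk(panc, "panc_"), mk(mrna, "mrna_"))
  features <- tibble::tibble(
    feature_id = rownames(rpkm),
    kind = rep(c("pancRNA", "mRNA"), each = length(genes)),
    gene_id = rep(genes, 2),
    length_bp = 1000L
  )
  samples <- tibble::tibble(
    sample_id = sample_ids, stage = stage_of,
    replicate = rep(seq_len(n_rep), each = length(stages)),
    total_reads = 1000000L
  )
  expr_table(features, samples, round(rpkm), rpkm)
}

# brute-force oracle for strand-aware 5'-end counting: per-interval,
# per-sample double loop over reads
brute_count <- function(reads, intervals, samples) {
  out <- matrix(0L, nrow(intervals), length(samples),
                dimnames = list(intervals$id, samples))
  for (i in seq_len(nrow(intervals))) {
    for (j in seq_along(samples)) {
      out[i, j] <- sum(reads$chrom == intervals$chrom[i] &
                         reads$pos >= intervals$start[i] &
                         reads$pos < intervals$end[i] &
                         reads$strand == intervals$strand[i] &
                         reads$sample_id == samples[j])
    }
  }
  out
}

# independent textbook Welch computation on log2(x + 1)
welch_oracle <- function(x, y) {
  lx <- log2(x + 1); ly <- log2(y + 1)
  v1 <- stats::var(lx) / length(lx)
  v2 <- stats::var(ly) / length(ly)
  t <- (mean(lx) - mean(ly)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(lx) - 1) + v2^2 / (length(ly) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# independent exhaustive Mann-Whitney oracle: enumerate labelings through
# bitmasks (different code path from the package's combn-based exact mode)
mwu_oracle <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  us <- c()
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[1:N]
    if (sum(bits) != n) next
    us <- c(us, sum(r[bits == 1]) - n * (n + 1) / 2)
  }
  eps <- 1e-9
  list(U = u_obs,
       p_two = min(1, 2 * min(mean(us >= u_obs - eps),
                              mean(us <= u_obs + eps))))
}

# random read/interval fixture generator
random_read_fixture <- function(n_reads, n_intervals, seed,
                                chroms = c("chr1", "chr2"), clen = 100000L,
                                n_samples = 3L) {
  set.seed(seed)
  list(
    reads = tibble::tibble(
      chrom = sample(chroms, n_reads, replace = TRUE),
      pos = sample.int(clen, n_reads, replace = TRUE) - 1L,
      strand = sample(c("+", "-"), n_reads, replace = TRUE),
      sample_id = sample(paste0("s", seq_len(n_samples)), n_reads,
                         replace = TRUE)
    ),
    intervals = {
      s <- sample.int(clen - 2000L, n_intervals, replace = TRUE) - 1L
      tibble::tibble(
        id = paste0("iv", seq_len(n_intervals)),
        chrom = sample(chroms, n_intervals, replace = TRUE),
        start = s,
        end = s + sample(100:2000, n_intervals, replace = TRUE),
        strand = sample(c("+", "-"), n_intervals, replace = TRUE)
      )
    },
    samples = paste0("s", seq_len(n_samples))
  )
}
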