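test_that("counting honours the 5'-end rule and strand match", {
  intervals <- tibble::tibble(id = "prom", chrom = "chr1",
                              start = 4000L, end = 5000L, strand = "-")
  reads <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    pos = c(4500L, 4500L, 3999L, 4999L),
    strand = c("-", "+", "-", "-"),
    sample_id = "s1"
  )
  cnt <- count_stranded_reads(reads, intervals)
  # in-window antisense reads count; wrong strand and upstream do not;
  # the half-open end position 4999 still counts
  expect_equal(unname(cnt["prom", "s1"]), 2L)
})

test_that("counting matches the brute-force double loop on random data", {
  fx <- random_read_fixture(4000, 30, seed = 11)
  fast <- count_stranded_reads(fx$reads, fx$intervals, samples = fx$samples)
  expect_identical(fast, brute_count(fx$reads, fx$intervals, fx$samples))
})

test_that("counting is invariant to read and interval order", {
  fx <- random_read_fixture(2000, 20, seed = 12)
  base <- count_stranded_reads(fx$reads, fx$intervals, samples = fx$samples)
  set.seed(1)
  shuf_reads <- fx$reads[sample.int(nrow(fx$reads)), ]
  perm <- sample.int(nrow(fx$intervals))
  shuf <- count_stranded_reads(shuf_reads, fx$intervals[perm, ],
                               samples = fx$samples)
  expect_identical(shuf[fx$intervals$id, ], base)
})

test_that("reads on unknown chromosomes are skipped with a warning", {
  fx <- random_read_fixture(100, 5, seed = 13)
  reads <- dplyr::bind_rows(
    fx$reads,
    tibble::tibble(chrom = "chrUn", pos = 10L, strand = "+",
                   sample_id = "s1"))
  expect_warning(
    cnt <- count_stranded_reads(reads, fx$intervals, samples = fx$samples,
                                known_chroms = c("chr1", "chr2")),
    "unknown chromosome")
  expect_identical(cnt, count_stranded_reads(fx$reads, fx$intervals,
                                             samples = fx$samples))
})

test_that("compute_rpkm matches its closed form and validates input", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 500, 2e6), 0)
  set.seed(3)
  count <- rpois(50, 100); len <- sample(100:5000, 50); tot <- 10^runif(50, 4, 7)
  expect_equal(compute_rpkm(count, len, tot),
               count / ((len / 1000) * (tot / 1e6)))
  # doubling counts and library size leaves RPKM unchanged
  expect_equal(compute_rpkm(2 * count, len, 2 * tot),
               compute_rpkm(count, len, tot))
  expect_error(compute_rpkm(1, 1000, 0), "total")
})

test_that("strandedness_qc hits the exact endpoints", {
  genes <- toy_genes()
  set.seed(5)
  n <- 500
  gi <- sample.int(3, n, TRUE)
  reads <- tibble::tibble(
    chrom = genes$chrom[gi],
    pos = genes$start[gi] +
      floor(runif(n) * (genes$end[gi] - genes$start[gi])),
    strand = genes$strand[gi],
    sample_id = "s1"
  )
  expect_equal(strandedness_qc(reads, genes)$fraction, 1.0)
  flipped <- dplyr::mutate(reads, strand = ifelse(strand == "+", "-", "+"))
  expect_equal(strandedness_qc(flipped, genes)$fraction, 0.0)
  outside <- dplyr::mutate(reads, pos = 15000L)
  expect_error(strandedness_qc(outside, genes), "no reads")
})

test_that("replicate correlation detects perfect and inverted replicates", {
  set.seed(20)
  v <- runif(20, 0, 8)
  rpkm <- cbind(a_r1 = 2^v - 1, a_r2 = 2^v - 1, a_r3 = 2^(8 - v) - 1)
  rownames(rpkm) <- sprintf("g%02d", 1:20)
  expr <- toy_expr(rpkm, kind = rep("mRNA", 20),
                   gene_id = sprintf("g%02d", 1:20),
                   stages = c("a", "a", "a"))
  r <- replicate_correlation(expr, "a")
  expect_equal(unname(r["a_r1", "a_r2"]), 1.0)
  expect_equal(unname(r["a_r1", "a_r3"]), -1.0)
  expect_equal(unname(diag(r)), rep(1, 3))
})

test_that("zero-variance replicates give NA correlations with a warning", {
  rpkm <- cbind(a_r1 = runif(10), a_r2 = rep(2, 10))
  rownames(rpkm) <- sprintf("g%02d", 1:10)
  expr <- toy_expr(rpkm, kind = rep("mRNA", 10), gene_id = rownames(rpkm),
                   stages = c("a", "a"))
  expect_warning(r <- replicate_correlation(expr, "a"), "zero-variance")
  expect_true(is.na(r["a_r1", "a_r2"]))
  expect_equal(unname(diag(r)), c(1, 1))
})

test_that("NB replicates from identical means correlate above 0.9", {
  set.seed(21)
  # log-normal means with the wide spread typical of expression data
  mu <- rlnorm(2000, log(50), 1.5)
  rpkm <- cbind(a_r1 = rnbinom(2000, mu = mu, size = 10),
                a_r2 = rnbinom(2000, mu = mu, size = 10))
  rownames(rpkm) <- sprintf("g%04d", 1:2000)
  expr <- toy_expr(rpkm, kind = rep("mRNA", 2000), gene_id = rownames(rpkm),
                   stages = c("a", "a"))
  expect_gt(replicate_correlation(expr, "a")["a_r1", "a_r2"], 0.9)
})

test_that("quantify_pairs counts promoter antisense and span sense reads", {
  genes <- toy_genes()[1, ]   # gA: + strand, span [5000,7000), tss 5000
  prom <- define_promoters(genes, toy_chrom_sizes)
  mk_reads <- function(n, lo, hi, strand) {
    tibble::tibble(chrom = "chr1",
                   pos = as.integer(seq(lo, hi, length.out = n)),
                   strand = strand, sample_id = "s1")
  }
  reads <- dplyr::bind_rows(
    mk_reads(5, 4100, 4900, "-"),    # pancRNA (antisense promoter)
    mk_reads(20, 5100, 6900, "+"),   # mRNA (sense span)
    mk_reads(975, 12000, 19000, "+") # elsewhere: pads the library to 1000
  )
  sheet <- tibble::tibble(sample_id = "s1", stage = "MII", replicate = 1L)
  expr <- quantify_pairs(reads, prom, genes, sheet)
  expect_equal(unname(expr$counts["panc_gA", "s1"]), 5L)
  expect_equal(unname(expr$counts["mrna_gA", "s1"]), 20L)
  expect_equal(expr$samples$total_reads, 1000L)
  # RPKM: count / (len_kb * total_millions)
  expect_equal(unname(expr$rpkm["panc_gA", "s1"]), 5 / (1 * 0.001))
  expect_equal(unname(expr$rpkm["mrna_gA", "s1"]), 20 / (2 * 0.001))
})

test_that("excluded promoters yield no pancRNA feature", {
  genes <- dplyr::bind_rows(
    toy_genes(),
    tibble::tibble(gene_id = "gD", chrom = "chr1", strand = "+",
                   start = 7999L, end = 8200L, tss = 7999L, exon_len = 201L)
  )
  prom <- define_promoters(genes, toy_chrom_sizes)
  reads <- tibble::tibble(chrom = "chr1", pos = 5500L, strand = "+",
                          sample_id = "s1")
  sheet <- tibble::tibble(sample_id = "s1", stage = "MII", replicate = 1L)
  expr <- quantify_pairs(reads, prom, genes, sheet)
  expect_false("panc_gD" %in% expr$features$feature_id)
  expect_true("mrna_gD" %in% expr$features$feature_id)
  expect_error(
    quantify_pairs(dplyr::mutate(reads, sample_id = "sX"), prom, genes,
                   sheet),
    "absent from sample sheet")
})

test_that("quantify_pairs equals counting and RPKM composed by hand", {
  cfg <- tiny_config(seed = 31)
  sim <- simulate_all(cfg)
  genes <- sim$genes[, c("gene_id", "chrom", "strand", "start", "end",
                         "tss", "exon_len")]
  prom <- define_promoters(genes, sim$chrom_sizes)
  sheet <- sim$sample_sheet[, c("sample_id", "stage", "replicate")]
  expr <- quantify_pairs(sim$reads, prom, genes, sheet)

  kept <- prom[!prom$excluded, ]
  intervals <- tibble::tibble(
    id = c(paste0("panc_", kept$gene_id), paste0("mrna_", genes$gene_id)),
    chrom = c(kept$chrom, genes$chrom),
    start = c(kept$start, genes$start),
    end = c(kept$end, genes$end),
    strand = c(kept$panc_strand, genes$strand)
  )
  cnt <- count_stranded_reads(sim$reads, intervals,
                              samples = sort(unique(sim$reads$sample_id)))
  expect_identical(expr$counts, cnt[expr$features$feature_id, ])
  totals <- table(sim$reads$sample_id)[colnames(cnt)]
  len <- c(kept$end - kept$start, genes$exon_len)
  ref_rpkm <- compute_rpkm(
    cnt, matrix(len, nrow(cnt), ncol(cnt)),
    matrix(as.numeric(totals), nrow(cnt), ncol(cnt), byrow = TRUE))
  expect_equal(expr$rpkm, ref_rpkm[expr$features$feature_id, ])
})
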