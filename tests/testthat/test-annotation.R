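write_gtf_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("parse_gene_models converts GTF coordinates and derives the TSS", {
  gtf <- write_gtf_lines(c(
    'chr1\tsrc\texon\t1001\t1400\t.\t+\t.\tgene_id "gp";',
    'chr1\tsrc\texon\t1601\t2000\t.\t+\t.\tgene_id "gp";',
    'chr1\tsrc\texon\t1001\t2000\t.\t-\t.\tgene_id "gm";'
  ))
  g <- parse_gene_models(gtf)
  gp <- g[g$gene_id == "gp", ]
  expect_equal(gp$start, 1000L)   # 1-based inclusive -> 0-based half-open
  expect_equal(gp$end, 2000L)
  expect_equal(gp$tss, 1000L)
  expect_equal(gp$exon_len, 800L) # union of the two exons
  gm <- g[g$gene_id == "gm", ]
  expect_equal(gm$tss, 1999L)     # minus strand: TSS at the right edge
  expect_equal(gm$exon_len, 1000L)
})

test_that("parse_gene_models merges overlapping exons in the union length", {
  gtf <- write_gtf_lines(c(
    'chr1\tsrc\texon\t101\t300\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t201\t400\t.\t+\t.\tgene_id "g1";'
  ))
  expect_equal(parse_gene_models(gtf)$exon_len, 300L)
})

test_that("parse_gene_models handles empty input and bad lines", {
  empty <- write_gtf_lines("# just a comment")
  expect_equal(nrow(parse_gene_models(empty)), 0)
  bad <- write_gtf_lines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1";',
    "chr1 not a gtf line"
  ))
  expect_error(parse_gene_models(bad), "line 2")
})

test_that("define_promoters places strand-aware windows", {
  genes <- toy_genes()
  prom <- define_promoters(genes, toy_chrom_sizes)
  a <- prom[prom$gene_id == "gA", ]
  expect_equal(c(a$start, a$end), c(4000L, 5000L))
  expect_equal(a$panc_strand, "-")
  expect_false(a$excluded)
  b <- prom[prom$gene_id == "gB", ]   # minus strand: window right of TSS
  expect_equal(c(b$start, b$end), c(10000L, 11000L))
  expect_equal(b$panc_strand, "+")
  expect_true(all(prom$end - prom$start == 1000L))
})

test_that("promoters overlapping another gene span are excluded", {
  genes <- dplyr::bind_rows(
    toy_genes(),
    tibble::tibble(gene_id = "gD", chrom = "chr1", strand = "+",
                   start = 7999L, end = 8200L, tss = 7999L, exon_len = 201L)
  )
  # gD promoter is [6999, 7999): overlaps gA's span [5000,7000) by 1 bp
  prom <- define_promoters(genes, toy_chrom_sizes)
  d <- prom[prom$gene_id == "gD", ]
  expect_true(d$excluded)
  expect_equal(d$reason, "overlaps_gene")
  # ... and gA in turn is not excluded (gD's span starts at 7999)
  expect_false(prom$excluded[prom$gene_id == "gA"])
})

test_that("promoters that do not fit the chromosome are excluded", {
  genes <- tibble::tibble(gene_id = "gE", chrom = "chr1", strand = "+",
                          start = 500L, end = 1500L, tss = 500L,
                          exon_len = 1000L)
  prom <- define_promoters(genes, toy_chrom_sizes)
  expect_true(prom$excluded)
  expect_equal(prom$reason, "out_of_bounds")
})

test_that("non-excluded promoters never overlap another gene span", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    start <- sort(sample.int(60000L, n))
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
      strand = sample(c("+", "-"), n, TRUE),
      start = start, end = start + sample(200:3000, n, TRUE)
    )
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    genes$exon_len <- genes$end - genes$start
    prom <- define_promoters(genes, c(chr1 = 80000L))
    for (i in which(!prom$excluded)) {
      others <- genes$gene_id != prom$gene_id[i]
      expect_false(any(prom$start[i] < genes$end[others] &
                         genes$start[others] < prom$end[i]))
    }
  }
})

test_that("define_promoters is symmetric under genome reflection", {
  genes <- toy_genes()
  L <- 20000L
  reflected <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    strand = ifelse(genes$strand == "+", "-", "+"),
    start = L - genes$end, end = L - genes$start,
    exon_len = genes$exon_len
  )
  reflected$tss <- ifelse(reflected$strand == "+", reflected$start,
                          reflected$end - 1L)
  p1 <- define_promoters(genes, toy_chrom_sizes)
  p2 <- define_promoters(reflected, toy_chrom_sizes)
  expect_equal(p2$start, L - p1$end)
  expect_equal(p2$end, L - p1$start)
  expect_equal(p2$panc_strand, ifelse(p1$panc_strand == "+", "-", "+"))
  expect_equal(p2$excluded, p1$excluded)
})

test_that("motif_windows mirrors orientation and truncates short bodies", {
  genes <- toy_genes()
  w <- motif_windows(genes)
  a <- w[w$gene_id == "gA", ]   # + gene, tss 5000
  expect_equal(c(a$prom_start, a$prom_end), c(4500L, 5000L))
  expect_equal(c(a$body_start, a$body_end), c(5000L, 5500L))
  b <- w[w$gene_id == "gB", ]   # - gene, tss 9999, span [9000,10000)
  expect_equal(c(b$prom_start, b$prom_end), c(10000L, 10500L))
  expect_equal(c(b$body_start, b$body_end), c(9500L, 10000L))
  cc <- w[w$gene_id == "gC", ]  # 300 bp span -> truncated body
  expect_true(cc$body_truncated)
  expect_equal(cc$body_end - cc$body_start, 300L)
})

test_that("detect_cpg_islands matches the hand-computed CG-repeat case", {
  isl <- detect_cpg_islands(strrep("CG", 125))
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 0L)
  expect_equal(isl$end, 250L)
  expect_equal(isl$gc_fraction, 1.0)
  expect_equal(isl$obs_exp_cpg, 2.0)  # 125 * 250 / (125 * 125)
})

test_that("detect_cpg_islands rejects AT-rich and sub-threshold sequence", {
  expect_equal(nrow(detect_cpg_islands(strrep("AT", 125))), 0)
  # GC fraction 0.49 throughout: 98 GC in every 200-bp window
  block <- paste0(strrep("CG", 49), strrep("AT", 51))
  expect_equal(nrow(detect_cpg_islands(strrep(block, 3))), 0)
  expect_equal(nrow(detect_cpg_islands("CGCG")), 0)  # shorter than min_len
})

test_that("N bases break CpG islands", {
  seq <- paste0(strrep("CG", 125), "N", strrep("CG", 125))
  isl <- detect_cpg_islands(seq)
  expect_equal(nrow(isl), 2)
  expect_true(all(isl$length == 250))
})

test_that("island detection mirrors under reverse complement", {
  set.seed(7)
  for (rep in 1:3) {
    seq <- paste0(
      paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""),
      strrep("CG", 150),
      paste(sample(c("A", "T"), 300, TRUE), collapse = "")
    )
    fwd <- detect_cpg_islands(seq)
    rev <- detect_cpg_islands(revcomp(seq))
    n <- nchar(seq)
    expect_equal(rev$start, rev(n - fwd$end))
    expect_equal(rev$end, rev(n - fwd$start))
    expect_equal(rev$gc_fraction, rev(fwd$gc_fraction))
    expect_equal(rev$obs_exp_cpg, rev(fwd$obs_exp_cpg))
  }
})

test_that("classify_promoter_cpgi uses half-open 1 bp overlap", {
  prom <- tibble::tibble(gene_id = "g", chrom = "chr1",
                         start = 4000L, end = 5000L)
  inside <- tibble::tibble(chrom = "chr1", start = 4100L, end = 4400L)
  adjacent <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5200L)
  expect_true(classify_promoter_cpgi(prom, inside))
  expect_false(classify_promoter_cpgi(prom, adjacent))
  expect_false(classify_promoter_cpgi(prom, inside[0, ]))
})
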