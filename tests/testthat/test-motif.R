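test_that("build_pwm produces the stated column probabilities", {
  one_hot <- build_pwm("ACGT", pseudocount = 0)
  expect_equal(unname(one_hot["A", 1]), 1)
  expect_equal(unname(one_hot["T", 4]), 1)
  expect_equal(sum(one_hot == 1), 4)

  p <- build_pwm(c("AA", "AA"), pseudocount = 0.5)
  expect_equal(unname(p["A", ]), c(0.625, 0.625))  # (2 + .5) / (2 + 2)
  expect_equal(unname(p["C", ]), c(0.125, 0.125))

  set.seed(51)
  sites <- replicate(5, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                              collapse = ""))
  expect_equal(unname(colSums(build_pwm(sites))), rep(1, 12))
  expect_error(build_pwm(c("AA", "AAA")), "same length")
  expect_error(build_pwm("ANA"), "A, C, G, T")
})

test_that("JASPAR round trip preserves the matrix", {
  pwm <- build_pwm(rep("CTCTCTCC", 10))
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwm, path, name = "ct")
  back <- read_jaspar(path)
  expect_equal(unclass(back), unclass(pwm), ignore_attr = TRUE)
  expect_equal(pwm_consensus(back), "CTCTCTCC")
})

test_that("scan_pwm finds the consensus at identity 1 on both strands", {
  pwm <- build_pwm(rep("CTCTCTCC", 10))
  seq <- paste0("AAAAA", "CTCTCTCC", "AAAAA")
  hits <- scan_pwm(seq, pwm)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, 5L)
  expect_equal(fwd$identity, 1.0)

  rc_seq <- paste0("TTTT", revcomp("CTCTCTCC"), "TTTT")
  rev <- scan_pwm(rc_seq, pwm)
  expect_equal(rev$strand, "-")
  expect_equal(rev$start, 4L)
  expect_equal(rev$identity, 1.0)
})

test_that("scan_pwm matches brute-force per-window rescoring", {
  set.seed(52)
  pwm <- build_pwm(c("CTCTCTCC", "CTCTCTCC", "CTCTGTCC", "CTATCTCC"))
  seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  # use a low threshold so plenty of windows qualify
  got <- scan_pwm(seq, pwm, min_identity = 0.5)

  logp <- log2(unclass(pwm))
  w <- ncol(pwm)
  s_min <- sum(apply(logp, 2, min))
  s_max <- sum(apply(logp, 2, max))
  score_one <- function(s) {
    b <- strsplit(s, "")[[1]]
    sum(vapply(seq_len(w), function(j) logp[b[j], j], numeric(1)))
  }
  ref <- list()
  for (i in 0:(nchar(seq) - w)) {
    win <- substr(seq, i + 1, i + w)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") win else revcomp(win)
      idy <- (score_one(s) - s_min) / (s_max - s_min)
      if (idy >= 0.5 - 1e-9) {
        ref[[length(ref) + 1]] <- tibble::tibble(
          start = i, strand = strand, identity = idy)
      }
    }
  }
  ref <- dplyr::arrange(dplyr::bind_rows(ref), start, strand)
  expect_equal(got$start, ref$start)
  expect_equal(got$strand, ref$strand)
  expect_equal(got$identity, ref$identity, tolerance = 1e-12)
})

test_that("scan_pwm skips windows containing N", {
  pwm <- build_pwm(rep("CCCC", 5))
  hits <- scan_pwm("CCNCCCCC", pwm, min_identity = 0)
  # windows at 0,1,2 contain the N and are dropped (both strands)
  expect_true(all(hits$start >= 3))
  expect_equal(sum(hits$strand == "+"), 2)
})

test_that("hits mirror under reverse complement", {
  set.seed(53)
  pwm <- build_pwm(c("CTCTCTCC", "CTCTCTCT"))
  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  fwd <- scan_pwm(seq, pwm, min_identity = 0.6)
  rev <- scan_pwm(revcomp(seq), pwm, min_identity = 0.6)
  n <- nchar(seq)
  w <- ncol(pwm)
  mirrored <- dplyr::arrange(tibble::tibble(
    start = n - fwd$start - w,
    strand = ifelse(fwd$strand == "+", "-", "+"),
    identity = fwd$identity
  ), start, strand)
  expect_equal(rev$start, mirrored$start)
  expect_equal(rev$strand, mirrored$strand)
  expect_equal(rev$identity, mirrored$identity, tolerance = 1e-12)
})

test_that("identity is invariant to a constant added to all log scores", {
  # multiplying all probabilities by a constant shifts every log score
  # equally and cancels in the min-max normalization
  pwm <- build_pwm(c("CTCTCTCC", "CTCTGTCC"))
  scaled <- unclass(pwm) * 0.5
  pwm2 <- structure(scaled, class = c("pwm", "matrix"),
                    counts = attr(pwm, "counts"), pseudocount = 0.5)
  seq <- paste0("GG", "CTCTCTCC", "AATTCCGG")
  h1 <- scan_pwm(seq, pwm, min_identity = 0.3)
  h2 <- scan_pwm(seq, pwm2, min_identity = 0.3)
  expect_equal(h1$identity, h2$identity, tolerance = 1e-12)
})

test_that("region_strand_profile recovers a planted asymmetric signal", {
  set.seed(54)
  n <- 40
  L <- 3000L
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), n * L, TRUE),
                           collapse = ""))
  start <- (seq_len(n) - 1L) * L + 1200L
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
    strand = sample(c("+", "-"), n, TRUE),
    start = start, end = start + 1000L
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$exon_len <- 1000L
  consensus <- "CTCTCTCC"
  pwm <- build_pwm(rep(consensus, 10))
  planted <- rep(c(TRUE, FALSE), length.out = n)  # 50% promoter-sense
  win <- motif_windows(genes)
  for (i in which(planted)) {
    pos <- win$prom_start[i] + 100L
    text <- if (genes$strand[i] == "+") consensus else revcomp(consensus)
    substr(genome[["chr1"]], pos + 1L, pos + nchar(consensus)) <- text
  }
  prof <- region_strand_profile(genes, genome, pwm)
  fr <- prof$fractions
  ps <- fr$fraction[fr$category == "promoter_sense"]
  expect_gt(ps, 0.35)
  expect_lt(ps, 0.65)
  expect_lt(max(fr$fraction[fr$category != "promoter_sense"]), 0.15)
  expect_error(region_strand_profile(genes[0, ], genome, pwm), "empty")
})

test_that("motif-CpGi association recovers planting confined to CpGi", {
  set.seed(55)
  n <- 30
  L <- 4000L
  # CpG-depleted background so detected islands are the planted ones
  genome <- simulate_genome(sim_config(seed = 55, n_chrom = 1,
                                       chrom_length = n * L,
                                       n_genes = 1))$genome
  names(genome) <- "chr1"
  start <- (seq_len(n) - 1L) * L + 1500L
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1", strand = "+",
    start = start, end = start + 800L
  )
  genes$tss <- genes$start
  genes$exon_len <- 800L
  prom <- define_promoters(genes, c(chr1 = n * L))
  cpgi <- rep(c(TRUE, FALSE), length.out = n)
  consensus <- "CTCTCTCC"
  for (i in which(cpgi)) {
    s <- genes$tss[i] - 400L
    substr(genome[["chr1"]], s + 1L, s + 250L) <- strrep("CG", 125)
    substr(genome[["chr1"]], s - 50L, s - 50L + nchar(consensus) - 1L) <-
      consensus
  }
  pwm <- build_pwm(rep(consensus, 10))
  islands <- detect_cpg_islands_genome(genome)
  assoc <- motif_cpgi_association(genes, prom, genome, pwm, islands)
  fr <- assoc$fractions
  expect_gt(fr$frac_with_motif[fr$class == "CpGi"], 0.8)
  expect_lt(fr$frac_with_motif[fr$class == "non_CpGi"], 0.3)
  # degenerate class: every promoter CpGi-type
  all_cpgi <- motif_cpgi_association(
    genes[cpgi, ], prom[cpgi, ], genome, pwm, islands)
  expect_true(is.na(
    all_cpgi$fractions$frac_with_motif[all_cpgi$fractions$class ==
                                         "non_CpGi"]))
})

test_that("motif search set applies the fold threshold and orientation", {
  genome <- c(chr1 = strrep("A", 3000))
  substr(genome[["chr1"]], 801, 1000) <- strrep("C", 200)  # [800,1000)
  genes <- tibble::tibble(
    gene_id = c("gup", "glow", "gneg"), chrom = "chr1",
    strand = c("+", "+", "-"),
    start = c(1000L, 1000L, 500L), end = c(1500L, 1500L, 1000L),
    tss = c(1000L, 1000L, 999L), exon_len = 500L
  )
  panc <- cbind(MII = c(0, 5, 0), `2cell` = c(20, 49, 20))
  mrna <- panc * 0 + 5
  rownames(panc) <- rownames(mrna) <- genes$gene_id
  expr <- pair_expr(panc, mrna, c("MII", "2cell"))
  res <- select_motif_search_set(expr, genes, genome, min_fold = 10)
  # gup: (20.5 / 0.5) = 41-fold, selected; glow: (49.5 / 5.5) = 9-fold, out
  expect_setequal(res$gene_id, c("gup", "gneg"))
  expect_true(all(nchar(res$seq) == 200))
  expect_equal(res$seq[res$gene_id == "gup"], strrep("C", 200))
  # minus-strand gene reads the downstream window reverse-complemented:
  # genomic [1000,1200) is all A, so the oriented sequence is all T
  expect_equal(res$seq[res$gene_id == "gneg"], strrep("T", 200))
})
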