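stage_prob <- function(probs, stage, default = 0.5) {
  if (stage %in% names(probs)) unname(probs[[stage]]) else default
}

#' Simulate the expression truth table
#'
#' Expression is bimodal per stage: a feature is either silent (exactly 0
#' RPKM) or "on" with a lognormal level, emulating the on/off structure of
#' zygotic gene activation. Partnered genes draw their pancRNA on/off state
#' per stage; mRNA levels of partnered genes are tied to the partner pancRNA
#' level on the log scale (slope `panc_mrna_beta`), planting the positive
#' pancRNA-level/mRNA-level association. For pairs expressed at both of the
#' first two stages, the (pancRNA, mRNA) log2 fold changes are drawn from a
#' bivariate normal with correlation `lfc_cor` (planted coordination).
#' Finally, true RPKMs are rescaled per stage so that
#' `sum(rpkm * length_kb) = 1e6`, i.e. the truth is self-consistent with the
#' library size and measured RPKM converges to it.
#'
#' @param config [sim_config()].
#' @param genes generator gene table from [simulate_annotation()].
#' @return tibble with one row per gene: flags (`partnered`, `is_decoy`,
#'   `promoter_excluded`, `cpgi`), per-stage `panc_on_*` / `mrna_on_*` and
#'   true `panc_rpkm_*` / `mrna_rpkm_*`, and the planted `true_lfc_panc` /
#'   `true_lfc_mrna` between the first two stages (NA when a side is silent
#'   at either stage).
#' @export
simulate_expression <- function(config, genes) {
  set.seed(derive_seed(config$seed, 505L))
  n <- nrow(genes)
  stages <- config$stages
  s_from <- stages[1]
  s_to <- if (length(stages) >= 2) stages[2] else stages[1]

  panc_on <- sapply(stages, function(s) {
    genes$partnered & stats::runif(n) < stage_prob(config$panc_on_prob, s)
  })
  mrna_on <- sapply(stages, function(s) {
    p <- ifelse(genes$partnered & s == "2cell",
                config$mrna_on_prob_partnered_2cell, config$mrna_on_prob)
    stats::runif(n) < p
  })
  colnames(panc_on) <- colnames(mrna_on) <- stages

  # planted (pancRNA, mRNA) log2 fold-change pairs, correlation lfc_cor
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- config$lfc_cor
  lfc_p <- config$lfc_mean[["panc"]] + config$lfc_sd[["panc"]] * z1
  lfc_m <- config$lfc_mean[["mrna"]] +
    config$lfc_sd[["mrna"]] * (rho * z1 + sqrt(1 - rho^2) * z2)

  panc_lv <- matrix(0, n, length(stages), dimnames = list(NULL, stages))
  mrna_lv <- matrix(0, n, length(stages), dimnames = list(NULL, stages))

  ln_panc_from <- exp(config$panc_meanlog +
                        config$panc_sdlog * stats::rnorm(n))
  panc_lv[, s_from] <- ifelse(panc_on[, s_from], ln_panc_from, 0)
  fresh_to <- exp(config$panc_meanlog + log(2) +
                    config$panc_sdlog * stats::rnorm(n))
  panc_lv[, s_to] <- ifelse(
    panc_on[, s_to],
    ifelse(panc_on[, s_from], ln_panc_from * 2^lfc_p, fresh_to), 0)
  for (s in setdiff(stages, c(s_from, s_to))) {
    panc_lv[, s] <- ifelse(
      panc_on[, s],
      exp(config$panc_meanlog + config$panc_sdlog * stats::rnorm(n)), 0)
  }

  # mRNA base level tied to the partner pancRNA level (group C > A planting)
  panc_ref <- ifelse(panc_on[, s_to], log(pmax(panc_lv[, s_to], 1e-12)),
                     config$panc_meanlog)
  base_ln <- config$mrna_meanlog +
    ifelse(genes$partnered, config$panc_mrna_beta, 0) *
      (panc_ref - config$panc_meanlog)

  mrna_from <- exp(base_ln + config$mrna_sdlog * stats::rnorm(n))
  mrna_lv[, s_from] <- ifelse(mrna_on[, s_from], mrna_from, 0)
  fresh_m <- exp(base_ln + log(2) + config$mrna_sdlog * stats::rnorm(n))
  mrna_lv[, s_to] <- ifelse(
    mrna_on[, s_to],
    ifelse(mrna_on[, s_from], mrna_from * 2^lfc_m, fresh_m), 0)
  for (s in setdiff(stages, c(s_from, s_to))) {
    mrna_lv[, s] <- ifelse(
      mrna_on[, s],
      exp(base_ln + config$mrna_sdlog * stats::rnorm(n)), 0)
  }

  # per-stage rescale: sum(rpkm * length_kb) over read-generating features
  # equals 1e6, so the nominal depth is the realized library size
  panc_len_kb <- config$promoter_len / 1000
  mrna_len_kb <- genes$exon_len / 1000
  for (s in stages) {
    mass <- sum(mrna_lv[, s] * mrna_len_kb) + sum(panc_lv[, s] * panc_len_kb)
    if (mass <= 0) stop("no expressed feature at stage ", s)
    panc_lv[, s] <- panc_lv[, s] * 1e6 / mass
    mrna_lv[, s] <- mrna_lv[, s] * 1e6 / mass
  }

  truth <- genes[, c("gene_id", "chrom", "strand", "is_decoy", "partnered",
                     "promoter_excluded", "cpgi", "exon_len")]
  for (s in stages) {
    truth[[paste0("panc_on_", s)]] <- panc_on[, s]
    truth[[paste0("mrna_on_", s)]] <- mrna_on[, s]
    truth[[paste0("panc_rpkm_", s)]] <- panc_lv[, s]
    truth[[paste0("mrna_rpkm_", s)]] <- mrna_lv[, s]
  }
  # true fold changes on the final (library-consistent RPKM) scale; the
  # per-stage rescale adds the same constant to every gene's log2 fold
  # change, so the planted correlation is untouched
  both_p <- panc_on[, s_from] & panc_on[, s_to]
  both_m <- mrna_on[, s_from] & mrna_on[, s_to]
  truth$true_lfc_panc <- ifelse(both_p,
                                log2(panc_lv[, s_to] / panc_lv[, s_from]),
                                NA_real_)
  truth$true_lfc_mrna <- ifelse(both_m,
                                log2(mrna_lv[, s_to] / mrna_lv[, s_from]),
                                NA_real_)
  truth
}

#' Simulate negative-binomial counts from the expression truth
#'
#' Per feature and replicate, `count ~ NB(mu, dispersion)` with
#' `mu = true_rpkm * length_kb * depth / 1e6` and
#' `var = mu + dispersion * mu^2`; dispersion 0 gives deterministic
#' `round(mu)`. pancRNA features exist for every partnered gene (promoter
#' exclusion is an analysis-side decision; the transcript is still made),
#' mRNA features for every gene.
#'
#' @param config [sim_config()].
#' @param genes generator gene table.
#' @param truth tibble from [simulate_expression()].
#' @param seed optional seed; by default the current RNG state is used (the
#'   read simulator seeds once for the whole stage).
#' @return list with `features` (feature_id, kind, gene_id, chrom, start,
#'   end, strand, length_bp), `sample_sheet` and `counts` matrix.
#' @export
simulate_counts <- function(config, genes, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_ix <- which(genes$partnered)
  features <- tibble::tibble(
    feature_id = c(paste0("panc_", genes$gene_id[p_ix]),
                   paste0("mrna_", genes$gene_id)),
    kind = rep(c("pancRNA", "mRNA"), c(length(p_ix), nrow(genes))),
    gene_id = c(genes$gene_id[p_ix], genes$gene_id),
    chrom = c(genes$chrom[p_ix], genes$chrom),
    start = c(genes$promoter_start[p_ix], genes$start),
    end = c(genes$promoter_end[p_ix], genes$end),
    strand = c(genes$panc_strand[p_ix], genes$strand),
    length_bp = c(rep(config$promoter_len, length(p_ix)), genes$exon_len)
  )
  sample_sheet <- tibble::tibble(
    stage = rep(config$stages, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(config$stages))
  )
  sample_sheet$sample_id <- paste0(sample_sheet$stage, "_r",
                                   sample_sheet$replicate)

  rpkm_col <- function(kind, stage) {
    v <- truth[[paste0(ifelse(kind == "pancRNA", "panc", "mrna"),
                       "_rpkm_", stage)]]
    v[match(features$gene_id, truth$gene_id)]
  }
  counts <- matrix(0L, nrow(features), nrow(sample_sheet),
                   dimnames = list(features$feature_id,
                                   sample_sheet$sample_id))
  for (j in seq_len(nrow(sample_sheet))) {
    stage <- sample_sheet$stage[j]
    rpkm <- ifelse(features$kind == "pancRNA",
                   rpkm_col("pancRNA", stage), rpkm_col("mRNA", stage))
    mu <- rpkm * (features$length_bp / 1000) * (config$depth / 1e6)
    counts[, j] <- if (config$dispersion == 0) as.integer(round(mu)) else
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  list(features = features, sample_sheet = sample_sheet, counts = counts)
}

#' Simulate stranded 5'-end reads
#'
#' Draws per-feature counts with [simulate_counts()], then places read
#' 5'-end positions uniformly within each feature's interval (promoter
#' window for pancRNAs, gene span for mRNAs) on the feature's strand,
#' flipping each read's reported strand with probability `strand_flip`.
#'
#' @param config [sim_config()].
#' @param genes generator gene table.
#' @param truth tibble from [simulate_expression()].
#' @return list with `reads` (tibble `chrom`, `pos`, `strand`, `sample_id`),
#'   `sample_sheet`, `features` and the `counts` matrix.
#' @export
simulate_reads <- function(config, genes, truth) {
  set.seed(derive_seed(config$seed, 606L))
  cnt <- simulate_counts(config, genes, truth)
  feats <- cnt$features
  out <- vector("list", nrow(cnt$sample_sheet))
  for (j in seq_len(nrow(cnt$sample_sheet))) {
    k <- cnt$counts[, j]
    idx <- rep(seq_len(nrow(feats)), k)
    if (length(idx) == 0) next
    pos <- as.integer(floor(feats$start[idx] +
      stats::runif(length(idx)) * (feats$end[idx] - feats$start[idx])))
    flip <- stats::runif(length(idx)) < config$strand_flip
    strand <- ifelse(flip, opposite_strand(feats$strand[idx]),
                     feats$strand[idx])
    out[[j]] <- tibble::tibble(
      chrom = feats$chrom[idx], pos = pos, strand = strand,
      sample_id = cnt$sample_sheet$sample_id[j]
    )
  }
  reads <- dplyr::bind_rows(out)
  reads <- reads[order(reads$sample_id, reads$chrom, reads$pos), ]
  list(reads = reads, sample_sheet = cnt$sample_sheet,
       features = feats, counts = cnt$counts)
}
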