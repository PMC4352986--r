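#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generator; the seed
#' fully determines all outputs. Defaults emulate a ZGA-like study: three
#' stages (MII oocyte, 2-cell embryo, ESC) with four replicates each,
#' bimodal (on/off) expression with coordinated pancRNA/mRNA 2-cell
#' upregulation, a CT-rich motif planted with strand-asymmetric placement,
#' CpG-island-type promoters enriched among pancRNA-partnered genes, and
#' bimodal bisulfite methylation that drops at the 2-cell stage.
#'
#' @param seed integer seed; determines every random draw.
#' @param n_chrom,chrom_length genome shape (2 x 500 kb default).
#' @param n_genes number of target genes (decoy genes used to exercise the
#'   promoter-exclusion rule are added on top).
#' @param gene_length_range,gap_range gene span lengths and inter-gene gaps
#'   in bp; gaps leave >= 1 kb promoter clearance.
#' @param promoter_len promoter window length (bp).
#' @param frac_panc_partnered fraction of genes with a transcribed pancRNA.
#' @param frac_promoter_excluded fraction of genes whose promoter is made to
#'   overlap a decoy gene, triggering exclusion.
#' @param stages,n_replicates stage names and replicates per stage.
#' @param depth nominal mapped reads per sample.
#' @param dispersion negative-binomial dispersion alpha in
#'   `var = mu + alpha * mu^2`; 0 gives deterministic counts `round(mu)`.
#' @param strand_flip probability that a simulated read reports the wrong
#'   strand.
#' @param panc_on_prob named per-stage probability that a partnered gene's
#'   pancRNA is transcribed at that stage.
#' @param mrna_on_prob baseline per-stage probability that an mRNA is
#'   expressed; `mrna_on_prob_partnered_2cell` overrides it at the 2-cell
#'   stage for partnered genes (co-expression enrichment).
#' @param panc_meanlog,panc_sdlog,mrna_meanlog,mrna_sdlog lognormal
#'   parameters of on-state expression levels (relative units; rescaled to
#'   library-consistent RPKM).
#' @param panc_mrna_beta slope tying mRNA level to partner pancRNA level on
#'   the log2 scale (plants the group C > A effect).
#' @param lfc_mean,lfc_sd,lfc_cor bivariate-normal parameters of the
#'   (pancRNA, mRNA) log2 fold changes MII -> 2-cell for pairs expressed at
#'   both stages; `lfc_cor` is the planted coordination.
#' @param motif_consensus planted CT-rich motif.
#' @param motif_rates_partnered,motif_rates_lacking per-category planting
#'   probabilities (promoter_sense, promoter_antisense, body_sense,
#'   body_antisense) for partnered and pancRNA-lacking genes.
#' @param cpgi_rate_partnered,cpgi_rate_lacking probability of a planted CpG
#'   island in the promoter.
#' @param cpgi_length planted island length (bp).
#' @param meth_stages,meth_levels bisulfite stages and per-stage true
#'   methylation levels.
#' @param n_meth_loci,n_clones,n_cpg,missing_rate bisulfite data shape.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 500000L,
                       n_genes = 400L,
                       gene_length_range = c(600L, 1500L),
                       gap_range = c(1050L, 1300L),
                       promoter_len = 1000L,
                       frac_panc_partnered = 0.6,
                       frac_promoter_excluded = 0.05,
                       stages = c("MII", "2cell", "ESC"),
                       n_replicates = 4L,
                       depth = 200000L,
                       dispersion = 0.1,
                       strand_flip = 0.02,
                       panc_on_prob = c(MII = 0.55, `2cell` = 1.0,
                                        ESC = 0.5),
                       mrna_on_prob = 0.8,
                       mrna_on_prob_partnered_2cell = 0.9,
                       panc_meanlog = log(4), panc_sdlog = 1.0,
                       mrna_meanlog = log(10), mrna_sdlog = 1.0,
                       panc_mrna_beta = 0.5,
                       lfc_mean = c(panc = 1.5, mrna = 1.0),
                       lfc_sd = c(panc = 1.5, mrna = 1.5),
                       lfc_cor = 0.7,
                       motif_consensus = "CTCTCTCC",
                       motif_rates_partnered = c(promoter_sense = 0.6,
                                                 promoter_antisense = 0.05,
                                                 body_sense = 0.05,
                                                 body_antisense = 0.4),
                       motif_rates_lacking = c(promoter_sense = 0.05,
                                               promoter_antisense = 0.3,
                                               body_sense = 0.05,
                                               body_antisense = 0.3),
                       cpgi_rate_partnered = 0.7,
                       cpgi_rate_lacking = 0.3,
                       cpgi_length = 250L,
                       meth_stages = c("MII", "sperm", "1cell", "2cell"),
                       meth_levels = c(MII = 0.85, sperm = 0.8,
                                       `1cell` = 0.75, `2cell` = 0.1),
                       n_meth_loci = 3L,
                       n_clones = 20L,
                       n_cpg = 16L,
                       missing_rate = 0.02) {
  cfg <- as.list(environment())
  rates <- c(cfg$frac_panc_partnered, cfg$frac_promoter_excluded,
             cfg$strand_flip, cfg$panc_on_prob, cfg$mrna_on_prob,
             cfg$mrna_on_prob_partnered_2cell, cfg$motif_rates_partnered,
             cfg$motif_rates_lacking, cfg$cpgi_rate_partnered,
             cfg$cpgi_rate_lacking, cfg$meth_levels, cfg$missing_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (abs(cfg$lfc_cor) > 1) stop("lfc_cor must lie in [-1, 1]")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (!setequal(names(cfg$meth_levels), cfg$meth_stages)) {
    stop("meth_levels must name every meth_stage")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d: %d x %d bp genome, %d genes, stages %s x %d reps, depth %d\n",
    x$seed, x$n_chrom, x$chrom_length, x$n_genes,
    paste(x$stages, collapse = "/"), x$n_replicates, x$depth
  ))
  invisible(x)
}
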