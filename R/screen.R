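#' Call candidate pancRNAs at one stage
#'
#' A gene is a candidate iff its mean pancRNA RPKM across the stage's
#' replicates is at least `min_rpkm`; genes whose promoter was excluded have
#' no pancRNA feature and can never be candidates.
#'
#' @param expr [expr_table()].
#' @param stage stage name.
#' @param min_rpkm expression cutoff in RPKM (default 1).
#' @return list with `stage`, `min_rpkm` and `candidates` (tibble `gene_id`,
#'   `panc_rpkm`, sorted by descending RPKM, ties by `gene_id`).
#' @export
call_panc_candidates <- function(expr, stage, min_rpkm = 1.0) {
  panc <- mean_rpkm(expr, stage, "pancRNA")
  cand <- tibble::tibble(gene_id = names(panc), panc_rpkm = unname(panc)) |>
    dplyr::filter(.data$panc_rpkm >= min_rpkm) |>
    dplyr::arrange(dplyr::desc(.data$panc_rpkm), .data$gene_id)
  list(stage = stage, min_rpkm = min_rpkm, candidates = cand)
}

#' Co-expression status of pancRNA/mRNA pairs
#'
#' Flags each gene that carries a pancRNA feature by whether its pancRNA and
#' its mRNA exceed `expressed_thresh` (mean RPKM across replicates) at the
#' stage; a pair is co-expressed iff both do.
#'
#' @inheritParams call_panc_candidates
#' @param expressed_thresh RPKM above which a feature counts as expressed.
#' @return tibble `gene_id`, `panc_rpkm`, `mrna_rpkm`, `panc_expressed`,
#'   `mrna_expressed`, `coexpressed`.
#' @export
classify_coexpression <- function(expr, stage, expressed_thresh = 0.5) {
  panc <- mean_rpkm(expr, stage, "pancRNA")
  mrna <- mean_rpkm(expr, stage, "mRNA")
  tibble::tibble(
    gene_id = names(panc),
    panc_rpkm = unname(panc),
    mrna_rpkm = unname(mrna[names(panc)]),
    panc_expressed = unname(panc) > expressed_thresh,
    mrna_expressed = unname(mrna[names(panc)]) > expressed_thresh
  ) |>
    dplyr::mutate(coexpressed = .data$panc_expressed & .data$mrna_expressed) |>
    dplyr::arrange(.data$gene_id)
}

#' Group mRNAs by partner pancRNA expression level
#'
#' Group A: expressed mRNAs without an expressed pancRNA. Groups B and C: the
#' mRNAs partnered with the `n` most weakly and most strongly expressed
#' pancRNAs among co-expressed pairs. Ties at the n-th rank are broken by
#' `gene_id` lexical order, so membership is deterministic. One-sided
#' Mann-Whitney tests compare mRNA levels of C vs A and C vs B.
#'
#' @param pairs tibble from [classify_coexpression()] at the same stage.
#' @param expr [expr_table()].
#' @param stage stage name.
#' @param n group size for B and C (default 100); truncated with a warning
#'   when fewer co-expressed pairs exist.
#' @param expressed_thresh RPKM threshold defining "expressed" for group A.
#' @return list with `groups` (tibble `gene_id`, `group`, `panc_rpkm`,
#'   `mrna_rpkm`) and `tests` (tibble `comparison`, `U`, `p`).
#' @export
group_by_panc_level <- function(pairs, expr, stage, n = 100L,
                                expressed_thresh = 0.5) {
  mrna <- mean_rpkm(expr, stage, "mRNA")
  panc_genes_expressed <- pairs$gene_id[pairs$panc_expressed]
  a_ids <- setdiff(names(mrna)[mrna > expressed_thresh], panc_genes_expressed)

  co <- pairs[pairs$coexpressed, , drop = FALSE]
  if (nrow(co) < n) {
    warning("only ", nrow(co), " co-expressed pairs; groups B/C truncated")
    n <- nrow(co)
  }
  b <- co[order(co$panc_rpkm, co$gene_id), ][seq_len(n), , drop = FALSE]
  c_ <- co[order(-co$panc_rpkm, co$gene_id), ][seq_len(n), , drop = FALSE]

  groups <- dplyr::bind_rows(
    tibble::tibble(gene_id = a_ids, group = "A", panc_rpkm = NA_real_,
                   mrna_rpkm = unname(mrna[a_ids])),
    tibble::tibble(gene_id = b$gene_id, group = "B", panc_rpkm = b$panc_rpkm,
                   mrna_rpkm = b$mrna_rpkm),
    tibble::tibble(gene_id = c_$gene_id, group = "C", panc_rpkm = c_$panc_rpkm,
                   mrna_rpkm = c_$mrna_rpkm)
  )
  test_one <- function(x, y, label) {
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(comparison = label, U = NA_real_, p = NA_real_))
    }
    res <- mann_whitney_u(x, y, alternative = "greater")
    tibble::tibble(comparison = label, U = res$U, p = res$p)
  }
  tests <- dplyr::bind_rows(
    test_one(c_$mrna_rpkm, unname(mrna[a_ids]), "C_vs_A"),
    test_one(c_$mrna_rpkm, b$mrna_rpkm, "C_vs_B")
  )
  list(groups = groups, tests = tests)
}

#' Coordination of pancRNA and mRNA fold changes between stages
#'
#' Per pair, `log2fc = log2((RPKM_to + pseudo) / (RPKM_from + pseudo))` for
#' the pancRNA and the mRNA; reports the Pearson correlation across pairs and
#' the number of pairs upregulated on both sides. With `min_fold` set, a
#' filtered summary restricted to pairs whose mRNA fold change is at least
#' `min_fold` is reported alongside.
#'
#' @param pairs tibble with a `gene_id` column (e.g. co-expressed pairs), or
#'   a character vector of gene ids.
#' @param expr [expr_table()].
#' @param stage_from,stage_to stage names.
#' @param pseudo pseudocount in RPKM units (default 0.5) keeping fold changes
#'   finite for silent features.
#' @param min_fold optional mRNA fold-change filter for the secondary
#'   summary.
#' @return list with `per_pair` (tibble `gene_id`, `log2fc_panc`,
#'   `log2fc_mrna`), `r`, `n_pairs`, `n_up_up`, and optionally `filtered`.
#' @export
coordination_stats <- function(pairs, expr, stage_from, stage_to,
                               pseudo = 0.5, min_fold = NULL) {
  ids <- if (is.character(pairs)) pairs else pairs$gene_id
  lfc_of <- function(kind) {
    from <- mean_rpkm(expr, stage_from, kind)[ids]
    to <- mean_rpkm(expr, stage_to, kind)[ids]
    log2((to + pseudo) / (from + pseudo))
  }
  per_pair <- tibble::tibble(
    gene_id = ids,
    log2fc_panc = unname(lfc_of("pancRNA")),
    log2fc_mrna = unname(lfc_of("mRNA"))
  )
  if (any(is.na(per_pair$log2fc_panc))) {
    stop("pair gene(s) without a pancRNA feature: ",
         paste(utils::head(ids[is.na(per_pair$log2fc_panc)], 3),
               collapse = ", "))
  }
  if (nrow(per_pair) < 3) stop("need >= 3 pairs for a correlation")
  out <- list(
    per_pair = per_pair,
    r = stats::cor(per_pair$log2fc_panc, per_pair$log2fc_mrna),
    n_pairs = nrow(per_pair),
    n_up_up = sum(per_pair$log2fc_panc > 0 & per_pair$log2fc_mrna > 0)
  )
  if (!is.null(min_fold)) {
    sel <- per_pair$log2fc_mrna >= log2(min_fold)
    sub <- per_pair[sel, , drop = FALSE]
    out$filtered <- list(
      min_fold = min_fold,
      n_pairs = nrow(sub),
      r = if (nrow(sub) >= 3) stats::cor(sub$log2fc_panc, sub$log2fc_mrna)
          else NA_real_,
      n_up_up = sum(sub$log2fc_panc > 0 & sub$log2fc_mrna > 0)
    )
  }
  out
}

#' Select follow-up pancRNA candidates across stages
#'
#' Keeps pancRNAs silent in MII oocytes (RPKM below `mii_max`) but expressed
#' in 2-cell embryos and ESCs (RPKM above `twocell_min` / `esc_min`), ranked
#' by descending ESC pancRNA RPKM with ties broken by `gene_id`.
#'
#' @param expr [expr_table()].
#' @param mii_max maximal mean RPKM at the MII stage.
#' @param twocell_min,esc_min minimal mean RPKM at the 2-cell and ESC stages.
#' @param stages named character vector mapping roles `mii`, `twocell`, `esc`
#'   to stage names in the table.
#' @return tibble `gene_id`, `mii_rpkm`, `twocell_rpkm`, `esc_rpkm`, ranked.
#' @export
select_followup_candidates <- function(expr, mii_max = 0.5,
                                       twocell_min = 1.0, esc_min = 1.0,
                                       stages = c(mii = "MII",
                                                  twocell = "2cell",
                                                  esc = "ESC")) {
  missing <- setdiff(unname(stages), unique(expr$samples$stage))
  if (length(missing) > 0) {
    stop("stage(s) missing from expression table: ",
         paste(missing, collapse = ", "))
  }
  mii <- mean_rpkm(expr, stages[["mii"]], "pancRNA")
  two <- mean_rpkm(expr, stages[["twocell"]], "pancRNA")
  esc <- mean_rpkm(expr, stages[["esc"]], "pancRNA")
  tibble::tibble(
    gene_id = names(mii),
    mii_rpkm = unname(mii),
    twocell_rpkm = unname(two[names(mii)]),
    esc_rpkm = unname(esc[names(mii)])
  ) |>
    dplyr::filter(.data$mii_rpkm < mii_max,
                  .data$twocell_rpkm > twocell_min,
                  .data$esc_rpkm > esc_min) |>
    dplyr::arrange(dplyr::desc(.data$esc_rpkm), .data$gene_id)
}
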