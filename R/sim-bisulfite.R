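#' Simulate bisulfite subclone data
#'
#' Per locus, stage and clone, each CpG call is M with the stage's true
#' methylation level, independently across CpGs; calls are turned into
#' missing (`.`) with probability `missing_rate`.
#'
#' @param config [sim_config()].
#' @return list with `clones` (tibble `locus_id`, `stage`, `clone_id`,
#'   `calls`) and `truth` (tibble `locus_id`, `stage`, `level`).
#' @export
simulate_bisulfite <- function(config) {
  set.seed(derive_seed(config$seed, 707L))
  loci <- sprintf("locus%02d", seq_len(config$n_meth_loci))
  rows <- list()
  for (locus in loci) {
    for (stage in config$meth_stages) {
      level <- config$meth_levels[[stage]]
      for (cl in seq_len(config$n_clones)) {
        calls <- ifelse(stats::runif(config$n_cpg) < level, "M", "U")
        miss <- stats::runif(config$n_cpg) < config$missing_rate
        calls[miss] <- "."
        rows[[length(rows) + 1]] <- tibble::tibble(
          locus_id = locus, stage = stage,
          clone_id = sprintf("%s_%s_c%02d", locus, stage, cl),
          calls = paste(calls, collapse = "")
        )
      }
    }
  }
  truth <- tidyr_expand_meth(loci, config)
  list(clones = dplyr::bind_rows(rows), truth = truth)
}

tidyr_expand_meth <- function(loci, config) {
  tibble::tibble(
    locus_id = rep(loci, each = length(config$meth_stages)),
    stage = rep(config$meth_stages, length(loci)),
    level = rep(unname(config$meth_levels[config$meth_stages]), length(loci))
  )
}
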