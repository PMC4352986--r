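#' Parse bisulfite subclone records
#'
#' Reads a TSV with columns `locus_id`, `clone_id`, `calls` (and optionally
#' `stage`), where `calls` is a string over M (methylated), U (unmethylated)
#' and `.` (missing), one character per CpG position of the locus. All clones
#' of a locus must have the same length.
#'
#' @param x path to a TSV file, or a data frame with those columns.
#' @return tibble of validated clone records.
#' @export
parse_bisulfite_clones <- function(x) {
  df <- if (is.data.frame(x)) tibble::as_tibble(x) else {
    readr::read_tsv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  need <- c("locus_id", "clone_id", "calls")
  if (!all(need %in% names(df))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop("no clones")
  bad <- grepl("[^MU.]", df$calls)
  if (any(bad)) {
    stop("invalid call characters in clone(s): ",
         paste(utils::head(df$clone_id[bad], 3), collapse = ", "))
  }
  lens <- tapply(nchar(df$calls), df$locus_id, function(v) length(unique(v)))
  if (any(lens > 1)) {
    stop("clone call strings differ in length at locus/loci: ",
         paste(names(lens)[lens > 1], collapse = ", "))
  }
  df
}

#' Methylation profile of a clone set
#'
#' Missing calls are excluded from numerator and denominator everywhere;
#' nothing is imputed.
#'
#' @param calls character vector of clone call strings (M/U/.), all the same
#'   length.
#' @return list with `per_cpg` (methylated fraction per CpG position),
#'   `per_clone` (methylated fraction per clone) and `overall` (methylated
#'   calls / non-missing calls).
#' @export
methylation_level <- function(calls) {
  if (length(calls) == 0) stop("no clones")
  m <- do.call(rbind, strsplit(calls, "", fixed = TRUE))
  is_m <- m == "M"
  obs <- m != "."
  if (!any(obs)) stop("all calls missing")
  per_cpg <- colSums(is_m) / pmax(colSums(obs), 1L)
  per_cpg[colSums(obs) == 0] <- NA_real_
  per_clone <- rowSums(is_m) / pmax(rowSums(obs), 1L)
  per_clone[rowSums(obs) == 0] <- NA_real_
  list(per_cpg = per_cpg, per_clone = per_clone,
       overall = sum(is_m) / sum(obs))
}

#' Summarise methylation by locus (and stage)
#'
#' @param clones tibble from [parse_bisulfite_clones()].
#' @return tibble with one row per locus (x stage when present): `n_clones`,
#'   `n_cpg`, `overall` methylated fraction.
#' @export
methylation_summary <- function(clones) {
  keys <- intersect(c("locus_id", "stage"), names(clones))
  clones |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      n_cpg = nchar(.data$calls[1]),
      overall = methylation_level(.data$calls)$overall,
      .groups = "drop"
    )
}

#' Text lollipop rendering of bisulfite clones
#'
#' One line per clone: filled circles for methylated, open circles for
#' unmethylated, a middle dot for missing calls.
#'
#' @param calls character vector of clone call strings.
#' @return character vector of rendered lines.
#' @export
render_lollipop <- function(calls) {
  vapply(calls, function(s) {
    chartr("MU.", "●○·", s)
  }, character(1), USE.NAMES = FALSE)
}
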