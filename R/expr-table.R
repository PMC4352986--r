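#' Expression table container
#'
#' Holds raw counts and RPKM for pancRNA and mRNA features across samples.
#' Every pancRNA feature has a cognate mRNA feature with the same `gene_id`;
#' pancRNA features exist only for genes whose promoter passed the exclusion
#' rules.
#'
#' @param features tibble with `feature_id`, `kind` ("pancRNA"/"mRNA"),
#'   `gene_id`, `length_bp`.
#' @param samples tibble with `sample_id`, `stage`, `replicate`,
#'   `total_reads`.
#' @param counts,rpkm numeric matrices, features x samples, dimnames set to
#'   `feature_id` and `sample_id`.
#' @return object of class `expr_table`.
#' @export
expr_table <- function(features, samples, counts, rpkm) {
  stopifnot(
    nrow(counts) == nrow(features), ncol(counts) == nrow(samples),
    identical(dim(counts), dim(rpkm)),
    identical(rownames(counts), features$feature_id),
    identical(colnames(counts), samples$sample_id),
    all(counts >= 0), all(rpkm >= 0)
  )
  panc <- features$gene_id[features$kind == "pancRNA"]
  mrna <- features$gene_id[features$kind == "mRNA"]
  if (!all(panc %in% mrna)) {
    stop("every pancRNA feature needs a cognate mRNA feature")
  }
  structure(list(features = features, samples = samples,
                 counts = counts, rpkm = rpkm),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf(
    "<expr_table> %d features (%d pancRNA, %d mRNA) x %d samples (%s)\n",
    nrow(x$features), sum(x$features$kind == "pancRNA"),
    sum(x$features$kind == "mRNA"), nrow(x$samples),
    paste(unique(x$samples$stage), collapse = ", ")
  ))
  invisible(x)
}

stage_samples <- function(expr, stage) {
  ids <- expr$samples$sample_id[expr$samples$stage == stage]
  if (length(ids) == 0) stop("stage not present in expression table: ", stage)
  ids
}

#' Mean RPKM per gene for one feature kind at one stage
#'
#' @param expr [expr_table()].
#' @param stage stage name.
#' @param kind "pancRNA" or "mRNA".
#' @return named numeric vector, names are `gene_id`.
#' @export
mean_rpkm <- function(expr, stage, kind = c("pancRNA", "mRNA")) {
  kind <- match.arg(kind)
  ids <- stage_samples(expr, stage)
  keep <- expr$features$kind == kind
  m <- expr$rpkm[keep, ids, drop = FALSE]
  stats::setNames(rowMeans(m), expr$features$gene_id[keep])
}
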