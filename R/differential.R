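#' Welch two-sample test on log2(RPKM + 1)
#'
#' Replicate-based differential test between two stages for one feature:
#' Welch's unequal-variance t-test on log-transformed RPKM. When both sides
#' have zero variance the test degenerates: p = 1 if the means are equal,
#' p = 0 otherwise (t = 0 or +/-Inf).
#'
#' @param x,y RPKM vectors for the two stages (>= 2 replicates each).
#' @return one-row tibble `mean_x`, `mean_y`, `t`, `df`, `p` (means on the
#'   log2(RPKM+1) scale).
#' @export
differential_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 replicates per side")
  lx <- log2(x + 1)
  ly <- log2(y + 1)
  se2 <- stats::var(lx) / length(lx) + stats::var(ly) / length(ly)
  if (se2 == 0) {
    eq <- mean(lx) == mean(ly)
    return(tibble::tibble(
      mean_x = mean(lx), mean_y = mean(ly),
      t = if (eq) 0 else sign(mean(lx) - mean(ly)) * Inf,
      df = NA_real_,
      p = if (eq) 1 else 0
    ))
  }
  tt <- stats::t.test(lx, ly, var.equal = FALSE)
  tibble::tibble(
    mean_x = mean(lx), mean_y = mean(ly),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped at 1 and monotone in p rank.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential table between two stages
#'
#' Applies [differential_test()] to every feature (optionally one kind) and
#' adjusts p-values with [bh_adjust()].
#'
#' @param expr [expr_table()].
#' @param stage_a,stage_b stage names (test is `stage_a` vs `stage_b`).
#' @param kind optional feature kind filter ("pancRNA"/"mRNA").
#' @return tibble `feature_id`, `kind`, `gene_id`, `mean_a`, `mean_b`, `t`,
#'   `df`, `p`, `q`.
#' @export
differential_table <- function(expr, stage_a, stage_b, kind = NULL) {
  ia <- stage_samples(expr, stage_a)
  ib <- stage_samples(expr, stage_b)
  feats <- expr$features
  if (!is.null(kind)) feats <- feats[feats$kind == kind, , drop = FALSE]
  res <- lapply(feats$feature_id, function(f) {
    differential_test(expr$rpkm[f, ia], expr$rpkm[f, ib])
  })
  out <- dplyr::bind_cols(
    feats[, c("feature_id", "kind", "gene_id")],
    dplyr::bind_rows(res)
  )
  names(out)[names(out) == "mean_x"] <- "mean_a"
  names(out)[names(out) == "mean_y"] <- "mean_b"
  out$q <- bh_adjust(out$p)
  out
}
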