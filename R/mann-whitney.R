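#' Mann-Whitney U test with exact enumeration for small samples
#'
#' U is computed from midranks (ties contribute 1/2). In `exact` mode (the
#' default for n + m <= 12) the null distribution is obtained by full
#' enumeration of all choose(n+m, n) labelings of the pooled observations,
#' ties included, so the p-value is exact even with tied data. Otherwise a
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. The two-sided p-value is min(1, 2 * one-sided).
#'
#' @param x,y numeric samples (here: per-clone methylated fractions).
#' @param alternative "two.sided" (default), "greater" (x tends larger) or
#'   "less".
#' @param mode "auto" (exact when n + m <= `exact_max`), "exact" or
#'   "approx".
#' @param exact_max size bound for auto exact mode (default 12).
#' @return list with `U` (for `x`), `p`, `mode` actually used.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "greater", "less"),
                           mode = c("auto", "exact", "approx"),
                           exact_max = 12L) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (any(is.na(c(x, y)))) stop("NA values not supported")
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  if (mode == "auto") mode <- if (n + m <= exact_max) "exact" else "approx"

  if (mode == "exact") {
    combs <- utils::combn(n + m, n)
    u_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p_ge <- mean(u_all >= u_obs - eps)
    p_le <- mean(u_all <= u_obs + eps)
  } else {
    nt <- table(pooled)
    tie_term <- sum(nt^3 - nt)
    N <- n + m
    v <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (v <= 0) {
      # all observations identical: no evidence either way
      p_ge <- p_le <- 0.5
    } else {
      mu <- n * m / 2
      # continuity correction pulls each tail statistic toward the mean
      p_ge <- stats::pnorm((u_obs - mu - 0.5) / sqrt(v), lower.tail = FALSE)
      p_le <- stats::pnorm((u_obs - mu + 0.5) / sqrt(v), lower.tail = TRUE)
    }
  }
  p <- switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
  list(U = u_obs, p = p, mode = mode)
}

#' Mann-Whitney tests between all stage pairs of a methylation data set
#'
#' Per locus, compares the per-clone methylated fractions of every pair of
#' stages with [mann_whitney_u()] (two-sided).
#'
#' @param clones tibble from [parse_bisulfite_clones()] with a `stage`
#'   column.
#' @return tibble `locus_id`, `stage_a`, `stage_b`, `level_a`, `level_b`,
#'   `U`, `p`.
#' @export
methylation_stage_tests <- function(clones) {
  stopifnot("stage" %in% names(clones))
  out <- list()
  for (locus in unique(clones$locus_id)) {
    sub <- clones[clones$locus_id == locus, , drop = FALSE]
    stages <- unique(sub$stage)
    if (length(stages) < 2) next
    for (i in seq_len(length(stages) - 1)) {
      for (j in seq((i + 1), length(stages))) {
        fa <- methylation_level(sub$calls[sub$stage == stages[i]])$per_clone
        fb <- methylation_level(sub$calls[sub$stage == stages[j]])$per_clone
        res <- mann_whitney_u(fa[!is.na(fa)], fb[!is.na(fb)])
        out[[length(out) + 1]] <- tibble::tibble(
          locus_id = locus, stage_a = stages[i], stage_b = stages[j],
          level_a = mean(fa, na.rm = TRUE), level_b = mean(fb, na.rm = TRUE),
          U = res$U, p = res$p
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
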