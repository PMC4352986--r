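#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`,
#' so every probability is positive when `pseudocount > 0`.
#'
#' @param sites character vector of equal-length DNA strings (ACGT only).
#' @param pseudocount added per base per column (default 0.5).
#' @return `pwm` object: a 4 x W probability matrix (rows A, C, G, T) with
#'   the count matrix and pseudocount kept as attributes.
#' @export
build_pwm <- function(sites, pseudocount = 0.5) {
  if (length(sites) < 1) stop("need >= 1 site")
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites must all have the same length")
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  if (!all(mat %in% c("A", "C", "G", "T"))) {
    stop("sites must contain only A, C, G, T")
  }
  counts <- apply(mat, 2, function(col) {
    table(factor(col, levels = c("A", "C", "G", "T")))
  })
  counts <- matrix(as.numeric(counts), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_from_counts(counts, pseudocount)
}

#' Build a PWM from a 4 x W count matrix
#'
#' @param counts numeric matrix with rows A, C, G, T.
#' @param pseudocount added per base per column.
#' @return `pwm` object (see [build_pwm()]).
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.5) {
  stopifnot(nrow(counts) == 4, all(counts >= 0))
  rownames(counts) <- c("A", "C", "G", "T")
  n <- colSums(counts)
  probs <- sweep(counts + pseudocount, 2, n + 4 * pseudocount, "/")
  structure(probs, class = c("pwm", "matrix"),
            counts = counts, pseudocount = pseudocount)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", ncol(x), pwm_consensus(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm a [build_pwm()] object.
#' @return character scalar, the per-column most probable base.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(unclass(pwm), 2, which.max)], collapse = "")
}

#' Read a JASPAR-style count matrix
#'
#' Minimal JASPAR format: an optional `>` header line, then four lines
#' `A [ n n ... ]` (brackets optional) in A, C, G, T order.
#'
#' @param path input file.
#' @param pseudocount passed to [pwm_from_counts()].
#' @return `pwm` object.
#' @export
read_jaspar <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4) stop("expected 4 base rows in ", path)
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGT]", "", trimws(l))
    as.numeric(strsplit(trimws(gsub("\\[|\\]", " ", l)), "\\s+")[[1]])
  })
  counts <- do.call(rbind, rows)
  pwm_from_counts(counts, pseudocount)
}

#' Write a PWM's count matrix in JASPAR style
#'
#' @param pwm `pwm` object carrying a counts attribute.
#' @param path output file.
#' @param name motif name for the header line.
#' @export
write_jaspar <- function(pwm, path, name = "motif") {
  counts <- attr(pwm, "counts")
  if (is.null(counts)) stop("pwm has no counts attribute")
  lines <- c(
    paste0(">", name),
    vapply(c("A", "C", "G", "T"), function(b) {
      sprintf("%s [ %s ]", b, paste(counts[b, ], collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Scan a sequence with a PWM at a min-max identity threshold
#'
#' Each window is scored as the sum of per-position log2 probabilities; the
#' identity of a window is its min-max normalized score,
#' `(s - s_min) / (s_max - s_min)`, where `s_min`/`s_max` are the lowest and
#' highest scores any window could achieve. Both strands are scanned (the
#' minus strand via the reverse complement, hit coordinates mapped back).
#' Windows containing non-ACGT characters are skipped. All hits with identity
#' at or above `min_identity` are reported; overlapping hits are not masked.
#'
#' @param seq DNA string.
#' @param pwm `pwm` object.
#' @param min_identity identity threshold in \[0, 1\] (default 0.9).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return tibble `start` (0-based, on the input sequence), `strand`,
#'   `identity`, sorted by position.
#' @export
scan_pwm <- function(seq, pwm, min_identity = 0.9, both_strands = TRUE) {
  empty <- tibble::tibble(start = integer(), strand = character(),
                          identity = numeric())
  w <- ncol(pwm)
  n <- nchar(seq)
  if (n < w) return(empty)
  logp <- log2(unclass(pwm))
  s_min <- sum(apply(logp, 2, min))
  s_max <- sum(apply(logp, 2, max))

  identity_fwd <- function(s) {
    idx <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
    nw <- nchar(s) - w + 1L
    sc <- numeric(nw)
    for (j in seq_len(w)) {
      sc <- sc + logp[cbind(idx[j:(nw + j - 1L)], j)]
    }
    (sc - s_min) / (s_max - s_min)   # NA where a window contains N
  }

  eps <- 1e-9   # absorb float rounding for windows exactly at the threshold
  fwd <- identity_fwd(seq)
  hits_f <- which(!is.na(fwd) & fwd >= min_identity - eps)
  out <- tibble::tibble(start = hits_f - 1L, strand = "+",
                        identity = fwd[hits_f])
  if (both_strands) {
    rev <- identity_fwd(revcomp(seq))
    hits_r <- which(!is.na(rev) & rev >= min_identity - eps)
    out <- dplyr::bind_rows(out, tibble::tibble(
      start = n - (hits_r - 1L) - w,   # map rc window start back
      strand = "-",
      identity = rev[hits_r]
    ))
  }
  dplyr::arrange(out, .data$start, .data$strand)
}
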