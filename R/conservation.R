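#' Exact global pairwise alignment (linear gap penalty)
#'
#' Needleman-Wunsch over `{A,C,G,T,N}` with match/mismatch scoring and a
#' linear gap penalty. `N` matches nothing (any column involving `N` scores
#' as a mismatch and never counts as an identity match). Traceback ties are
#' broken deterministically: diagonal, then up (gap in `b`), then left
#' (gap in `a`).
#'
#' Identity is the fraction of matching columns among aligned columns,
#' excluding end-gap columns (leading/trailing columns where either string
#' has a gap).
#'
#' @param a,b Non-empty nucleotide strings.
#' @param match Score for a matching column (default `1`).
#' @param mismatch Score for a mismatching column (default `-1`).
#' @param gap Score for each gapped column (default `-2`).
#' @return List of class `pairwise_alignment` with `aligned_a`, `aligned_b`,
#'   `score`, `identity`.
#' @export
#' @examples
#' pairwise_align("ACGT", "AGGT")
pairwise_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- normalize_seq(a); b <- normalize_seq(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("cannot align empty sequences", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  sub <- matrix(mismatch, n, m)
  eq <- outer(ca, cb, "==") & outer(ca != "N", cb != "N", "&")
  sub[eq] <- match
  for (i in seq_len(n)) {
    Si <- S[i, ]
    row <- numeric(m + 1L)
    row[1L] <- gap * i
    for (j in seq_len(m)) {
      row[j + 1L] <- max(Si[j] + sub[i, j],   # diagonal
                         Si[j + 1L] + gap,    # up
                         row[j] + gap)        # left
    }
    S[i + 1L, ] <- row
  }
  # traceback, preferring diagonal, then up, then left
  i <- n; j <- m
  out_a <- character(0); out_b <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && S[i + 1L, j + 1L] == S[i, j] + sub[i, j]) {
      out_a <- c(ca[i], out_a); out_b <- c(cb[j], out_b)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      out_a <- c(ca[i], out_a); out_b <- c("-", out_b)
      i <- i - 1L
    } else {
      out_a <- c("-", out_a); out_b <- c(cb[j], out_b)
      j <- j - 1L
    }
  }
  gap_a <- out_a == "-"; gap_b <- out_b == "-"
  any_gap <- gap_a | gap_b
  ncol_aln <- length(out_a)
  # end-gap columns: runs of gapped columns touching either end
  lead <- if (any_gap[1L]) seq_len(rle(any_gap)$lengths[1L]) else integer(0)
  r <- rle(rev(any_gap))
  trail <- if (rev(any_gap)[1L]) ncol_aln - seq_len(r$lengths[1L]) + 1L else integer(0)
  core_cols <- setdiff(seq_len(ncol_aln), c(lead, trail))
  matches <- sum(out_a[core_cols] == out_b[core_cols] &
                   out_a[core_cols] != "-" & out_a[core_cols] != "N")
  identity <- if (length(core_cols) > 0L) matches / length(core_cols) else 0
  structure(list(aligned_a = paste(out_a, collapse = ""),
                 aligned_b = paste(out_b, collapse = ""),
                 score = S[n + 1L, m + 1L],
                 identity = identity),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %g, identity %.3f\n", x$score, x$identity))
  invisible(x)
}

#' Call conserved HRE windows between two species
#'
#' Every confident window of species A is globally aligned against every
#' confident window of species B. Pairs pass when alignment identity reaches
#' `min_identity` and the two 5-bp cores are identical after strand
#' orientation (window sequences are stored on the hit strand, so cores are
#' compared directly at window positions 9-13). Passing pairs are matched
#' one-to-one greedily in order of decreasing identity (ties: decreasing
#' score, then positions), so each window appears in at most one pair.
#'
#' @param report_a,report_b `hre_scan_report` objects (same matrix width).
#' @param min_identity Minimum alignment identity in `[0, 1]` (default 0.7).
#' @param match,mismatch,gap Alignment scores, see [pairwise_align()].
#' @return Data frame with one row per conserved pair: ids, positions,
#'   strands, window sequences, `identity`, `score`, sorted by identity
#'   descending.
#' @export
find_conserved <- function(report_a, report_b, min_identity = 0.7,
                           match = 1, mismatch = -1, gap = -2) {
  stopifnot(inherits(report_a, "hre_scan_report"),
            inherits(report_b, "hre_scan_report"))
  if (report_a$params$matrix_width != report_b$params$matrix_width) {
    stop("scan reports were produced with different matrix widths", call. = FALSE)
  }
  wa <- confident_windows(report_a)
  wb <- confident_windows(report_b)
  empty <- data.frame(
    id_a = character(0), pos_a = integer(0), strand_a = character(0),
    window_a = character(0), id_b = character(0), pos_b = integer(0),
    strand_b = character(0), window_b = character(0),
    identity = numeric(0), score = numeric(0), core_match = logical(0))
  if (nrow(wa) == 0L || nrow(wb) == 0L) return(empty)
  core <- function(w) substr(w, CORE_OFFSET, CORE_OFFSET + 4L)
  cand <- expand.grid(i = seq_len(nrow(wa)), j = seq_len(nrow(wb)))
  cand <- cand[core(wa$window_seq[cand$i]) == core(wb$window_seq[cand$j]), ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  aln <- lapply(seq_len(nrow(cand)), function(k) {
    pairwise_align(wa$window_seq[cand$i[k]], wb$window_seq[cand$j[k]],
                   match, mismatch, gap)
  })
  cand$identity <- vapply(aln, `[[`, 0, "identity")
  cand$score <- vapply(aln, `[[`, 0, "score")
  cand <- cand[cand$identity >= min_identity, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ord <- order(-cand$identity, -cand$score,
               wa$pos[cand$i], wb$pos[cand$j])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(wa)); used_b <- logical(nrow(wb))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE
      used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    id_a = wa$seq_id[cand$i], pos_a = wa$pos[cand$i],
    strand_a = wa$strand[cand$i], window_a = wa$window_seq[cand$i],
    id_b = wb$seq_id[cand$j], pos_b = wb$pos[cand$j],
    strand_b = wb$strand[cand$j], window_b = wb$window_seq[cand$j],
    identity = cand$identity, score = cand$score,
    core_match = TRUE)
  rownames(out) <- NULL
  out
}

#' Write conserved pairs as TSV
#'
#' @param pairs Data frame from [find_conserved()].
#' @param path Output path.
#' @param params Optional named list echoed as `#key=value` header lines.
#' @export
write_pairs_tsv <- function(pairs, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("#%s=%s", names(params),
                       vapply(params, function(v) paste(v, collapse = ","), "")),
               con)
  }
  utils::write.table(pairs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
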