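CORE_PATTERN <- "RCGTG"

#' Find [A/G]CGTG core motif hits
#'
#' Reports every position whose 5-mer, read on the scanned strand, is exactly
#' `ACGTG` or `GCGTG`. Overlapping hits are all reported (no masking), and
#' positions are always the 1-based forward-coordinate start of the 5-mer.
#' The `variant` column records the first core base as read on the hit strand
#' (for a minus-strand hit this is the complement of the forward base at
#' `pos + 4`).
#'
#' @param p A [promoter_seq()] or plain nucleotide string.
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @return Data frame `seq_id`, `pos`, `strand`, `variant`, sorted by `pos`
#'   then strand.
#' @export
#' @examples
#' find_core_hits("ACGTG", "forward")
find_core_hits <- function(p, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  if (is.character(p)) p <- promoter_seq("seq", p)
  hits <- scan_iupac(p, c(core = CORE_PATTERN), strand_mode)
  if (nrow(hits) == 0L) {
    return(data.frame(seq_id = character(0), pos = integer(0),
                      strand = character(0), variant = character(0)))
  }
  # on the minus strand the first core base is the complement of the forward
  # base at pos + 4 (forward ...CACGT/C... reads RCGTG on the other strand)
  variant <- ifelse(hits$strand == "-",
                    c(T = "A", C = "G")[substring(p$seq, hits$pos + 4L, hits$pos + 4L)],
                    substring(p$seq, hits$pos, hits$pos))
  out <- data.frame(seq_id = hits$seq_id, pos = hits$pos,
                    strand = hits$strand, variant = unname(variant))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the 33-bp scoring window around a core hit
#'
#' The window spans 8 bases 5' of the 5-bp core through 20 bases 3' of it,
#' read on the hit strand (so a minus-strand window is the reverse complement
#' of the forward slice `pos - 20 .. pos + 12`). Hits whose window would run
#' off either end of the sequence are boundary-dropped (`NULL` is returned);
#' dropping is a recorded outcome in [scan_promoter()], not an error.
#'
#' @param p A [promoter_seq()].
#' @param pos 1-based forward-coordinate start of the 5-bp core.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar of 33 bases, or `NULL` if the window does not fit.
#' @export
extract_window <- function(p, pos, strand = "+") {
  if (is.character(p)) p <- promoter_seq("seq", p)
  L <- nchar(p$seq)
  if (strand == "+") {
    s <- pos - WIN_UP; e <- pos + 4L + WIN_DOWN
    if (s < 1L || e > L) return(NULL)
    substr(p$seq, s, e)
  } else {
    s <- pos - WIN_DOWN; e <- pos + 4L + WIN_UP
    if (s < 1L || e > L) return(NULL)
    reverse_complement(substr(p$seq, s, e))
  }
}

#' Scan a promoter for confident HRE windows
#'
#' Composition of [find_core_hits()], [extract_window()] and
#' [psfm_probability()]: every core hit that admits a full 33-bp window is
#' scored and classified confident when its normalized score reaches the
#' threshold (closed threshold: ties pass). Windows containing `N` are kept
#' but flagged unscorable and excluded from the confident count.
#'
#' @param p A [promoter_seq()] or nucleotide string.
#' @param m A [new_psfm()] of width 33 (or matching the masked positions).
#' @param threshold Normalized-score cutoff; default taken from the matrix.
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @param positions Optional position mask passed to [psfm_probability()]
#'   (e.g. `c(1:8, 14:33)` for flank-only scoring).
#' @return An object of class `hre_scan_report`: a list with counts
#'   (`n_core_hits`, `n_boundary_dropped`, `n_windows`, `n_unscorable`,
#'   `n_confident`), the window table `windows`, and a `params` echo.
#' @export
scan_promoter <- function(p, m, threshold = NULL,
                          strand_mode = c("both", "forward"),
                          positions = NULL) {
  strand_mode <- match.arg(strand_mode)
  if (is.character(p)) p <- promoter_seq("seq", p)
  stopifnot(inherits(m, "psfm"))
  if (is.null(positions) && m$width != WIN_WIDTH) {
    stop(sprintf("matrix width %d does not match the %d-bp scoring window",
                 m$width, WIN_WIDTH), call. = FALSE)
  }
  if (is.null(threshold)) threshold <- m$threshold
  hits <- find_core_hits(p, strand_mode)
  win_seqs <- if (nrow(hits) > 0L) {
    vapply(seq_len(nrow(hits)), function(i) {
      w <- extract_window(p, hits$pos[i], hits$strand[i])
      if (is.null(w)) NA_character_ else w
    }, "")
  } else character(0)
  keep <- !is.na(win_seqs)
  windows <- hits[keep, , drop = FALSE]
  windows$window_seq <- win_seqs[keep]
  if (nrow(windows) > 0L) {
    scores <- lapply(windows$window_seq, function(w)
      psfm_probability(m, w, positions))
    windows$raw_prob <- vapply(scores, `[[`, 0, "raw")
    windows$norm_score <- vapply(scores, `[[`, 0, "norm")
    windows$scorable <- vapply(scores, `[[`, TRUE, "scorable")
  } else {
    windows$raw_prob <- numeric(0)
    windows$norm_score <- numeric(0)
    windows$scorable <- logical(0)
  }
  windows$confident <- windows$scorable & !is.na(windows$norm_score) &
    windows$norm_score >= threshold
  rownames(windows) <- NULL
  structure(list(
    seq_id = p$id,
    n_core_hits = nrow(hits),
    n_boundary_dropped = sum(!keep),
    n_windows = nrow(windows),
    n_unscorable = sum(!windows$scorable),
    n_confident = sum(windows$confident),
    windows = windows,
    params = list(threshold = threshold, strand_mode = strand_mode,
                  matrix_width = m$width,
                  positions = positions %||% seq_len(m$width),
                  pseudocount = m$pseudocount)
  ), class = "hre_scan_report")
}

#' @export
print.hre_scan_report <- function(x, ...) {
  cat(sprintf(
    "HRE scan of '%s': %d core hits, %d boundary-dropped, %d windows (%d unscorable), %d confident (threshold %g, strands %s)\n",
    x$seq_id, x$n_core_hits, x$n_boundary_dropped, x$n_windows,
    x$n_unscorable, x$n_confident, x$params$threshold, x$params$strand_mode))
  invisible(x)
}

#' Confident windows of a scan report
#'
#' @param report An `hre_scan_report`.
#' @return Data frame of confident windows.
#' @export
confident_windows <- function(report) {
  stopifnot(inherits(report, "hre_scan_report"))
  report$windows[report$windows$confident, , drop = FALSE]
}

#' Write a scan report as TSV
#'
#' One row per window (id, position, strand, core variant, window sequence,
#' raw probability, normalized score, confident flag); all parameters that
#' affected the result are echoed as `#key=value` header lines.
#'
#' @param report An `hre_scan_report`.
#' @param path Output path.
#' @export
write_scan_tsv <- function(report, path) {
  stopifnot(inherits(report, "hre_scan_report"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- report$params
  writeLines(c(
    sprintf("#seq_id=%s", report$seq_id),
    sprintf("#threshold=%g", p$threshold),
    sprintf("#strand_mode=%s", p$strand_mode),
    sprintf("#matrix_width=%d", p$matrix_width),
    sprintf("#scored_positions=%s", paste(p$positions, collapse = ",")),
    sprintf("#n_core_hits=%d", report$n_core_hits),
    sprintf("#n_boundary_dropped=%d", report$n_boundary_dropped),
    sprintf("#n_windows=%d", report$n_windows),
    sprintf("#n_confident=%d", report$n_confident)
  ), con)
  utils::write.table(report$windows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
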