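# IUPAC degenerate nucleotide codes expanded to their base sets. A subject
# position matches iff its (unambiguous) base lies in the pattern's set, so a
# subject N never matches any pattern code, including N.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

.check_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L) stop("empty IUPAC pattern", call. = FALSE)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("illegal IUPAC code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pattern
}

.reverse_complement_iupac <- function(pattern) {
  chars <- rev(strsplit(pattern, "", fixed = TRUE)[[1]])
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

# all 1-based start positions where `pattern` (IUPAC) matches `seq` exactly,
# scanning the given string as-is
.iupac_starts <- function(seq, pattern) {
  L <- nchar(seq)
  w <- nchar(pattern)
  if (L < w) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n_start <- L - w + 1L
  ok <- rep(TRUE, n_start)
  for (k in seq_len(w)) {
    ok <- ok & (chars[seq_len(n_start) + k - 1L] %in% IUPAC_SETS[[pat[k]]])
  }
  which(ok)
}

#' Scan a promoter for degenerate (IUPAC) motifs
#'
#' Every start position whose subsequence matches the expanded IUPAC pattern
#' is reported; overlapping matches are all kept. On the minus strand the
#' reverse-complemented pattern is matched against the forward sequence, and
#' positions are always reported in forward coordinates (1-based start of the
#' matched stretch). With pattern `"RCGTG"` the forward/both semantics are
#' identical to [find_core_hits()].
#'
#' @param p A [promoter_seq()] (or plain nucleotide string).
#' @param motifs Data frame with columns `name` and `pattern`, or a named
#'   character vector of IUPAC patterns.
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @return Data frame with columns `seq_id`, `motif`, `pos`, `strand`.
#' @export
#' @examples
#' scan_iupac(promoter_seq("x", "ACGTGA"), c(hre_core = "RCGTG"))
scan_iupac <- function(p, motifs, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  if (is.character(p)) p <- promoter_seq("seq", p)
  stopifnot(inherits(p, "promoter_seq"))
  if (is.character(motifs)) {
    motifs <- data.frame(name = names(motifs) %||% motifs,
                         pattern = unname(motifs))
  }
  stopifnot(all(c("name", "pattern") %in% names(motifs)))
  out <- lapply(seq_len(nrow(motifs)), function(i) {
    pat <- .check_iupac(motifs$pattern[i])
    fwd <- .iupac_starts(p$seq, pat)
    res <- data.frame(seq_id = character(0), motif = character(0),
                      pos = integer(0), strand = character(0))
    if (length(fwd) > 0L) {
      res <- data.frame(seq_id = p$id, motif = motifs$name[i],
                        pos = fwd, strand = "+")
    }
    if (strand_mode == "both") {
      rev_hits <- .iupac_starts(p$seq, .reverse_complement_iupac(pat))
      if (length(rev_hits) > 0L) {
        res <- rbind(res, data.frame(seq_id = p$id, motif = motifs$name[i],
                                     pos = rev_hits, strand = "-"))
      }
    }
    res
  })
  out <- do.call(rbind, out)
  out <- out[order(out$motif, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a motif table (name, IUPAC pattern) from TSV
#'
#' @param path Two-column TSV with header `name`, `pattern`.
#' @return Data frame with validated patterns.
#' @export
read_motifs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("name", "pattern") %in% names(tab))) {
    stop("motif TSV needs columns 'name' and 'pattern'", call. = FALSE)
  }
  tab$pattern <- vapply(tab$pattern, .check_iupac, "")
  tab
}

#' Read a transcription-factor symbol list
#'
#' One gene symbol per line (blank lines and `#` comments ignored); symbols
#' are uppercased and deduplicated.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_tf_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(toupper(lines))
}

#' Co-factor overlap between promoter-bound TFs and HIF1A interactors
#'
#' Intersects the set of transcription factors reported to bind a promoter
#' with a set of experimentally validated HIF1A interactors, identifying
#' candidate co-regulators acting alongside HIF1A.
#'
#' @param promoter_tfs Character vector of gene symbols bound at the
#'   promoter.
#' @param interactors Character vector of validated interactor symbols.
#' @return Sorted character vector of shared symbols.
#' @export
#' @examples
#' cofactor_overlap(c("SP1", "MYC", "GATA1"), c("MYC", "SP1", "EP300"))
cofactor_overlap <- function(promoter_tfs, interactors) {
  if (length(promoter_tfs) == 0L) {
    stop("promoter TF set is empty (missing table?)", call. = FALSE)
  }
  if (length(interactors) == 0L) {
    stop("interactor set is empty (missing table?)", call. = FALSE)
  }
  sort(intersect(unique(toupper(promoter_tfs)), unique(toupper(interactors))))
}
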