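BASES <- c("A", "C", "G", "T")

#' Construct a position-specific frequency matrix object
#'
#' @param freq Numeric 4 x width matrix, rows `A,C,G,T`, each column summing
#'   to 1.
#' @param pseudocount Non-negative pseudocount the matrix was built with.
#' @param background Length-4 probability vector over `A,C,G,T`.
#' @param threshold Normalized-score confidence cutoff in (0, 1].
#' @return An object of class `psfm`.
#' @export
new_psfm <- function(freq, pseudocount = 0.5,
                     background = rep(0.25, 4), threshold = 0.05) {
  freq <- as.matrix(freq)
  if (nrow(freq) != 4L) stop("freq must have 4 rows (A, C, G, T)", call. = FALSE)
  dimnames(freq) <- list(BASES, paste0("p", seq_len(ncol(freq))))
  csums <- colSums(freq)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("each PSFM position must sum to 1 (max deviation ",
         format(max(abs(csums - 1))), ")", call. = FALSE)
  }
  if (any(freq < 0)) stop("negative frequency in PSFM", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background must sum to 1", call. = FALSE)
  }
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  structure(list(width = ncol(freq), freq = freq,
                 pseudocount = pseudocount,
                 background = stats::setNames(as.numeric(background), BASES),
                 threshold = threshold),
            class = "psfm")
}

#' @export
print.psfm <- function(x, ...) {
  cat(sprintf("psfm: width %d, pseudocount %g, threshold %g\n",
              x$width, x$pseudocount, x$threshold))
  cat("consensus:", psfm_consensus(x), "\n")
  invisible(x)
}

#' Build a PSFM from a training alignment of equal-length windows
#'
#' Frequencies are `(count + pseudocount) / (n + 4 * pseudocount)` per
#' position and base.
#'
#' @param training_windows Character vector (>= 2) of equal-length nucleotide
#'   strings over `{A,C,G,T}`.
#' @param pseudocount Non-negative real added to every count (default 0.5).
#' @param background Background base probabilities (default uniform).
#' @param threshold Confidence cutoff stored with the matrix (default 0.05).
#' @return A [new_psfm()] object of the training width.
#' @export
#' @examples
#' m <- build_psfm(c("ACGTGA", "ACGTGA", "ACGTGC"), pseudocount = 0.5)
build_psfm <- function(training_windows, pseudocount = 0.5,
                       background = rep(0.25, 4), threshold = 0.05) {
  if (length(training_windows) < 2L) {
    stop("need at least 2 training windows", call. = FALSE)
  }
  w <- unique(nchar(training_windows))
  if (length(w) != 1L) {
    stop("training windows have ragged widths: ", paste(w, collapse = ", "),
         call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(training_windows, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(chars)), BASES)
  if (length(bad) > 0L) {
    stop("illegal base(s) in training windows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(training_windows)
  freq <- vapply(seq_len(w), function(i) {
    counts <- table(factor(chars[, i], levels = BASES))
    (as.numeric(counts) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4))
  new_psfm(freq, pseudocount, background, threshold)
}

#' Consensus window of a PSFM
#'
#' Per position, the highest-frequency base; ties broken in favour of the
#' first base in `A < C < G < T` order.
#'
#' @param m A [new_psfm()] object.
#' @return Character scalar of length `m$width`.
#' @export
psfm_consensus <- function(m) {
  stopifnot(inherits(m, "psfm"))
  paste(BASES[apply(m$freq, 2L, which.max)], collapse = "")
}

#' Score a window against a PSFM
#'
#' The raw probability is the product over positions of the matrix frequency
#' of the observed base; the normalized score divides by the maximum
#' attainable product, so the consensus window scores exactly 1. Windows
#' containing `N` are unscorable (both scores `NA`, `scorable = FALSE`)
#' rather than numbers.
#'
#' @param m A [new_psfm()] object.
#' @param window Nucleotide string of length `m$width`.
#' @param positions Optional integer vector of window positions to score
#'   (e.g. flank-only masking); default all positions.
#' @return List with `raw`, `norm`, `scorable`.
#' @export
psfm_probability <- function(m, window, positions = NULL) {
  stopifnot(inherits(m, "psfm"))
  window <- normalize_seq(window)
  if (nchar(window) != m$width) {
    stop(sprintf("window length %d does not match matrix width %d",
                 nchar(window), m$width), call. = FALSE)
  }
  if (is.null(positions)) positions <- seq_len(m$width)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > m$width)) {
    stop("positions out of matrix range", call. = FALSE)
  }
  chars <- strsplit(window, "", fixed = TRUE)[[1]][positions]
  if (any(chars == "N")) {
    return(list(raw = NA_real_, norm = NA_real_, scorable = FALSE))
  }
  f <- m$freq[cbind(match(chars, BASES), positions)]
  fmax <- apply(m$freq[, positions, drop = FALSE], 2L, max)
  raw <- prod(f)
  list(raw = raw, norm = prod(f / fmax), scorable = TRUE)
}

#' Read a PSFM from a TSV matrix file
#'
#' Expects a header row `A C G T` and one row per position. Rows may hold
#' counts or frequencies: if every row already sums to 1 (within 1e-6) the
#' values are taken as frequencies; otherwise they are treated as counts and
#' normalized with `pseudocount`.
#'
#' @param path TSV file path.
#' @param pseudocount Pseudocount applied when normalizing count rows.
#' @param background,threshold Stored with the matrix; see [new_psfm()].
#' @return A [new_psfm()] object.
#' @export
read_psfm <- function(path, pseudocount = 0.5,
                      background = rep(0.25, 4), threshold = 0.05) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#")
  if (!identical(sort(colnames(tab)), sort(BASES))) {
    stop("PSFM file must have exactly the columns A, C, G, T; got: ",
         paste(colnames(tab), collapse = ", "), call. = FALSE)
  }
  tab <- as.matrix(tab[, BASES])
  rs <- rowSums(tab)
  if (any(rs <= 0)) {
    stop("PSFM row(s) with non-positive total: ",
         paste(which(rs <= 0), collapse = ", "), call. = FALSE)
  }
  if (any(tab < 0)) stop("negative entries in PSFM file", call. = FALSE)
  freq <- if (all(abs(rs - 1) < 1e-6)) {
    t(tab)
  } else {
    t((tab + pseudocount) / (rs + 4 * pseudocount))
  }
  new_psfm(freq, pseudocount, background, threshold)
}

#' Write a PSFM to a TSV matrix file
#'
#' Writes per-position frequencies (header `A C G T`, one row per position);
#' [read_psfm()] reproduces the matrix within 1e-9.
#'
#' @param m A [new_psfm()] object.
#' @param path Output path.
#' @export
write_psfm <- function(m, path) {
  stopifnot(inherits(m, "psfm"))
  tab <- as.data.frame(t(m$freq))
  utils::write.table(format(tab, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
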