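# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (direct string comparison / exhaustive search).

random_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# brute-force [A/G]CGTG enumeration by whole-5-mer string equality
bf_core_hits <- function(seq, strand_mode = "both") {
  L <- nchar(seq)
  if (L < 5L) {
    return(data.frame(pos = integer(0), strand = character(0)))
  }
  kmers <- substring(seq, 1:(L - 4L), 5:L)
  fwd <- which(kmers %in% c("ACGTG", "GCGTG"))
  out <- data.frame(pos = fwd, strand = rep("+", length(fwd)))
  if (strand_mode == "both") {
    rev <- which(kmers %in% c("CACGT", "CACGC"))
    out <- rbind(out, data.frame(pos = rev, strand = rep("-", length(rev))))
  }
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force IUPAC matching by per-offset set membership on string splits
bf_iupac_hits <- function(seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  w <- length(pc)
  hits <- integer(0)
  for (i in seq_len(max(length(sc) - w + 1L, 0L))) {
    if (all(mapply(function(s, p) s %in% sets[[p]], sc[i:(i + w - 1L)], pc))) {
      hits <- c(hits, i)
    }
  }
  hits
}

# exhaustive global-alignment optimum by recursive enumeration of all
# alignments (exponential; only for short strings)
bf_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j) &&
               substr(a, i, i) != "N") match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# position-by-position product, coded independently of psfm_probability
bf_psfm_raw <- function(freq, window) {
  chars <- strsplit(window, "")[[1]]
  p <- 1
  for (i in seq_along(chars)) {
    p <- p * unname(freq[match(chars[i], c("A", "C", "G", "T")), i])
  }
  p
}

random_psfm <- function(width) {
  freq <- matrix(stats::rexp(4 * width), nrow = 4)
  freq <- sweep(freq, 2, colSums(freq), "/")
  new_psfm(freq, pseudocount = 0.5)
}

extdata <- function(...) system.file("extdata", ..., package = "hrescan")
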