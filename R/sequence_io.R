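SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a nucleotide string
#'
#' Uppercases, converts RNA `U` to `T`, and rejects any character outside
#' `{A,C,G,T,N}`.
#'
#' @param seq Character scalar.
#' @return Normalized character scalar.
#' @keywords internal
normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), SEQ_ALPHABET)
  if (length(bad) > 0L) {
    stop("illegal sequence character(s): ", paste(bad, collapse = ", "),
         " (alphabet is A/C/G/T/N, U is converted to T)", call. = FALSE)
  }
  seq
}

#' Construct a genomic region
#'
#' Coordinates follow the Ensembl convention: 1-based, inclusive at both ends,
#' as in citations such as "Chromosome 16: 3,716,198-3,718,509".
#'
#' @param species Free-text species label (e.g. `"hs"`, `"dr"`).
#' @param chrom Chromosome name.
#' @param start,end Integer positions, 1-based inclusive, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_region`.
#' @export
#' @examples
#' genomic_region("dr", "3", 9602709, 9659449)
genomic_region <- function(species, chrom, start, end, strand = "+") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || start < 1L) stop("start must be an integer >= 1", call. = FALSE)
  if (is.na(end) || end < start) stop("end must be an integer >= start", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(
    list(species = as.character(species), chrom = as.character(chrom),
         start = start, end = end, strand = strand),
    class = "genomic_region"
  )
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<%s> %s:%d-%d(%s)\n", x$species, x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

#' Construct a promoter sequence record
#'
#' @param id Record identifier.
#' @param seq Nucleotide string over `{A,C,G,T,N}` (lowercase and `U`
#'   are normalized).
#' @param region Optional [genomic_region()]; when present its span must equal
#'   the sequence length.
#' @return An object of class `promoter_seq` with fields `id`, `seq`, `region`.
#' @export
#' @examples
#' promoter_seq("x", "acgtg")
promoter_seq <- function(id, seq, region = NULL) {
  seq <- normalize_seq(seq)
  if (!is.null(region)) {
    stopifnot(inherits(region, "genomic_region"))
    span <- region$end - region$start + 1L
    if (span != nchar(seq)) {
      stop(sprintf("region span (%d bp) does not match sequence length (%d bp)",
                   span, nchar(seq)), call. = FALSE)
    }
  }
  structure(list(id = as.character(id), seq = seq, region = region),
            class = "promoter_seq")
}

#' @export
print.promoter_seq <- function(x, ...) {
  cat(sprintf("promoter_seq '%s': %d bp", x$id, nchar(x$seq)))
  if (!is.null(x$region)) {
    cat(sprintf(" [%s %s:%d-%d(%s)]", x$region$species, x$region$chrom,
                x$region$start, x$region$end, x$region$strand))
  }
  cat("\n")
  invisible(x)
}

# header dialect: species|chrom:start-end(strand)
.region_header_re <- "^([^|]+)\\|([^:|[:space:]]+):([0-9]+)-([0-9]+)\\(([+-])\\)$"

.parse_fasta_header <- function(header) {
  m <- regmatches(header, regexec(.region_header_re, header))[[1]]
  if (length(m) == 0L) {
    return(list(id = header, region = NULL))
  }
  list(id = m[2],
       region = genomic_region(m[2], m[3], as.integer(m[4]), as.integer(m[5]), m[6]))
}

.format_fasta_header <- function(p) {
  if (is.null(p$region)) return(p$id)
  r <- p$region
  sprintf("%s|%s:%d-%d(%s)", p$id, r$chrom, r$start, r$end, r$strand)
}

#' Read promoter sequences from FASTA
#'
#' Sequences are uppercased, `U` converted to `T`, and validated against the
#' `{A,C,G,T,N}` alphabet. Headers of the form
#' `species|chrom:start-end(strand)` are parsed into a [genomic_region()]
#' (1-based inclusive coordinates); any other header becomes the record id
#' with no region.
#'
#' @param path FASTA file path.
#' @return List of [promoter_seq()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(first), ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", first, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path, call. = FALSE)
  lapply(seq_along(set), function(i) {
    h <- .parse_fasta_header(names(set)[i])
    promoter_seq(h$id, as.character(set[[i]]), h$region)
  })
}

#' Write promoter sequences to FASTA
#'
#' Standard FASTA with 60-column line wrapping; when a record carries a
#' region, the header is written in the `species|chrom:start-end(strand)`
#' dialect that [read_fasta()] parses back.
#'
#' @param records List of [promoter_seq()] objects (non-empty).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "promoter_seq")) records <- list(records)
  if (length(records) == 0L) stop("no records to write", call. = FALSE)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, .format_fasta_header, "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(NULL)
}

#' Extract a subregion of a promoter sequence
#'
#' Coordinates are sequence-local, 1-based and inclusive. When the record has
#' a genomic region, the region is shifted so it still describes the
#' extracted slice.
#'
#' @param p A [promoter_seq()].
#' @param start_1based,end_1based Slice bounds, `1 <= start <= end <= length`.
#' @return A [promoter_seq()] of length `end - start + 1`.
#' @export
extract_subregion <- function(p, start_1based, end_1based) {
  stopifnot(inherits(p, "promoter_seq"))
  L <- nchar(p$seq)
  s <- as.integer(start_1based); e <- as.integer(end_1based)
  if (is.na(s) || is.na(e) || s < 1L || e < s || e > L) {
    stop(sprintf("subregion %s-%s out of bounds (available: 1-%d)",
                 start_1based, end_1based, L), call. = FALSE)
  }
  region <- p$region
  if (!is.null(region)) {
    region <- genomic_region(region$species, region$chrom,
                             region$start + s - 1L, region$start + e - 1L,
                             region$strand)
  }
  promoter_seq(p$id, substr(p$seq, s, e), region)
}

#' Reverse complement of a nucleotide string
#'
#' Standard complement over `{A,C,G,T}` with `N -> N`; an involution
#' (applying it twice returns the input).
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @return Reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("ACGTG")  # "CACGT"
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# forward-coordinate interval [start,end] (1-based inclusive) of a feature
.hit_interval <- function(pos, strand, type = c("window", "core")) {
  type <- match.arg(type)
  if (type == "core") {
    cbind(start = pos, end = pos + 4L)
  } else {
    start <- ifelse(strand == "+", pos - WIN_UP, pos - WIN_DOWN)
    end <- ifelse(strand == "+", pos + 4L + WIN_DOWN, pos + 4L + WIN_UP)
    cbind(start = start, end = end)
  }
}

#' Write core hits or scored windows as BED6
#'
#' Output follows BED conventions (0-based, half-open): a feature occupying
#' 1-based positions `s..e` becomes `start = s - 1`, `end = e`. The score
#' column is the normalized matrix probability rescaled to 0-1000 and rounded
#' (0 for unscored core hits); the name encodes the candidate.
#'
#' @param hits Data frame of core hits (from [find_core_hits()]) or windows
#'   (from [scan_promoter()]'s report, column `window_seq` present).
#' @param path Output BED path.
#' @export
write_bed <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(NULL))
  }
  is_window <- "window_seq" %in% names(hits)
  iv <- .hit_interval(hits$pos, hits$strand, if (is_window) "window" else "core")
  score <- if (is_window && "norm_score" %in% names(hits)) {
    s <- round(1000 * hits$norm_score)
    s[is.na(s)] <- 0
    pmin(pmax(s, 0), 1000)
  } else rep(0, nrow(hits))
  gr <- GenomicRanges::GRanges(
    seqnames = hits$seq_id,
    ranges = IRanges::IRanges(start = iv[, "start"], end = iv[, "end"]),
    strand = hits$strand
  )
  S4Vectors::mcols(gr)$name <- sprintf("%s_%s_%d%s", hits$seq_id,
                                       if (is_window) "hre" else "core",
                                       hits$pos, hits$strand)
  S4Vectors::mcols(gr)$score <- as.numeric(score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(NULL)
}
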