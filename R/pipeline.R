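.as_promoters <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_fasta(x))
  if (inherits(x, "promoter_seq")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "promoter_seq"))) return(x)
  stop("expected a FASTA path, a promoter_seq, or a list of them", call. = FALSE)
}

.as_psfm <- function(x, ...) {
  if (inherits(x, "psfm")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_psfm(x, ...))
  stop("expected a psfm object or a PSFM TSV path", call. = FALSE)
}

# scan every record of one species and pool windows into a single report so
# conservation can be called across all of them
.scan_species <- function(records, m, threshold, strand_mode, positions) {
  reports <- lapply(records, scan_promoter, m = m, threshold = threshold,
                    strand_mode = strand_mode, positions = positions)
  pooled <- reports[[1L]]
  if (length(reports) > 1L) {
    pooled$windows <- do.call(rbind, lapply(reports, `[[`, "windows"))
    for (f in c("n_core_hits", "n_boundary_dropped", "n_windows",
                "n_unscorable", "n_confident")) {
      pooled[[f]] <- sum(vapply(reports, `[[`, 0L, f))
    }
    pooled$seq_id <- paste(vapply(records, `[[`, "", "id"), collapse = ",")
  }
  list(pooled = pooled, per_record = reports)
}

#' Run the full two-species HRE analysis
#'
#' Scans both species for confident HRE windows, calls conserved pairs
#' between them, and optionally scans auxiliary IUPAC motifs. When `out_dir`
#' is given, writes per-species scan TSV/BED, a conserved-pairs TSV, and a
#' summary TSV; every parameter that affected the results is echoed into the
#' TSV headers, and re-running with identical inputs reproduces the files
#' byte-for-byte.
#'
#' @param fasta_a,fasta_b FASTA paths (or `promoter_seq` objects / lists) for
#'   the two species.
#' @param matrix A [new_psfm()] or PSFM TSV path.
#' @param threshold Normalized-score confidence cutoff (default: matrix
#'   threshold).
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @param min_identity Minimum alignment identity for conserved pairs
#'   (default 0.7).
#' @param match,mismatch,gap Alignment scores (defaults +1/-1/-2).
#' @param positions Optional scoring-position mask (see [scan_promoter()]).
#' @param motifs Optional motif table (data frame or TSV path) for auxiliary
#'   IUPAC scanning.
#' @param out_dir Optional output directory.
#' @param verbose Log a summary block to standard error (default `TRUE`).
#' @return List with `report_a`, `report_b` (pooled `hre_scan_report`s),
#'   `pairs`, optional `aux_hits`, and a `summary` data frame.
#' @export
run_full_analysis <- function(fasta_a, fasta_b, matrix, threshold = NULL,
                              strand_mode = c("both", "forward"),
                              min_identity = 0.7, match = 1, mismatch = -1,
                              gap = -2, positions = NULL, motifs = NULL,
                              out_dir = NULL, verbose = TRUE) {
  strand_mode <- match.arg(strand_mode)
  recs_a <- .as_promoters(fasta_a)
  recs_b <- .as_promoters(fasta_b)
  for (r in c(recs_a, recs_b)) {
    if (nchar(r$seq) == 0L) stop("empty sequence: ", r$id, call. = FALSE)
  }
  m <- .as_psfm(matrix)
  if (is.null(threshold)) threshold <- m$threshold

  scan_a <- .scan_species(recs_a, m, threshold, strand_mode, positions)
  scan_b <- .scan_species(recs_b, m, threshold, strand_mode, positions)
  pairs <- find_conserved(scan_a$pooled, scan_b$pooled, min_identity,
                          match, mismatch, gap)
  aux_hits <- NULL
  if (!is.null(motifs)) {
    if (is.character(motifs)) motifs <- read_motifs(motifs)
    aux_hits <- do.call(rbind, lapply(c(recs_a, recs_b), scan_iupac,
                                      motifs = motifs, strand_mode = strand_mode))
  }
  summary <- data.frame(
    species = c("A", "B"),
    n_core_hits = c(scan_a$pooled$n_core_hits, scan_b$pooled$n_core_hits),
    n_windows = c(scan_a$pooled$n_windows, scan_b$pooled$n_windows),
    n_confident = c(scan_a$pooled$n_confident, scan_b$pooled$n_confident),
    n_conserved = nrow(pairs))
  params <- list(threshold = threshold, strand_mode = strand_mode,
                 min_identity = min_identity, match = match,
                 mismatch = mismatch, gap = gap,
                 matrix_width = m$width, pseudocount = m$pseudocount)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scan_tsv(scan_a$pooled, file.path(out_dir, "scan_a.tsv"))
    write_scan_tsv(scan_b$pooled, file.path(out_dir, "scan_b.tsv"))
    write_bed(scan_a$pooled$windows, file.path(out_dir, "scan_a.bed"))
    write_bed(scan_b$pooled$windows, file.path(out_dir, "scan_b.bed"))
    write_pairs_tsv(pairs, file.path(out_dir, "conserved_pairs.tsv"), params)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(aux_hits)) {
      utils::write.table(aux_hits, file.path(out_dir, "aux_motif_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (isTRUE(verbose)) {
    message(sprintf(
      "species A: %d core hits, %d confident | species B: %d core hits, %d confident | conserved pairs: %d",
      summary$n_core_hits[1], summary$n_confident[1],
      summary$n_core_hits[2], summary$n_confident[2], nrow(pairs)))
  }
  list(report_a = scan_a$pooled, report_b = scan_b$pooled, pairs = pairs,
       aux_hits = aux_hits, summary = summary, params = params)
}
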