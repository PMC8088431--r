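#' Simulation configuration for synthetic promoters
#'
#' Defaults emulate the scanned promoter window (5,500 bp, i.e. -5000 to
#' +500 around a TSS) with a uniform base composition. Randomness uses R's
#' default Mersenne-Twister generator; fixing `seed` makes every generation
#' fully reproducible.
#'
#' @param length Sequence length in bp (default 5500).
#' @param base_freqs Background base probabilities over `A,C,G,T`
#'   (default uniform).
#' @param n_planted Number of planted 33-bp HRE windows (default 10).
#' @param min_spacing Minimum gap in bp between planted windows (default 40).
#' @param flank_divergence Flank divergence applied to species-B copies of
#'   shared sites (default 0.1); the 5-bp core is never mutated. Under
#'   `divergence_mode = "exact"` (default) exactly `round(28 *
#'   flank_divergence)` flank bases are substituted per shared site, so the
#'   realized flank identity is controlled at `1 - flank_divergence`; under
#'   `"bernoulli"` each flank base mutates independently with this
#'   probability.
#' @param divergence_mode `"exact"` (controlled realized divergence,
#'   default) or `"bernoulli"` (per-base substitution probability).
#' @param shared_fraction Fraction of planted sites present in both species
#'   of a pair (default 0.5).
#' @param plant_mode `"sample"` (default; windows drawn position-wise from
#'   the matrix, core positions forced to a legal `[A/G]CGTG`) or
#'   `"consensus"` (every planted window is the matrix consensus with the
#'   core variant drawn).
#' @param plant_strand `"forward"` (default) or `"random"`.
#' @param seed Optional integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(length = 5500L,
                       base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_planted = 10L, min_spacing = 40L,
                       flank_divergence = 0.1, shared_fraction = 0.5,
                       divergence_mode = c("exact", "bernoulli"),
                       plant_mode = c("sample", "consensus"),
                       plant_strand = c("forward", "random"),
                       seed = NULL) {
  divergence_mode <- match.arg(divergence_mode)
  plant_mode <- match.arg(plant_mode)
  plant_strand <- match.arg(plant_strand)
  length <- as.integer(length)
  n_planted <- as.integer(n_planted)
  min_spacing <- as.integer(min_spacing)
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-9) {
    stop("base_freqs must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (n_planted < 0L) stop("n_planted must be >= 0", call. = FALSE)
  if (n_planted > 0L && n_planted * (WIN_WIDTH + min_spacing) > length) {
    stop("n_planted * (33 + min_spacing) exceeds sequence length; ",
         "reduce n_planted or min_spacing", call. = FALSE)
  }
  if (flank_divergence < 0 || flank_divergence > 1) {
    stop("flank_divergence must lie in [0, 1]", call. = FALSE)
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(length = length,
                 base_freqs = stats::setNames(base_freqs, BASES),
                 n_planted = n_planted, min_spacing = min_spacing,
                 flank_divergence = flank_divergence,
                 shared_fraction = shared_fraction,
                 divergence_mode = divergence_mode,
                 plant_mode = plant_mode, plant_strand = plant_strand,
                 seed = seed),
            class = "sim_config")
}

.maybe_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
}

#' Default simulation matrix: sharp RCGTG core, unconstrained flanks
#'
#' The 33-position matrix used by the generator (and as scoring default in
#' the synthetic studies): positions 9-13 carry the core (position 9 splits
#' A/G evenly, positions 10-13 are fixed C,G,T,G) and the 28 flank positions
#' are uniform. Windows sampled from it are mutually distinct in their
#' flanks yet all score 1 on the normalized scale, so detection and
#' conservation can be studied independently of flank informativeness; see
#' the package vignette for the rationale.
#'
#' @return A [new_psfm()] of width 33 with pseudocount 0.
#' @export
sim_psfm <- function() {
  freq <- matrix(0.25, nrow = 4L, ncol = WIN_WIDTH, dimnames = list(BASES, NULL))
  core <- matrix(0, nrow = 4L, ncol = 5L, dimnames = list(BASES, NULL))
  core["A", 1L] <- 0.5; core["G", 1L] <- 0.5
  core["C", 2L] <- 1; core["G", 3L] <- 1; core["T", 4L] <- 1; core["G", 5L] <- 1
  freq[, CORE_OFFSET:(CORE_OFFSET + 4L)] <- core
  new_psfm(freq, pseudocount = 0, background = rep(0.25, 4), threshold = 0.05)
}

#' Generate an i.i.d. background promoter sequence
#'
#' @param cfg A [sim_config()]; uses `length`, `base_freqs`, `seed`.
#' @param id Record id (default `"synth"`).
#' @return A [promoter_seq()].
#' @export
generate_background <- function(cfg, id = "synth") {
  stopifnot(inherits(cfg, "sim_config"))
  .maybe_seed(cfg)
  promoter_seq(id, paste(sample(BASES, cfg$length, replace = TRUE,
                                prob = cfg$base_freqs), collapse = ""))
}

# number of [A/G]CGTG occurrences in a window, counting both strands
.count_cores <- function(window) {
  length(.iupac_starts(window, CORE_PATTERN)) +
    length(.iupac_starts(window, "CACGY"))
}

# draw one 33-bp window from the matrix; core positions forced to a legal
# [A/G]CGTG (first core base drawn from the renormalized A/G weights). In
# sampling mode, windows are redrawn until the core occurrence is unique on
# both strands, so the planted ground truth is unambiguous.
.draw_window <- function(m, mode, max_tries = 200L) {
  core_cols <- CORE_OFFSET:(CORE_OFFSET + 4L)
  wA <- m$freq["A", core_cols[1L]]; wG <- m$freq["G", core_cols[1L]]
  if (wA + wG <= 0) { wA <- 0.5; wG <- 0.5 }
  draw_once <- function() {
    chars <- if (mode == "consensus") {
      strsplit(psfm_consensus(m), "", fixed = TRUE)[[1]]
    } else {
      vapply(seq_len(m$width), function(i) {
        sample(BASES, 1L, prob = m$freq[, i])
      }, "")
    }
    chars[core_cols[1L]] <- sample(c("A", "G"), 1L, prob = c(wA, wG))
    chars[core_cols[2:5]] <- c("C", "G", "T", "G")
    paste(chars, collapse = "")
  }
  w <- draw_once()
  if (mode == "consensus") return(w)
  tries <- 1L
  while (.count_cores(w) != 1L && tries < max_tries) {
    w <- draw_once()
    tries <- tries + 1L
  }
  w
}

# uniformly choose k window start positions with pairwise separation of at
# least WIN_WIDTH + min_spacing, by the standard order-statistics
# transformation (sample k distinct values in a shrunken range, then expand
# by the separation), which is uniform over valid configurations
.place_windows <- function(L, k, min_spacing) {
  if (k == 0L) return(integer(0))
  d <- WIN_WIDTH + min_spacing
  M <- L - WIN_WIDTH + 1L
  M_shrunk <- M - (k - 1L) * (d - 1L)
  if (M_shrunk < k) {
    stop("could not place ", k, " non-overlapping windows; ",
         "reduce n_planted or min_spacing", call. = FALSE)
  }
  sort(sample.int(M_shrunk, k)) + (seq_len(k) - 1L) * (d - 1L)
}

.overwrite <- function(seq, start, replacement) {
  substr(seq, start, start + nchar(replacement) - 1L) <- replacement
  seq
}

#' Plant matrix-drawn HRE windows into a background sequence
#'
#' Windows are written over (not inserted into) the background at uniformly
#' chosen non-overlapping positions, keeping coordinates stable. The
#' returned truth table records each placement exactly; `pos` is the 1-based
#' forward-coordinate start of the 33-bp window and `window_seq` is read on
#' the planted strand.
#'
#' @param bg A [promoter_seq()] background.
#' @param m A [new_psfm()] of width 33.
#' @param cfg A [sim_config()]; uses `n_planted`, `min_spacing`,
#'   `plant_mode`, `plant_strand`, `seed`.
#' @return List with `seq` (modified [promoter_seq()]) and `truth` (data
#'   frame `site`, `pos`, `core_pos`, `strand`, `window_seq`).
#' @export
plant_sites <- function(bg, m, cfg) {
  stopifnot(inherits(bg, "promoter_seq"), inherits(m, "psfm"),
            inherits(cfg, "sim_config"))
  if (m$width != WIN_WIDTH) {
    stop("planting requires a 33-position matrix", call. = FALSE)
  }
  .maybe_seed(cfg)
  k <- cfg$n_planted
  truth <- data.frame(site = integer(0), pos = integer(0),
                      core_pos = integer(0), strand = character(0),
                      window_seq = character(0))
  if (k == 0L) return(list(seq = bg, truth = truth))
  starts <- .place_windows(nchar(bg$seq), k, cfg$min_spacing)
  strands <- if (cfg$plant_strand == "random") {
    sample(c("+", "-"), k, replace = TRUE)
  } else rep("+", k)
  seq <- bg$seq
  windows <- character(k)
  for (i in seq_len(k)) {
    w <- .draw_window(m, cfg$plant_mode)
    windows[i] <- w
    seq <- .overwrite(seq, starts[i],
                      if (strands[i] == "+") w else reverse_complement(w))
  }
  truth <- data.frame(
    site = seq_len(k), pos = starts,
    core_pos = ifelse(strands == "+", starts + WIN_UP, starts + WIN_DOWN),
    strand = strands, window_seq = windows)
  list(seq = promoter_seq(bg$id, seq, bg$region), truth = truth)
}

#' Expected number of background core hits
#'
#' Closed-form expectation of `[A/G]CGTG` occurrences in an i.i.d.
#' background: `(length - 4) * (p_A + p_G) * p_C * p_G * p_T * p_G` on the
#' forward strand; in both-strand mode the expectation of the
#' reverse-complement motif `CACG[C/T]`, computed on forward frequencies, is
#' added.
#'
#' @param length Sequence length in bp.
#' @param base_freqs Probabilities over `A,C,G,T`.
#' @param strand_mode `"both"` or `"forward"`.
#' @return Expected hit count (real).
#' @export
#' @examples
#' expected_background_core_hits(1004, rep(0.25, 4), "forward")  # ~1.953
expected_background_core_hits <- function(length,
                                          base_freqs = rep(0.25, 4),
                                          strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  p <- stats::setNames(as.numeric(base_freqs), BASES)
  if (abs(sum(p) - 1) > 1e-9) stop("base_freqs must sum to 1", call. = FALSE)
  n_pos <- max(length - 4L, 0L)
  p_fwd <- (p["A"] + p["G"]) * p["C"] * p["G"] * p["T"] * p["G"]
  if (strand_mode == "forward") return(unname(n_pos * p_fwd))
  p_rev <- p["C"] * p["A"] * p["C"] * p["G"] * (p["C"] + p["T"])
  unname(n_pos * (p_fwd + p_rev))
}

# mutate flank bases (window positions outside 9..13) to a different base;
# "exact" substitutes a fixed round(divergence * n_flank) positions (chosen
# uniformly), "bernoulli" mutates each flank base independently
.diverge_flanks <- function(window, divergence, mode = "exact") {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  flank <- setdiff(seq_along(chars), CORE_OFFSET:(CORE_OFFSET + 4L))
  hit <- if (mode == "exact") {
    n_mut <- round(divergence * length(flank))
    if (n_mut > 0L) sample(flank, n_mut) else integer(0)
  } else {
    flank[stats::runif(length(flank)) < divergence]
  }
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a two-species synthetic promoter pair with shared HREs
#'
#' Backgrounds are generated independently for the two species. A
#' `shared_fraction` of the `n_planted` sites is copied into both species
#' (species-B flanks mutated per-base at `flank_divergence`, core
#' preserved); the remaining sites are private, alternately assigned to one
#' species. Placement positions are drawn independently per species.
#'
#' @param cfg A [sim_config()].
#' @param m A [new_psfm()] of width 33 (default [sim_psfm()]).
#' @return List with [promoter_seq()] entries `a` and `b` and a `truth` data
#'   frame (`site`, `species` in `{"both","A","B"}`, `pos_a`, `pos_b`,
#'   `strand`, `window_a`, `window_b`; `NA` where a site is absent from a
#'   species).
#' @export
make_species_pair <- function(cfg, m = sim_psfm()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(m, "psfm"))
  .maybe_seed(cfg)
  k <- cfg$n_planted
  n_shared <- round(cfg$shared_fraction * k)
  n_private <- k - n_shared
  species <- c(rep("both", n_shared),
               rep(c("A", "B"), length.out = n_private))
  n_a <- sum(species != "B"); n_b <- sum(species != "A")
  cfg_noseed <- cfg; cfg_noseed$seed <- NULL
  bg_a <- generate_background(cfg_noseed, id = "speciesA")
  bg_b <- generate_background(cfg_noseed, id = "speciesB")
  windows_a <- vapply(seq_len(k), function(i) .draw_window(m, cfg$plant_mode), "")
  windows_b <- ifelse(
    species == "both",
    vapply(windows_a, .diverge_flanks, "", divergence = cfg$flank_divergence,
           mode = cfg$divergence_mode),
    windows_a)
  strands <- if (cfg$plant_strand == "random") {
    sample(c("+", "-"), k, replace = TRUE)
  } else rep("+", k)
  pos_a <- rep(NA_integer_, k); pos_b <- rep(NA_integer_, k)
  in_a <- species != "B"; in_b <- species != "A"
  pos_a[in_a] <- .place_windows(cfg$length, n_a, cfg$min_spacing)
  pos_b[in_b] <- .place_windows(cfg$length, n_b, cfg$min_spacing)
  seq_a <- bg_a$seq; seq_b <- bg_b$seq
  for (i in seq_len(k)) {
    if (in_a[i]) {
      seq_a <- .overwrite(seq_a, pos_a[i],
                          if (strands[i] == "+") windows_a[i]
                          else reverse_complement(windows_a[i]))
    }
    if (in_b[i]) {
      seq_b <- .overwrite(seq_b, pos_b[i],
                          if (strands[i] == "+") windows_b[i]
                          else reverse_complement(windows_b[i]))
    }
  }
  truth <- data.frame(
    site = seq_len(k), species = species,
    pos_a = pos_a, pos_b = pos_b, strand = strands,
    window_a = ifelse(in_a, windows_a, NA_character_),
    window_b = ifelse(in_b, unname(windows_b), NA_character_))
  list(a = promoter_seq("speciesA", seq_a),
       b = promoter_seq("speciesB", seq_b),
       truth = truth)
}

#' Write a planted-truth table as TSV (and optionally BED)
#'
#' @param truth Truth data frame from [plant_sites()].
#' @param path TSV output path.
#' @param bed_path Optional BED6 output of the planted windows.
#' @param seq_id Sequence name used in the BED output.
#' @export
write_truth <- function(truth, path, bed_path = NULL, seq_id = "synth") {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path) && nrow(truth) > 0L) {
    df <- data.frame(seq_id = seq_id, pos = truth$core_pos,
                     strand = truth$strand, window_seq = truth$window_seq,
                     norm_score = 1)
    write_bed(df, bed_path)
  }
  invisible(NULL)
}
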