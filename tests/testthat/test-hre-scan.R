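test_that("find_core_hits handles the canonical examples", {
  h <- find_core_hits("ACGTG", "forward")
  expect_equal(nrow(h), 1L)
  expect_equal(h$pos, 1L)
  expect_equal(h$variant, "A")

  expect_equal(nrow(find_core_hits("TTTTT", "both")), 0L)

  # CACGT carries the core only on the minus strand
  h <- find_core_hits("CACGT", "both")
  expect_equal(h$strand, "-")
  expect_equal(h$pos, 1L)
  expect_equal(h$variant, "A")
  h2 <- find_core_hits("CACGC", "both")
  expect_equal(h2$variant, "G")

  # overlapping cores are all reported
  h <- find_core_hits("GCGTGCGTG", "forward")
  expect_equal(h$pos, c(1L, 5L))
})

test_that("scanner equals brute-force 5-mer enumeration on random sequences", {
  set.seed(99)
  for (i in 1:60) {
    s <- random_dna(200)
    for (mode in c("forward", "both")) {
      got <- find_core_hits(s, mode)
      expect_identical(got[, c("pos", "strand")], bf_core_hits(s, mode))
    }
  }
})

test_that("scanning the reverse complement mirrors the hit set", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_dna(300)
    fwd <- find_core_hits(s, "both")
    rev <- find_core_hits(reverse_complement(s), "both")
    # a hit at pos on strand sigma maps to 300 - (pos + 4) + 1 on the other
    mapped <- data.frame(pos = 300L - fwd$pos - 3L,
                         strand = as.character(ifelse(fwd$strand == "+", "-", "+")))
    mapped <- mapped[order(mapped$pos, mapped$strand), ]
    expect_equal(rev$pos, mapped$pos)
    expect_equal(rev$strand, mapped$strand)
  }
})

test_that("extract_window geometry: exact fit, boundary drop, minus strand", {
  # core at pos 9 of a 33-base sequence fills the whole sequence
  s <- paste0(strrep("T", 8), "ACGTG", strrep("C", 20))
  expect_equal(extract_window(s, 9L, "+"), s)
  expect_equal(nchar(extract_window(s, 9L, "+")), 33L)

  # core at pos 1 needs 8 upstream bases -> boundary drop
  expect_null(extract_window(strrep("ACGTG", 10), 1L, "+"))

  # minus-strand window is the reverse complement of pos-20..pos+12
  set.seed(31)
  s <- random_dna(200)
  h <- find_core_hits(s, "both")
  minus <- h[h$strand == "-" & h$pos > 20 & h$pos + 12 <= 200, ]
  for (k in seq_len(nrow(minus))) {
    p <- minus$pos[k]
    oracle <- reverse_complement(substr(s, p - 20L, p + 12L))
    expect_equal(extract_window(s, p, "-"), oracle)
    expect_equal(substr(oracle, 9, 13), paste0(minus$variant[k], "CGTG"))
  }
})

test_that("scan_promoter composes counts consistently", {
  m <- sim_psfm()
  rep0 <- scan_promoter(strrep("T", 100), m)
  expect_equal(rep0$n_core_hits, 0L)
  expect_equal(rep0$n_windows, 0L)
  expect_equal(rep0$n_confident, 0L)

  set.seed(8)
  s <- random_dna(2000)
  rep <- scan_promoter(s, m)
  expect_equal(rep$n_core_hits, rep$n_windows + rep$n_boundary_dropped)
  expect_lte(rep$n_confident, rep$n_windows)
  expect_lte(rep$n_windows, rep$n_core_hits)

  # threshold extremes
  expect_equal(scan_promoter(s, m, threshold = 1e-300)$n_confident,
               rep$n_windows - rep$n_unscorable)
  expect_equal(scan_promoter(s, m, threshold = 1 + 1e-9)$n_confident, 0L)

  # raising the threshold never increases n_confident
  thr <- c(0.001, 0.01, 0.05, 0.2, 0.5, 1)
  counts <- vapply(thr, function(t) scan_promoter(s, m, threshold = t)$n_confident, 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("planted consensus windows are recovered as confident", {
  recs <- read_fasta(extdata("synthetic_hre_training.fasta"))
  m <- build_psfm(vapply(recs, `[[`, "", "seq"), pseudocount = 0.5)
  cfg <- sim_config(n_planted = 10, plant_mode = "consensus", seed = 123)
  planted <- plant_sites(generate_background(cfg), m, cfg)
  rep <- scan_promoter(planted$seq, m, threshold = 0.05)
  expect_gte(rep$n_confident, 10L)
  conf <- confident_windows(rep)
  expect_true(all(planted$truth$core_pos %in% conf$pos))
})

test_that("windows containing N are flagged and excluded from the confident count", {
  s <- paste0(strrep("T", 8), "ACGTG", strrep("C", 10), "N", strrep("C", 9))
  rep <- scan_promoter(s, sim_psfm(), strand_mode = "forward")
  expect_equal(rep$n_windows, 1L)
  expect_equal(rep$n_unscorable, 1L)
  expect_equal(rep$n_confident, 0L)
})

test_that("scan TSV report echoes parameters and window rows", {
  set.seed(2)
  rep <- scan_promoter(promoter_seq("toy", random_dna(500)), sim_psfm())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(rep, f)
  lines <- readLines(f)
  expect_true(any(grepl("^#threshold=0.05$", lines)))
  expect_true(any(grepl("^#strand_mode=both$", lines)))
  tab <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), rep$n_windows)
  expect_true(all(c("pos", "strand", "variant", "window_seq", "raw_prob",
                    "norm_score", "confident") %in% names(tab)))
})
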