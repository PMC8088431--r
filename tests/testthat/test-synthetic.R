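test_that("background generation is reproducible and respects base frequencies", {
  cfg <- sim_config(length = 10, base_freqs = c(1, 0, 0, 0), n_planted = 0,
                    seed = 4)
  expect_equal(generate_background(cfg)$seq, strrep("A", 10))

  cfg <- sim_config(length = 500, n_planted = 0, seed = 11)
  expect_equal(generate_background(cfg)$seq, generate_background(cfg)$seq)

  # uniform frequencies: each base count within 4 sigma of n/4
  cfg <- sim_config(length = 10000, n_planted = 0, seed = 21)
  counts <- table(strsplit(generate_background(cfg)$seq, "")[[1]])
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 4 * sigma))

  expect_error(sim_config(base_freqs = c(0.5, 0.5, 0.5, 0.5)), "sum")
  expect_error(sim_config(length = 100, n_planted = 10), "exceeds")
})

test_that("plant_sites records exact ground truth and respects spacing", {
  m <- sim_psfm()
  cfg0 <- sim_config(n_planted = 0, seed = 5)
  bg <- generate_background(cfg0)
  out <- plant_sites(bg, m, cfg0)
  expect_equal(out$seq$seq, bg$seq)
  expect_equal(nrow(out$truth), 0L)

  cfg <- sim_config(n_planted = 8, min_spacing = 40, seed = 6)
  out <- plant_sites(generate_background(cfg), m, cfg)
  tr <- out$truth
  expect_equal(nrow(tr), 8L)
  expect_true(all(diff(sort(tr$pos)) >= 33 + 40))
  # truth windows re-extracted from the sequence equal the recorded strings
  for (i in seq_len(nrow(tr))) {
    slice <- substr(out$seq$seq, tr$pos[i], tr$pos[i] + 32L)
    expect_equal(slice, tr$window_seq[i])
    expect_true(substr(tr$window_seq[i], 9, 13) %in% c("ACGTG", "GCGTG"))
  }
})

test_that("consensus plantings are fully recovered by the scanner", {
  m <- sim_psfm()
  cfg <- sim_config(n_planted = 3, plant_mode = "consensus", seed = 9)
  out <- plant_sites(generate_background(cfg), m, cfg)
  conf <- confident_windows(scan_promoter(out$seq, m))
  expect_true(all(out$truth$core_pos %in% conf$pos))
})

test_that("random-strand plantings are recovered under both-strand scanning", {
  m <- sim_psfm()
  cfg <- sim_config(n_planted = 6, plant_strand = "random", seed = 13)
  out <- plant_sites(generate_background(cfg), m, cfg)
  expect_true(any(out$truth$strand == "-"))  # seed chosen blind; property below holds either way
  rep <- scan_promoter(out$seq, m, strand_mode = "both")
  conf <- confident_windows(rep)
  found <- mapply(function(p, s) any(conf$pos == p & conf$strand == s),
                  out$truth$core_pos, out$truth$strand)
  expect_true(all(found))
})

test_that("expected background core hits follow the closed form", {
  expect_equal(expected_background_core_hits(1004, rep(0.25, 4), "forward"),
               1000 * 0.5 * 0.25^4)
  expect_equal(expected_background_core_hits(1004, rep(0.25, 4), "both"),
               2 * 1000 * 0.5 * 0.25^4)
  expect_equal(expected_background_core_hits(500, c(0.5, 0, 0.25, 0.25)), 0)

  # asymmetric composition: forward and reverse motif probabilities differ
  p <- c(A = 0.4, C = 0.3, G = 0.2, T = 0.1)
  expect_equal(expected_background_core_hits(104, p, "forward"),
               100 * (0.4 + 0.2) * 0.3 * 0.2 * 0.1 * 0.2)
  expect_equal(expected_background_core_hits(104, p, "both"),
               100 * ((0.4 + 0.2) * 0.3 * 0.2 * 0.1 * 0.2 +
                        0.3 * 0.4 * 0.3 * 0.2 * (0.3 + 0.1)))
})

test_that("empirical core-hit counts match the analytic expectation", {
  set.seed(31)
  n_seq <- 120
  L <- 800
  counts <- replicate(n_seq, nrow(find_core_hits(random_dna(L), "forward")))
  expected <- expected_background_core_hits(L, rep(0.25, 4), "forward")
  p1 <- 0.5 * 0.25^4
  sigma_mean <- sqrt((L - 4) * p1 * (1 - p1) / n_seq)
  expect_lt(abs(mean(counts) - expected), 4 * sigma_mean)
})

test_that("species pairs share sites with controlled divergence", {
  # perfect conservation: divergence 0, all shared
  cfg <- sim_config(n_planted = 4, shared_fraction = 1, flank_divergence = 0,
                    seed = 41)
  pair <- make_species_pair(cfg)
  expect_equal(pair$truth$window_a, pair$truth$window_b)
  m <- sim_psfm()
  pairs <- find_conserved(scan_promoter(pair$a, m), scan_promoter(pair$b, m),
                          min_identity = 0.8)
  expect_equal(nrow(pairs), 4L)
  expect_equal(pairs$identity, rep(1, 4))

  # controlled divergence: exactly round(0.1 * 28) = 3 flank substitutions
  cfg <- sim_config(n_planted = 6, shared_fraction = 1, flank_divergence = 0.1,
                    seed = 42)
  pair <- make_species_pair(cfg)
  muts <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 pair$truth$window_a, pair$truth$window_b)
  expect_equal(unname(muts), rep(3, 6))

  # private sites appear in exactly one species
  cfg <- sim_config(n_planted = 6, shared_fraction = 0.5, seed = 43)
  tr <- make_species_pair(cfg)$truth
  expect_equal(sum(tr$species == "both"), 3L)
  expect_true(all(is.na(tr$pos_b[tr$species == "A"])))
  expect_true(all(is.na(tr$pos_a[tr$species == "B"])))
})

test_that("bernoulli divergence yields ~90% flank identity on average", {
  cfg <- sim_config(n_planted = 30, shared_fraction = 1,
                    flank_divergence = 0.1, divergence_mode = "bernoulli",
                    min_spacing = 100, length = 30 * 150 + 100, seed = 44)
  pair <- make_species_pair(cfg)
  muts <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 pair$truth$window_a, pair$truth$window_b)
  # mean flank identity within 4 sigma of 0.9 (binomial on 28 flank bases)
  mean_id <- mean(1 - muts / 28)
  sigma <- sqrt(0.1 * 0.9 / 28 / 30)
  expect_lt(abs(mean_id - 0.9), 4 * sigma)
})

test_that("truth tables round-trip through TSV and BED", {
  m <- sim_psfm()
  cfg <- sim_config(n_planted = 3, seed = 51)
  out <- plant_sites(generate_background(cfg), m, cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_truth(out$truth, tsv, bed, seq_id = "synth")
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$pos, out$truth$pos)
  expect_equal(back$window_seq, out$truth$window_seq)
  bed_tab <- read.table(bed, sep = "\t")
  expect_equal(nrow(bed_tab), 3L)
  expect_true(all(bed_tab$V3 - bed_tab$V2 == 33L))
})
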