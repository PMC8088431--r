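---
title: "Scanning promoters for hypoxia-responsive elements: methods and design"
author: "hrescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning promoters for hypoxia-responsive elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrescan)
```

## The model

Hypoxia-inducible genes are activated by HIF transcription factors binding
short promoter elements whose core consensus is `[A/G]CGTG`. The core alone
is too short to be informative: in a uniform-composition promoter of length
$L$ the expected number of core occurrences per scanned strand is

$$E[\text{hits}] = (L - 4)\,(p_A + p_G)\,p_C\,p_G\,p_T\,p_G,$$

about 21 occurrences in a 5.5-kb window scanned on both strands. The package
therefore scores each candidate on its sequence context: a 33-bp window
spanning 8 bp upstream through 20 bp downstream of the 5-bp core, evaluated
with a position-specific frequency matrix (PSFM). The window probability is
the product of per-position base frequencies,
$P(w) = \prod_i f_i(w_i)$ with pseudocount-regularized frequencies
$f_i(b) = (n_i(b) + p)/(n + 4p)$, reported both raw and normalized by the
maximum attainable product so that the consensus window scores exactly 1.
Windows at or above a normalized-score threshold are *confident* HREs.

Conservation between two species is assessed on the confident windows
themselves: every cross-species pair of confident windows is aligned with an
exact global (Needleman–Wunsch) aligner, and pairs are accepted when
alignment identity reaches a cutoff and the two 5-bp cores are identical
after strand orientation. Accepted pairs are matched one-to-one, greedily in
order of decreasing identity, which yields a discrete list of conserved HRE
regions and prevents one window from claiming several partners.

## Assumptions

* Promoters are supplied as plain nucleotide sequence; no chromatin,
  methylation or expression evidence enters the score.
* The PSFM treats positions independently (no dinucleotide coupling).
* Conservation is judged by sequence identity of the 33-bp windows alone —
  no synteny or positional information is used, which is appropriate at
  large evolutionary distance where promoter architecture rearranges.
* Soft-masked (lowercase) bases are uppercased and scanned; `U` is read as
  `T`; any other character is a hard error rather than a silent `N`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| window geometry | −8/+20 | flank extent around the 5-bp core; fixed (33 bp total) |
| `pseudocount` | 0.5 | added to every base count when building/normalizing a PSFM |
| `threshold` | 0.05 | confidence cutoff on the normalized (consensus = 1) score; closed (ties pass) |
| `strand_mode` | `both` | the RCGTG core is conventionally scanned on both strands; `forward` provided for comparisons |
| `match`/`mismatch`/`gap` | +1/−1/−2 | global-alignment scores (linear gap) |
| `min_identity` | 0.7 | conserved-pair identity cutoff (`find_conserved`); end-gap columns excluded from identity |

The published screen this design follows did not state its probability
cutoff, so the threshold here is an explicit, tunable choice echoed into
every output header; thresholds are defined on the normalized scale so they
transfer between matrices. Whether the original probability covered all 33
positions or the 28 flanks only is likewise unstated; scoring defaults to
all positions, and a `positions` mask (e.g. `c(1:8, 14:33)`) provides
flank-only scoring.

## The synthetic generator

`sim_config()`/`generate_background()`/`plant_sites()`/`make_species_pair()`
emulate a promoter-scale input: an i.i.d. background (default 5,500 bp,
uniform composition, mirroring a −5000/+500 TSS window) with a chosen number
of planted 33-bp HRE windows at recorded, non-overlapping positions
(overwritten in place so coordinates stay stable; positions are drawn
uniformly among valid configurations by an order-statistics transformation,
not by rejection). Two-species pairs share a configurable fraction of sites;
species-B copies have flank bases substituted while the core is preserved.

Two divergence semantics are provided. The default, `divergence_mode =
"exact"`, substitutes exactly `round(28 * flank_divergence)` flank bases per
shared site, so realized flank identity is *controlled* (at divergence 0.1:
identity 30/33 ≈ 0.909 per pair) and recovery experiments measure the
method, not one binomial draw. `"bernoulli"` mutates each flank base
independently with probability `flank_divergence`, which reproduces the
binomial spread of real per-site divergence; the mean-identity property is
tested under this mode.

**Design of the default simulation matrix.** `sim_psfm()` has a sharp core
(position 9 splits A/G evenly; positions 10–13 fixed `CGTG`) and *uniform*
flank rows. This is deliberate. With a product-form normalized score and a
threshold of 0.05 over 33 positions, a matrix position sharp enough to
constrain sampled windows (consensus frequency near 1) necessarily assigns
a mutated base a frequency ratio far below the threshold budget, so no
single matrix can make sampled plantings confident *and* tolerate realistic
flank divergence — the two requirements are mathematically incompatible
position by position. Uninformative flanks resolve this: sampled planted
windows are mutually distinct (their flanks are random), every candidate
window scores 1, and detection, background calibration and conservation
calling can each be studied in isolation. Informative matrices (such as one
built from the bundled synthetic training alignment) are exercised
separately with consensus plantings, where recovery is exact and background
windows essentially never reach the threshold. Sampled windows are redrawn
until they contain a single core occurrence on either strand, so planted
truth is unambiguous — without this, a window containing `GCGTGCGTG` yields
two heavily overlapping candidate windows whose cross-species copies can
masquerade as extra conserved pairs.

What the generator does *not* emulate: CpG islands, TATA positioning,
dinucleotide composition, repeats, and indel divergence. Passing recovery
tests therefore demonstrates correctness of the scanning/scoring/conservation
machinery under the stated model, not expected performance on real
promoters, where background composition and alignment gaps matter.

## Numerical choices

* Ties at the confidence threshold pass (closed threshold).
* PSFM positions must sum to 1 within $10^{-9}$; TSV round-trips preserve
  frequencies to that tolerance. Count rows and frequency rows are
  auto-detected (row sums within $10^{-6}$ of 1 are frequencies).
* Consensus ties break toward the first base in `A < C < G < T` order.
* Alignment traceback prefers diagonal, then up, then left, making outputs
  deterministic; identity excludes end-gap columns; `N` matches nothing.
* Windows containing `N` are kept in the window table, flagged unscorable,
  and excluded from confident counts.
* Boundary windows (core closer than 8 bp to the 5' end or 20 bp to the 3'
  end on the hit strand) are dropped and counted, so
  `n_core_hits = n_windows + n_boundary_dropped` always holds.
* All randomness uses R's default Mersenne-Twister generator; every
  generator function honours a single integer seed in its configuration.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: the core
scanner against whole-5-mer string enumeration (1,000 random kilobases, both
strand modes), the aligner against exhaustive enumeration of all alignments
(all pairs of 1–3-mers exhaustively plus sampled 4–6-mers, three scoring
schemes, and a cross-check against Biostrings' aligner at 33 bp), PSFM
scoring against an independently coded product, background hit counts
against the closed-form expectation (500 sequences, 4σ band), and
planted-site recovery and conserved-pair recovery against recorded truth
(10 consensus plantings in 5.5 kb; 5 shared sites at 10% controlled
divergence with a shared-fraction-0 negative control). These sizes keep the
whole suite under a minute while leaving the statistical bands (4σ) with
comfortable power.

## Known limitations

* The bundled matrix is illustrative and synthetic; reproducing published
  hit counts on real promoters requires the original (unpublished) training
  matrix and threshold, so real-genome comparisons should be reported
  side-by-side rather than expected to match exactly.
* The aligner is quadratic and intended for 33-bp windows, not whole
  promoters.
* Greedy one-to-one pairing is order-dependent in pathological ties; ties
  are broken deterministically (identity, then score, then positions).
* Only two-species comparisons are supported; no phylogenetic weighting.
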