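---
title: "Methods: spatial phylotype mapping and radiotracer DIC assimilation"
author: "symbiospot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial phylotype mapping and radiotracer DIC assimilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiospot)
```

# The problem

A chemosymbiotic clam gill can host two symbiont phylotypes that are
identical over the whole 16S rRNA gene except for a single A/G base.
Mapping where each phylotype sits on the gill therefore requires
single-nucleotide discrimination from short spatially barcoded reads, a
job general spatial-transcriptomics counters are not built for. The second
half of the package quantifies what those symbionts do: the rate at which
the holobiont converts dissolved inorganic carbon (DIC) into biomass,
measured by ¹⁴C-bicarbonate tracer incubations, and how that rate responds
to temperature.

# Spatial phylotyping

## Read model and classification

Read 1 carries a 25-nt coordinate barcode (CID, bases 1–25) and a 10-nt
molecular barcode (MID, bases 26–35); read 2 is a 75-nt 16S fragment.
Demultiplexing (`demuxReads()`) is an exact CID lookup against the chip
mask; unknown CIDs are dropped and counted, never rescued by
mismatch-tolerant matching — with a 25-nt barcode the expected collision
rate under sequencing error is negligible, and the dropped count is
reported so nothing is silently lost.

Classification (`classifyReads()`) is deliberately strict: a read is
phylotype A if and only if it contains the full 47-nt diagnostic window of
the A reference with zero mismatches, G likewise. Reads covering only part
of the window, or carrying any substitution inside it, are `unclassified`.
This mirrors a mapping-based extraction that keeps only uniquely mapped,
completely matched, indel-free 47M alignments, and makes the
classification conservative rather than permissive: a sequencing error can
only demote a read to `unclassified`, except the (rare, rate ≈ e/3 per
read) error at the diagnostic base itself, which flips the call. Because
the two windows differ at exactly one base, no read can ever match both.

An alignment-ingestion path (`classifyAlignments()` on SAM/BAM via
Rsamtools) applies the filter tuple (NH = 1, MAPQ = 255, CIGAR = 47M)
verbatim and calls the phylotype from the read base over the diagnostic
reference position. MAPQ 255 is honoured as given — it is the uniqueness
marker of the aligner this emulates, not a probability. When the NM tag is
present, mismatches at non-diagnostic positions disqualify a record
(a perfect G read aligned to the A reference carries NM = 1, a perfect A
read NM = 0); this restores the "completely matched" semantics that the
filter tuple alone does not capture, and is what makes the two
classification paths agree exactly on indel-free reads — an agreement the
test suite checks.

## Binning, dominance and heterogeneity

Spot coordinates are 0-based with the spot (one DNA-nanoball pitch) as the
unit; bins are indexed by floor division, so `binSize = 20` gives
20 × 20-spot bins ≈ 10 µm, about one cell. A bin is *valid* when its
classified-read total (A + G) is at least `minReads = 180`; the threshold
is inclusive. A valid bin is called for a phylotype when that phylotype's
read fraction *strictly* exceeds `dominance = 0.95`. Strictness matters:
it makes the fraction rule exactly equivalent to the integer count rule
n_A > 19 n_G, which the suite verifies exhaustively over all count pairs
with total ≤ 500 against an integer-arithmetic oracle. The implementation
compares each phylotype's own fraction to the threshold (frac_A > d for A,
frac_G > d for G) rather than mixing `frac_A` with `1 - d`, which keeps
the two boundaries numerically symmetric in floating point.

`summarizeBins()` reports, over valid bins only:

* the single-phylotype share in two senses — *strict* (minor count
  exactly 0) and *dominance* (call not `mixed`) — because "a bin shows
  just one phylotype" is genuinely ambiguous between the two and they can
  differ by several percent;
* a 20-interval histogram of the phylotype-A fraction in 5% steps,
  intervals [0, 0.05), …, [0.95, 1] with the last closed;
* the extreme-bin share, defined as frac_A ≤ 0.05 or ≥ 0.95. This uses
  closed boundaries on both sides (a bin at exactly 19:1 is extreme),
  which differs from the half-open histogram convention only at the exact
  0.05 boundary;
* neighbour discordance: among 4-adjacent pairs of dominant-called bins,
  the fraction whose calls differ. 4-connectivity is the simplest
  adjacency on the bin lattice; 8-connectivity would count diagonal
  contacts and slightly dilute boundary signal. `NaN` when no such pair
  exists.

## Two coordinate conventions

The diagnostic base of the motivating system is described both as "the
590th position" of the 16S gene and via a kept region of 907–953; one
47-nt window cannot satisfy both literally. The package therefore treats
the reference length, diagnostic position and window as free parameters of
`makeReferencePair()` (defaults: 1500 nt, position 930, window 907–953)
and resolves nothing: any consistent (position, window) pair works, and
the tests exercise a short 200-nt reference with window 80–126 for speed.

# Radiotracer kinetics

## Turnover and assimilation

With a fraction *f* = DPM₍POC₎/DPM₍DIC₎ of the tracer recovered in
particulate organic carbon after *t* days, first-order turnover of the DIC
pool gives *k* = −ln(1 − *f*)/*t*. `turnoverK()` evaluates this with
`log1p`, so the small-*f* regime (*f* ~ 10⁻⁵, typical of seawater
incubations) is computed at full double precision; the noise-free
simulation round-trip recovers *k* to relative error below 10⁻¹². *f* ≥ 1
is a per-record error naming the record, not an NaN. Killed-control
subtraction (dpm_poc − control_dpm, floored at 0) is implemented but **off
by default**: the protocol describes killed controls, but not how they
enter the calculation, so blank subtraction is an explicit analyst choice.

The assimilation rate is *k* × [DIC] × 10⁶ × *V* × *norm* in
nmol C clam⁻¹ day⁻¹, with [DIC] in mmol L⁻¹ and *V* in litres. The 10⁶ is
the mmol→nmol conversion and is a named argument (`nmolPerMmol`) rather
than a buried constant: the source formulas print "×10⁻⁶", which taken
literally with these units would yield rates 10¹² times smaller than the
printed means (k = 7.4 × 10⁻⁴ day⁻¹ at [DIC] = 2.64 mmol L⁻¹ must give
29.3 nmol day⁻¹, which it does under the convention used here). The
discrepancy is documented rather than silently patched. Seawater rates are
normalized to 100 ml (`seawaterRate()`), and `equivalenceVolume()` converts
a holobiont rate into the volume of seawater with equal fixation,
100 × clam/seawater ml. Note that the ratio of *mean* rates (29.3 vs 8.43
→ ≈ 348 ml) is not the same quantity as a mean of per-sample pairings.

## Temperature response

`fitTemperatureResponse()` is ordinary least squares on raw polynomial
terms, degree 2 or 3, fit to replicate-level observations when available
and to per-temperature means otherwise. With exactly degree + 1 distinct
temperatures the fit interpolates (the suite requires residuals below
10⁻⁹ of the data scale). Model comparison uses adjusted R² as the primary
criterion with small-sample AICc reported alongside; AICc is `Inf` when
residual degrees of freedom cannot support the correction (e.g. a cubic
through four means), which is honest rather than misleading.

`peakTemperature()` solves the derivative quadratic
c₁ + 2c₂T + 3c₃T² = 0 in closed form and returns the stationary point
with negative second derivative strictly inside the search range. The
quadratic is solved in the numerically stable form (q = −(b +
sign(b)·√disc)/2; roots q/a and c/q), because a cubic fitted to
symmetric-about-centre data has a nearly vanishing leading coefficient and
the naive formula loses the finite root to cancellation. A degenerate
a = 0 falls back to the linear root. `method = "grid"` evaluates the fit
on a 0.001 °C grid as an independent cross-check; the suite requires
agreement within 0.002 °C on the four-mean fit and on 100 random cubics
with interior maxima. On the four mean observations (5, 12, 20, 28 °C),
the cubic's interior maximum lands at

```{r peak}
fit <- fitTemperatureResponse(c(5, 12, 20, 28),
                              c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3), 3)
peakTemperature(fit)
```

# The synthetic-data generator

The generator defines the conditions under which the pipeline is tested;
its defaults are fixed, not tuned.

* **Fields.** `simulateField()` produces either a mosaic of contiguous
  single-phylotype domains (multi-source random region growth from seeded
  spots — contiguity is guaranteed by construction, which the
  connected-component test requires for every seed, and which
  nearest-centre partitions cannot guarantee on a lattice) or a well-mixed
  field with per-spot fractions from Beta(β, β). β = 1000 concentrates
  fractions at 0.5 ± ~0.02, emulating the one observed individual with a
  well-mixed pattern.
* **Reads.** Per-spot totals are Poisson — the source gives no per-spot
  depth distribution, so Poisson is this package's stated assumption, not
  inferred intent. Fragment starts are uniform over the reference, so most
  reads do not cover the diagnostic window and must be rejected
  downstream, as in real capture. Errors are i.i.d. substitutions only:
  the downstream filter discards indel-containing alignments anyway, so
  simulating indels would add nothing testable. Barcodes are emitted
  error-free (a CID error would almost surely miss the mask and be
  dropped, which the drop counter already covers).
* **Incubations.** Expected filter activity is
  DPM₍DIC₎·(1 − e^(−kt)) + b (evaluated with `expm1`), with killed
  controls generated at k = 0 and optional Poisson counting noise.

What the generator does **not** emulate: optics and chemistry of the chip
(nanoball amplification, PCR bias, rRNA depletion), spatial correlation of
sequencing depth, chimeric reads, barcode synthesis errors, quench and
efficiency corrections of scintillation counting. Passing tests therefore
demonstrate the correctness of the computational pipeline under its stated
statistical assumptions, not robustness to every artefact of real
libraries.

# Problem sizes and test design

The suite runs on 100 × 100-spot grids (25 bins of 20 × 20) at a mean of
3 reads per spot with a 200-nt reference, which yields ≈ 200 classified
reads per bin — comfortably above the 180-read validity threshold while
keeping a full end-to-end run in seconds. Planted-field recovery is
evaluated on bins whose spots belong to a single pure domain (bins
straddling a domain boundary have genuinely mixed truth and no planted
call to recover). Monte-Carlo recovery tests size their replicate counts
so that the 5% acceptance band sits at ≥ 3 standard errors of the mean
under Poisson counting noise (e.g. 100 replicates at k = 10⁻³, 5000 at
k = 10⁻⁵), making a seed-dependent false failure a ≥ 3σ event rather than
a coin flip.

# Known limitations

* Sequence-mode classification requires an exact 47-mer match; it does not
  attempt error correction, so throughput (classified fraction) trades off
  against the near-zero misassignment rate. Increasing coverage, not
  relaxing the match, is the intended remedy.
* MID deduplication is available (`dedupMid = TRUE`) but off by default,
  matching a plain mapped-read count; with it on, at most one count per
  (spot, MID, call) survives.
* The rate model is single-pool and first-order: no DIC speciation or pH
  correction, no isotope fractionation, no time-resolved uptake. These are
  outside its scope by design.
* The temperature fit is a descriptive polynomial, not a mechanistic
  thermal-performance model; its peak is an interpolation statement about
  the fitted range and should not be extrapolated.
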