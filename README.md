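# symbiospot

Chemosymbiotic bivalves such as thyasirid clams host sulfur-oxidizing gill
symbionts that fix dissolved inorganic carbon (DIC) and feed the host. Two
questions about such holobionts are surprisingly hard to answer with
standard tooling:

1. **Where is each symbiont lineage on the gill?** When two symbiont
   phylotypes differ at a *single base* of the 16S rRNA gene, standard
   spatial-transcriptomics pipelines cannot tell them apart. symbiospot
   implements single-nucleotide-resolution spatial phylotyping for
   Stereo-seq-style libraries: read 1 carries a 25-nt coordinate barcode
   (CID) and a 10-nt molecular barcode (MID); read 2 carries a 75-nt 16S
   fragment. A read is assigned to phylotype A or G only if it contains
   that phylotype's full 47-nt diagnostic window with **zero mismatches**
   (the sequence-mode equivalent of the alignment filter NH:i:1,
   MAPQ = 255, CIGAR = 47M). Spot counts are aggregated into 20 × 20-spot
   bins (≈10 µm, one cell); bins with ≥ 180 reads are valid; a bin is
   called for a phylotype when its read fraction strictly exceeds 95%
   (equivalently, count ratio A/G > 19).

2. **How much carbon does the holobiont fix?** From a ¹⁴C-bicarbonate
   incubation, the DIC turnover rate constant is

   *k* = −ln(1 − DPM₍POC₎ / DPM₍DIC₎) / *t*   (day⁻¹)

   and the assimilation rate is

   *Assim* = *k* × [DIC] × 10⁶ × *V* × *norm*   (nmol C · clam⁻¹ · day⁻¹)

   with [DIC] in mmol L⁻¹, incubation volume *V* in litres (0.015 for a
   live clam, 0.010 for a gill-homogenate vial) and *norm* the per-clam
   normalization (1 or 4). The temperature response of *k* is fitted with
   quadratic/cubic least squares, and the thermal optimum of the cubic is
   located by the closed-form root of its derivative.

A synthetic-data module simulates both data types — planted two-phylotype
spatial fields with barcoded reads and substitution errors, and
scintillation-counter incubations with Poisson counting noise and killed
controls — so the whole pipeline is testable without any external data.

## Worked example

```r
library(symbiospot)

## --- spatial phylotyping on a simulated mosaic gill section ---
refs  <- makeReferencePair(seed = 1, diagnosticPos = 100,
                           window = c(80, 126), refLength = 200)
truth <- simulateField(100, 100, "domain-mosaic", nDomains = 4, seed = 2)
sim   <- simulateReads(truth, refs, meanReadsPerSpot = 3,
                       errorRate = 0.005, seed = 3)
dmx   <- demuxReads(sim$read1, sim$mask)
calls <- classifyReads(sim$read2[dmx$assigned$read], refs)
table(calls)
#>            A            G unclassified
#>         3633         1893        24846
spots <- accumulateCounts(cbind(dmx$assigned[c("x","y","mid")], call = calls))
bins  <- callBins(binAggregate(spots, binSize = 20, minReads = 180))
table(bins$call)
#> A-dominant G-dominant      mixed
#>         14          6          5
summarizeBins(bins)$extremeFraction
#> [1] 0.8
```

Most reads are `unclassified` because fragments are drawn uniformly along
the reference and only those spanning the full 47-nt window are eligible —
exactly the behaviour of the mapping-based extraction this emulates. 80%
of valid bins sit in the extreme frequency intervals (≤ 5% or ≥ 95%
phylotype A), the signature of spatially segregated single-phylotype
domains.

```r
## --- radiotracer kinetics ---
k <- turnoverK(dpm_poc = 53.08, dpm_dic = 3.7e4, t_days = 1.94)
signif(k, 3)                      # 0.00074 per day
assimRate(k, dic_mmol_per_l = 2.64)   # 29.3 nmol C per clam per day
equivalenceVolume(assimRate(k, 2.64), 8.43)   # ~348 ml of seawater

fit <- fitTemperatureResponse(c(5, 12, 20, 28),
                              c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3), 3)
peakTemperature(fit)              # 14.75 degrees C
ratioToMax(c(5, 12, 20, 28),
           c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3))[["28"]]  # 69 (%)
```

A turnover constant of 7.4 × 10⁻⁴ day⁻¹ at a DIC concentration of
2.64 mmol L⁻¹ corresponds to 29.3 nmol C fixed per clam per day — the
carbon fixation of roughly 350 ml of the surrounding seawater (at a
seawater rate of 8.43 nmol C · 100 ml⁻¹ · day⁻¹). The cubic temperature
response peaks at 14.75 °C and falls to 69% of its maximum by 28 °C.

## Pipeline entry points and CLI

`runSimulate()`, `runPhylotype()` and `runRates()` orchestrate the stages
over files, each writing TSV/JSON outputs plus a JSON manifest with
parameters, seed and stage counters. A thin command-line wrapper is
installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/symbiospot.R", package="symbiospot"))') \
    simulate --out outdir --seed 1 --grid 40x40 --n-domains 4
# ... phylotype --r1 ... --r2 ... --mask ... --refs ... --out outdir
# ... rates --incubations file.tsv --out outdir
```

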