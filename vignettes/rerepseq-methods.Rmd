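---
title: "Rerep-Seq: model, normalization chain, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rerep-Seq: model, normalization chain, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rerepseq)
```

## The problem and the measurement principle

DNA rereplication — re-firing of replication origins within one cell
cycle — produces regions of extra DNA copies that are hard to detect
against the background of normal replication. Rerep-Seq exploits
semiconservative replication and strand-specific labeling to fragment
*only* DNA that has replicated at least twice in the presence of the
thymidine analog BrdU:

1. Each replication pass leaves BrdU in the nascent strand only. DNA
   that has replicated once in BrdU carries the label on one strand;
   DNA that has replicated twice (or rereplicated) carries it on both.
2. UVA photolysis converts incorporated BrdU to uracil; UDG excises it
   and APE1 nicks the abasic site. Nicks therefore occur only on
   labeled strands.
3. Two nicks on *opposite* strands within a short offset form a
   staggered double-strand break. Single-labeled DNA accumulates nicks
   on one strand only and stays intact; double-labeled DNA shatters.
4. Gel extraction of 0.1–3 kb fragments selects the shattered
   (double-labeled) material for qPCR or sequencing.

The package implements this chemistry as a generative model
(`replicatePopulation()`, `digestMolecule()`, `sizeSelect()`,
`fragmentsToTrack()`), the normalization chain used for the resulting
coverage tracks, the replication-timing analyses, and the qPCR
arithmetic.

## The generative model

### Labeling through cell cycles

A `LabelSchedule` is a list of S-phases. Complete phases replicate the
whole genome; a sampled phase at time $t$ replicates position $x$ iff

$$\min_o\left(\text{firingTime}(o) + |x - \text{pos}(o)|/v\right) \le t,$$

with $v$ the fork speed — forks move outward from each origin at
constant speed from its firing time. The semiconservative rule is exact
population bookkeeping: each pass turns a duplex into two daughters,
each keeping one parental strand, nascent strands labeled over exactly
the region replicated while BrdU was present. After $n$ synchronous
complete cycles in BrdU the double-labeled duplex fraction is
$1 - 2^{1-n}$ (0, 1/2, 3/4 for 1, 2, 3 cycles): a duplex is
double-labeled iff its retained parental strand was itself synthesized
in a labeled cycle.

Two simplifications are deliberate. First, for an interrupted S-phase
the unreplicated flanks of a partially replicated chromosome are
carried by *both* daughters. This inflates the copy number of
unreplicated DNA (which is unlabeled on at least one strand and
therefore never fragments) but keeps every molecule a simple
whole-chromosome duplex; no measured quantity depends on it. If
nothing has replicated at sampling time the molecule passes through
unchanged. Second, cells following a deterministic schedule are all
identical, so the population is stored as distinct molecule types with
copy counts; digestion still treats every physical copy independently.

The mitochondrial contig is emitted fully double-labeled in every cell
(default 50 copies/cell): mitochondrial DNA turns over continuously
regardless of cell-cycle position, which is what makes it the internal
control for normalization.

Rereplication is modeled through `rerepDomains`: regions that fire a
second time within the final phase, each adding one extra fully
double-labeled copy per cell.

### Fragmentation chemistry

`DigestParams` collapses the experimental dials (UVA dose, digestion
time) into a single per-site nick probability `pNick`, applied to
labelable sites drawn per labeled bp at `labelableDensity` (default
0.3, a thymidine-frequency proxy; the combined per-bp nick rate is
their product). The experimental dose–response is only characterized
empirically on gels, so no attempt is made to model minutes of UVA or
hours of digestion mechanistically.

Opposed nicks within `dsbMaxOffset` bp (default 16 bp, a conventional
closely-opposed-nick scale; the chemistry literature does not pin a
single number) become double-strand breaks. Pairing is greedy
left-to-right with each nick used at most once — deterministic and
testable; alternatives such as all-pairs matching change fragment
counts only at high nick density. The break sits at the rounded-down
midpoint of the pair. Fragments are the segments between consecutive
breaks; molecule ends are not breaks, so terminal segments are flagged
and excluded by size selection, which keeps internal fragments of
100–3000 bp (flat recovery across the window; gels do not report a
within-window preference).

With the defaults, fully double-labeled DNA yields size-selected
fragments averaging roughly 550 bp — inside the method's 300–600 bp
operating range — while single-labeled DNA yields exactly zero
internal fragments at any `pNick`, which is the method's defining
selectivity.

## Normalization chain

`rerepPipeline()` fixes the order: RPM → mitochondrial scaling →
binning → blacklist construction from the baseline condition →
blacklist application → smoothing → replicate averaging.

* **RPM**: values scaled by $10^6/\text{total units}$ (aligned reads,
  or retained fragments in simulation).
* **Mitochondrial scaling**: sample $s$ with mitochondrial mass
  fraction $f_s$ is scaled by $\bar f / f_s$. Since a global factor
  cannot change a track's internal fraction, the equalized quantity is
  the scaled mitochondrial mass relative to each sample's pre-scaling
  total — the meaningful "same amount of mitochondrial DNA per library
  unit" statement. The mean fraction (rather than a designated
  reference sample) is used for symmetry.
* **Binning**: bins tile each chromosome from 0 at a fixed width (last
  bin truncated), so the grid depends only on genome and width and is
  identical across samples. The bin value is the length-weighted mean
  per-bp density (not the sum), keeping units invariant under
  re-binning; mass $\sum v_i w_i$ is conserved exactly.
* **Blacklist**: regions of artifactually high baseline signal are
  maximal runs of bins whose baseline-average value strictly exceeds
  $\mu + \sigma$ (population SD) over non-mitochondrial bins. The rule
  is evaluated at bin resolution — the only resolution at which "one
  standard deviation over the average genomic signal" is well defined —
  built from the baseline (time-point-0) replicates only, and applied
  to every sample. Mitochondrial bins are excluded from $\mu, \sigma$
  and can never be blacklisted. Masked bins become missing, and
  missing means *excluded*, not zero, so smoothing is not dragged down
  at blacklist edges.
* **Smoothing**: centered moving average, window coerced up to an odd
  multiple of the bin width; bins within half a window of a chromosome
  end pass through unsmoothed (values are still needed at chromosome
  ends for heatmaps), and fully-missing windows stay missing.
  Defaults follow the yeast-scale convention (100 bp bins, 10 kb
  window); a human-scale analysis would use 1 kb / 100 kb.
* **Averaging and QC**: per-condition bin means (missing anywhere →
  missing), with pairwise Spearman rank correlations of replicates as
  the reproducibility statistic.

## Timing-domain analyses

`classifyTimingRegions()` takes a replication-timing profile on the
published 0–2 scale (2 = replicated, 1 = not replicated) and returns
maximal runs of bins at or above the 75th / at or below the 25th
percentile (linear-interpolation percentiles, inclusive thresholds) as
early/late regions. `featureHeatmap()` builds the origin-centered
±flank matrix sorted by row sum (ties broken by feature id).
`extendDomainsToTzMidpoints()` moves each early/late-domain boundary
to the midpoint of the adjoining transition zone, or leaves it at the
chromosome edge; `scaledDomainProfile()` then resamples each extended
domain to 0–100% relative coordinates by linear interpolation between
bin centers, making 10 kb and 10 Mb domains comparable rows of one
matrix.

`enrichmentScore()` is the classic unweighted running-sum statistic:
walking the signal-ranked domain list, members of the query set add
$1/|Q|$ and non-members subtract $1/(N-|Q|)$; the score is the extreme
of largest magnitude, and significance comes from label permutations
(add-one smoothing, two-sided on $|ES|$). The walk is accumulated in
integers (hits $+(N-|Q|)$, misses $-|Q|$, rescaled at the end), so
magnitude ties are exact and resolve deterministically to the positive
extreme. The unweighted variant with label permutation was chosen
because the external enrichment tools' weighting and permutation
settings are not part of this package's contract; exact numeric
agreement with any external program is not claimed. Two calibration
caveats are worth knowing: (i) for short ranked lists the discrete
walk ties with its own permutation null at rate
$\sim 1/\sqrt{|Q|(N-|Q|)}$, making the tie-inclusive p-value visibly
conservative — a property of permutation tests on coarse statistics
generally, which disappears at gene-list scale ($N$ in the thousands);
(ii) a rank correlation over ~20 origins has a null sd of ~0.23, so
"no separation" controls should be read against that spread.

## qPCR arithmetic

Technical triplicates are averaged to one Cq per sample and target;
quantity is $2^{-C_q}$, normalized within-sample by the mitochondrial
amplicon: $2^{C_q^{\text{mito}} - C_q^{\text{target}}}$ (both
quantities on the $2^{-C_q}$ scale; the ratio is invariant to adding a
constant to both Cq values). Folds are relative to the baseline
sample, with mean ± SEM over biological replicates. The packaged
amplicon table stores the seven standard primer pairs with 1-based
inclusive coordinates — the only convention consistent with every
declared amplicon length (e.g. yeast ACT1 chrVI:54267–54341 = 75 bp,
human hCOX2 chrM:7399–7487 = 89 bp); primer sequences are validated
against the DNA alphabet but not aligned (no genome sequences ship
with the package). `simulatedQpcrSignal()` bridges simulated coverage
to the same read-out as mean target coverage over mean normalizer
coverage.

## Packaged study conditions

The demo conditions are fixed, not tunable knobs:

* Genome: two 500 kb chromosomes + 6 kb `chrM` — compact enough for
  desk-scale runs while preserving realistic ~50 kb origin spacing and
  a high-copy mitochondrial control.
* Origins: 10 per chromosome, firing times 0–19 min assigned in an
  interleaved spatial order (no early/late position confound), fork
  speed 1 kb/min.
* Timing time-course: one complete BrdU pre-label cycle, then a second
  S-phase sampled at 0, 22, 30, 45 min (22 min is the earliest time at
  which every origin has fired, so all 20 per-origin signals are
  informative), 3 replicates × 200 cells.
* Multi-cycle control: three *complete* BrdU cycles. A partial
  asynchronous final cycle layered on top would itself recreate a
  small early-region bias (the very signal the control is meant to
  lack), because the residual single-labeled quarter of the population
  gains double-labeling early-first; the fully-labeled control is the
  state the experiment is meant to represent. An asynchronous
  uniform-sampling mode exists for other uses.
* Rereplication scenario: BrdU present during a G1 arrest in which two
  100 kb domains (20% of the nuclear genome, each spanning an early
  and a late origin and a TAD boundary) re-fire; the background genome
  does not replicate.
* Per-origin signal windows are ±25 kb, the method's standard
  origin-centered window; at the earliest sampling time a narrower
  window saturates over early origins and discards their ordering.

Problem sizes throughout (200 cells, 1 Mb genome, 100 bp bins) were
chosen so a full replicated time-course simulates in about a minute on
one CPU.

## What the simulator does and does not emulate

Simulated tracks have replication-timing-structured coverage,
replicate-to-replicate digestion noise, and a dominant stable
mitochondrial control — the features the normalization chain and
timing analyses operate on. They do **not** include sequencing error,
PCR duplication, GC or mappability bias, diploidy, or real genome
coordinates; passing tests therefore demonstrate the correctness and
calibration of the method's logic, not robustness to those artifacts.
The baseline (time-point-0) samples carry no nuclear signal beyond
what leaks through digestion, so the demo blacklist is typically
empty; the blacklist rule itself is exercised separately on fixtures
with planted hot regions.

## Numerical conventions

All file formats are 0-based half-open (bedGraph/BED); in memory the
analysis side uses the standard 1-based closed `GRanges` containers
and the readers/writers do the conversion. bedGraph values are written
with 6 significant digits; comparisons are numeric, never textual. The
qPCR table alone is 1-based inclusive, converted internally. All
randomness flows from user-supplied seeds; every simulation is
bit-for-bit reproducible given the seed.
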