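# rerepseq

Simulation and analysis of **Rerep-Seq**, a sequencing method that
detects DNA rereplication — origins firing more than once in a single
cell cycle — by *selective fragmentation of DNA labeled with BrdU on
both strands*.

## Who this is for

Researchers working on replication licensing, origin firing and
rereplication who want to (a) analyze Rerep-Seq coverage tracks with
the method's normalization and timing-domain statistics, or (b) study
the method's behavior itself — what it can and cannot enrich, under
fully controlled synthetic conditions with known ground truth.

## The method in brief

Semiconservative replication puts BrdU only in nascent strands, so:

* replicated once in BrdU → one labeled strand,
* replicated ≥ twice (or rereplicated) → both strands labeled.

UVA photolysis + UDG/APE1 convert incorporated BrdU to single-strand
nicks. Nicks on opposite strands within a small offset (≤ 16 bp by
default) form staggered double-strand breaks, so only *double-labeled*
DNA shatters; gel size selection (0.1–3 kb) then recovers exactly that
material. After n complete labeled cycles the double-labeled duplex
fraction is `1 − 2^(1−n)` (0, 1/2, 3/4, ...), which is why enrichment
needs at least two passes through S-phase — or rereplication.

Coverage is normalized as RPM, scaled by each sample's mitochondrial
signal fraction (mitochondrial DNA replicates continuously and is
always double-labeled — a built-in internal control), masked with a
baseline-derived blacklist (bins > mean + 1 SD in time-point-0
samples), binned (100 bp), smoothed (10 kb centered window), and
averaged over replicates with Spearman reproducibility QC. Timing
analyses classify early/late regions as top/bottom quartiles of a 0–2
replication-timing profile, build origin-centered ±25 kb heatmaps and
size-normalized (0–100%) domain profiles, and quantify early-domain
enrichment with an unweighted running-sum enrichment score (hits
+1/|Q|, misses −1/(N−|Q|); permutation p-values).

## Worked example

Simulate the synchronized timing experiment (one complete BrdU
pre-label cycle, second S-phase harvested at 22 min) with replicates,
run the full normalization pipeline, and ask whether per-origin signal
recovers the known firing order:

```r
library(rerepseq)
genome  <- demoGenome()           # chrI+chrII (500 kb each) + 6 kb chrM
origins <- demoOrigins()          # 20 origins, firing times 0-19 min

schedules <- list(t0 = timingSchedule(0), t22 = timingSchedule(22))
samples <- simulateExperiment(genome, origins, schedules,
                              nReplicates = 2, nCells = 50, seed = 42)
res <- rerepPipeline(samples, binWidth = 100, smoothWindow = 10000)
res$spearman
#>   condition  sampleA  sampleB  spearman
#> 1        t0  t0_rep1  t0_rep2 0.9999999
#> 2       t22 t22_rep1 t22_rep2 0.9800170

tr <- timingRecovery(res$averaged$t22, origins, seed = 1)
tr$rho                       # Spearman(per-origin signal, firing time)
#> [1] -1
c(tr$es, tr$pValue)          # early-origin enrichment score and p-value
#> [1] 1.000000000 0.000999001

head(tr$table[order(tr$table$firingTime), ], 5)
#>     originId chrom    pos firingTime   signal
#>   chrI_ori01  chrI  25000          0 2241.036
#>  chrII_ori07 chrII 325000          1 2170.192
#>   chrI_ori06  chrI 275000          2 2070.992
#>  chrII_ori02 chrII  75000          3 1957.142
#>   chrI_ori03  chrI 125000          4 1843.545
```

Replicates agree (Spearman 0.98 at t22); per-origin signal ranks
perfectly anti-correlate with firing time (ρ = −1): the earlier an
origin fires, the more double-labeled DNA surrounds it at harvest. The
early-origin set is maximally enriched at the top of the signal
ranking (ES = 1) with the smallest p-value 1000 permutations can give.

The labeling algebra and the packaged qPCR amplicon table are exact:

```r
doubleLabeledFraction(
  replicatePopulation(genome, origins, multiCycleSchedule(2), nCells = 10))
#> [1] 0.5
all(validateAmplicons(ampliconTable())$length_ok)   # 75,63,109,73,60,111,89 bp
#> [1] TRUE
```

A command-line front end (`inst/scripts/rerepseq.R`) wraps the same
functions (`demo`, `simulate`, `pipeline`, `qpcr` subcommands).

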