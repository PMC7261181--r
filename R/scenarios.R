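#' @include genome.R
#' @include simulate.R
#' @include binning.R
NULL

# Packaged synthetic study conditions: a compact yeast-like genome with
# staggered-firing origins, the synchronized timing time-course, the
# fully-labeled multi-cycle control, and the licensing-bypass
# rereplication scenario. These defaults ARE the simulated experimental
# conditions; they are deliberately fixed.

#' Packaged yeast-like demo genome
#'
#' Two 500 kb nuclear chromosomes plus a 6 kb mitochondrial contig
#' (`chrM`), compact enough for desk-scale simulation while keeping
#' realistic origin spacing (~50 kb) and a high-copy mitochondrial
#' internal control.
#'
#' @return A [RerepGenome-class].
#' @export
demoGenome <- function() {
  RerepGenome(c(chrI = 500000, chrII = 500000, chrM = 6000), "chrM")
}

#' Packaged origin map: 20 origins with staggered firing times
#'
#' Ten origins per nuclear chromosome every 50 kb, firing times 0-19
#' minutes assigned in a fixed interleaved order so that early and late
#' origins alternate along each chromosome (no spatial confound), fork
#' speed 1 kb/min.
#'
#' @return An [OriginMap-class].
#' @export
demoOrigins <- function() {
  pos <- 25000 + (0:9) * 50000
  ftI <- c(0, 12, 4, 16, 8, 2, 14, 6, 18, 10)
  ftII <- c(11, 3, 15, 7, 19, 9, 1, 13, 5, 17)
  OriginMap(chrom = rep(c("chrI", "chrII"), each = 10),
            pos = c(pos, pos), firingTime = c(ftI, ftII),
            forkSpeed = 1000)
}

#' Origins as a GRanges with firing times
#'
#' One 1 bp range per origin with `label` = origin id and `score` =
#' firing time; convenient for heatmaps and per-origin signal windows.
#'
#' @param origins an [OriginMap-class].
#' @param genome a [RerepGenome-class].
#' @return A `GRanges`.
#' @export
originsAsGRanges <- function(origins, genome) {
  tab <- originTable(origins)
  gr <- GenomicRanges::GRanges(tab$chrom,
          IRanges::IRanges(start = tab$pos + 1, width = 1),
          seqinfo = genomeSeqinfo(genome))
  gr$label <- sprintf("%s_ori%02d", tab$chrom,
                      stats::ave(seq_len(nrow(tab)), tab$chrom,
                                 FUN = seq_along))
  gr$score <- tab$firingTime
  gr
}

#' Synchronized pre-label / second-S-phase schedule
#'
#' One complete cycle in BrdU labels one strand of every duplex
#' (pre-label); the second S-phase, also in BrdU, is harvested at `t`
#' minutes after release, so regions replicated by `t` have acquired BrdU
#' on both strands and become fragmentable.
#'
#' @param t sampling time in minutes of the second S-phase.
#' @return A [LabelSchedule-class].
#' @export
timingSchedule <- function(t) {
  LabelSchedule(list(cyclePhase(TRUE, "complete"), cyclePhase(TRUE, t)))
}

#' Fully-labeled multi-cycle control schedule
#'
#' `n` complete cycles in BrdU. After three or more cycles most DNA is
#' double-labeled genome-wide (fraction `1 - 2^(1-n)`), so fragmentation
#' no longer distinguishes early from late regions and no
#' timing-dependent enrichment should appear.
#'
#' @param n number of complete BrdU cycles (default 3).
#' @return A [LabelSchedule-class].
#' @export
multiCycleSchedule <- function(n = 3) {
  LabelSchedule(rep(list(cyclePhase(TRUE, "complete")), n))
}

#' Packaged rereplicating domains (20% of the nuclear genome)
#'
#' Two 100 kb domains, each spanning one early- and one late-firing
#' origin and crossing a packaged TAD boundary, emulating broad
#' licensing-bypass rereplication domains.
#'
#' @param genome a [RerepGenome-class].
#' @return A `GRanges`.
#' @export
demoRerepDomains <- function(genome = demoGenome()) {
  gr <- GenomicRanges::GRanges(c("chrI", "chrII"),
          IRanges::IRanges(start = c(150001, 300001),
                           end = c(250000, 400000)),
          seqinfo = genomeSeqinfo(genome))
  gr$label <- c("rerep_1", "rerep_2")
  gr
}

#' Packaged TAD annotation
#'
#' Fixed 120 kb topological domains tiling each nuclear chromosome; used
#' only as a boundary overlay for rereplication domains.
#'
#' @param genome a [RerepGenome-class].
#' @return A `GRanges` with `label` column.
#' @export
demoTads <- function(genome = demoGenome()) {
  lens <- chromLengths(genome)
  nuclear <- setdiff(chromNames(genome), mitoName(genome))
  pieces <- lapply(nuclear, function(chrom) {
    starts <- seq(1, lens[[chrom]], by = 120000)
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = starts,
                       end = pmin(starts + 120000 - 1, lens[[chrom]])))
    gr$label <- sprintf("%s_tad%d", chrom, seq_along(gr))
    gr
  })
  out <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlevels(out) <- chromNames(genome)
  GenomeInfoDb::seqinfo(out) <- genomeSeqinfo(genome)
  out
}

#' Synthetic replication-timing profile on the 0-2 scale
#'
#' Derived from the origin map: per bin, the replication time is the
#' minimum over origins of `firingTime + distance / forkSpeed`, linearly
#' rescaled so the earliest-replicating bin scores 2 (replicated) and the
#' latest 1 (not replicated), matching the published scale convention.
#' Mitochondrial bins are left missing.
#'
#' @param genome a [RerepGenome-class].
#' @param origins an [OriginMap-class].
#' @param binWidth bin width in bp.
#' @return A [BinnedTrack-class] timing profile.
#' @export
demoTimingProfile <- function(genome = demoGenome(),
                              origins = demoOrigins(), binWidth = 1000) {
  lens <- chromLengths(genome)
  tab <- originTable(origins)
  v <- forkSpeed(origins)
  vals <- lapply(chromNames(genome), function(chrom) {
    n <- ceiling(lens[[chrom]] / binWidth)
    if (chrom == mitoName(genome)) return(rep(NA_real_, n))
    centers <- (seq_len(n) - 0.5) * binWidth
    o <- tab[tab$chrom == chrom, , drop = FALSE]
    tRep <- vapply(centers, function(x)
      min(o$firingTime + abs(x - o$pos) / v), 0)
    tRep
  })
  allT <- unlist(vals, use.names = FALSE)
  rng <- range(allT, na.rm = TRUE)
  vals <- lapply(vals, function(tv)
    2 - (tv - rng[1]) / (rng[2] - rng[1]))
  names(vals) <- chromNames(genome)
  new("BinnedTrack", binWidth = as.integer(binWidth), values = vals,
      genome = genome, sampleId = "timing_profile")
}

#' Early-origin query set from the packaged origin map
#'
#' Origins with firing time below the median are "early".
#'
#' @param origins an [OriginMap-class].
#' @param genome a [RerepGenome-class].
#' @return Character vector of early origin ids (as in
#'   [originsAsGRanges()]).
#' @export
earlyOriginIds <- function(origins = demoOrigins(),
                           genome = demoGenome()) {
  gr <- originsAsGRanges(origins, genome)
  gr$label[gr$score < stats::median(gr$score)]
}

#' Simulate a replicated multi-sample Rerep-Seq experiment
#'
#' Generates one sample per (condition, replicate): for the synchronized
#' timing time-course each condition is a sampling time of the second
#' S-phase; arbitrary schedules can be supplied instead. Replicates share
#' the labeling schedule and differ only in digestion randomness.
#'
#' @param genome a [RerepGenome-class].
#' @param origins an [OriginMap-class].
#' @param schedules named list of [LabelSchedule-class] objects (names =
#'   condition ids).
#' @param nReplicates replicates per condition.
#' @param nCells cells per sample.
#' @param params a [DigestParams-class].
#' @param seed base RNG seed; per-sample seeds are derived from it.
#' @param mitoCopies mitochondrial copies per cell.
#' @return List of samples, each `list(track, totalUnits, condition,
#'   replicate, sampleId, meanFragmentLength)`.
#' @export
simulateExperiment <- function(genome, origins, schedules,
                               nReplicates = 3, nCells = 200,
                               params = DigestParams(), seed = 1,
                               mitoCopies = 50) {
  samples <- list()
  i <- 0L
  for (cond in names(schedules)) {
    for (rep in seq_len(nReplicates)) {
      i <- i + 1L
      sid <- sprintf("%s_rep%d", cond, rep)
      sim <- simulateSample(genome, origins, schedules[[cond]], nCells,
                            params, seed = (seed * 1000L + i) %% .Machine$integer.max,
                            sampleId = sid, mitoCopies = mitoCopies)
      samples[[sid]] <- list(track = sim$track,
                             totalUnits = max(sim$nFragments, 1L),
                             condition = cond, replicate = rep,
                             sampleId = sid,
                             meanFragmentLength = sim$meanFragmentLength)
    }
  }
  samples
}
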