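#' @include genome.R
#' @include binning.R
#' @include normalize.R
#' @include domains.R
NULL

# The full normalization/analysis chain, in the fixed order:
# RPM -> mitochondrial scaling -> binning -> blacklist construction from
# the baseline condition -> blacklist application -> smoothing ->
# replicate averaging. The blacklist is built at bin resolution (the only
# resolution at which the mean + 1 SD rule is well defined) from the
# baseline samples only, and applied to every condition.

#' Run the Rerep-Seq normalization pipeline on a set of samples
#'
#' @param samples list of samples as produced by [simulateExperiment()]
#'   or assembled by hand: each `list(track, totalUnits, condition,
#'   replicate, sampleId)`.
#' @param binWidth bin width in bp (yeast-scale default 100).
#' @param smoothWindow smoothing window in bp (yeast-scale default
#'   10000).
#' @param baselineCondition condition whose replicates define the
#'   blacklist (default: first condition in `samples`, conventionally the
#'   time-point-0 samples).
#' @return List with `normalized` (per-sample [CoverageTrack-class]),
#'   `binned`, `smoothed` (per-sample [BinnedTrack-class]), `averaged`
#'   (per-condition [BinnedTrack-class]), `blacklist` (`GRanges`),
#'   `spearman` (replicate QC data.frame), `mitoFactors`, and the
#'   parameters used.
#' @export
rerepPipeline <- function(samples, binWidth = 100, smoothWindow = 10000,
                          baselineCondition = NULL) {
  if (!length(samples))
    rerepError("no samples", "rerepError_noTracks")
  conditions <- vapply(samples, function(s) s$condition, "")
  if (is.null(baselineCondition)) baselineCondition <- conditions[[1]]
  if (!baselineCondition %in% conditions)
    rerepError(paste0("baseline condition '", baselineCondition,
                      "' has no samples"), "rerepError_missingBaseline")
  # RPM then mitochondrial scaling (jointly across all samples)
  rpm <- lapply(samples, function(s) rpmNormalize(s$track, s$totalUnits))
  scaled <- mitoScale(rpm)
  # binning on the common grid, blacklist from baseline replicates
  binned <- lapply(scaled, binTrack, width = binWidth)
  blacklist <- makeBlacklist(binned[conditions == baselineCondition])
  masked <- lapply(binned, applyBlacklist, blacklist = blacklist)
  smoothed <- lapply(masked, smoothTrack, window = smoothWindow)
  # replicate QC and averaging per condition
  qc <- list()
  averaged <- list()
  for (cond in unique(conditions)) {
    reps <- smoothed[conditions == cond]
    if (length(reps) > 1) {
      pairs <- utils::combn(length(reps), 2)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        qc[[length(qc) + 1L]] <- data.frame(
          condition = cond,
          sampleA = names(reps)[a], sampleB = names(reps)[b],
          spearman = replicateSpearman(reps[[a]], reps[[b]]))
      }
    }
    averaged[[cond]] <- averageReplicates(reps, sampleId = cond)
  }
  list(normalized = scaled, binned = binned, smoothed = smoothed,
       averaged = averaged, blacklist = blacklist,
       spearman = if (length(qc)) do.call(rbind, qc) else
         data.frame(condition = character(0), sampleA = character(0),
                    sampleB = character(0), spearman = numeric(0)),
       mitoFactors = attr(scaled, "factors"),
       params = list(binWidth = binWidth, smoothWindow = smoothWindow,
                     baselineCondition = baselineCondition))
}

#' Per-origin signal in a window around each origin
#'
#' Mean signal of the averaged track over `pos +/- flank` for every
#' origin, alongside its firing time; the basis of the timing-recovery
#' statistics.
#'
#' @param binned a [BinnedTrack-class] (typically a condition average).
#' @param origins an [OriginMap-class].
#' @param genome a [RerepGenome-class].
#' @param flank window half-width in bp.
#' @return data.frame `(originId, chrom, pos, firingTime, signal)`.
#' @export
originSignalTable <- function(binned, origins,
                              genome = binned@genome, flank = 25000) {
  gr <- originsAsGRanges(origins, genome)
  win <- GenomicRanges::resize(gr, width = 2 * flank, fix = "center")
  win <- GenomicRanges::trim(win)
  ranked <- rankDomains(binned, win)
  tab <- originTable(origins)
  idx <- match(ranked$domainId, gr$label)
  data.frame(originId = ranked$domainId,
             chrom = tab$chrom[idx], pos = tab$pos[idx],
             firingTime = tab$firingTime[idx],
             signal = ranked$meanSignal)
}

#' Timing-recovery statistics for one condition average
#'
#' Computes (a) the Spearman correlation between per-origin signal and
#' origin firing time (expected strongly negative early in a synchronized
#' second S-phase: the earlier the origin fires, the more double-labeled
#' DNA surrounds it) and (b) the enrichment score of the early-origin set
#' on the signal-ranked origin list with its permutation p-value.
#'
#' @param avgTrack a [BinnedTrack-class] condition average.
#' @param origins an [OriginMap-class].
#' @param earlySet character vector of early origin ids; default: firing
#'   time below the median.
#' @param flank per-origin window half-width in bp.
#' @param nPermutations permutations for the enrichment p-value.
#' @param seed RNG seed for the permutations.
#' @return List with `rho`, `es`, `pValue`, and the per-origin `table`.
#' @export
timingRecovery <- function(avgTrack, origins, earlySet = NULL,
                           flank = 25000, nPermutations = 1000,
                           seed = 1) {
  tab <- originSignalTable(avgTrack, origins, flank = flank)
  if (is.null(earlySet))
    earlySet <- tab$originId[tab$firingTime <
                               stats::median(tab$firingTime)]
  rho <- cor(tab$signal, tab$firingTime, method = "spearman")
  ranked <- data.frame(domainId = tab$originId,
                       meanSignal = tab$signal)
  es <- enrichmentScore(ranked, earlySet, nPermutations, seed = seed)
  list(rho = rho, es = es$es, pValue = es$pValue, table = tab)
}

#' Mean signal inside versus outside a set of domains
#'
#' Length-weighted mean of non-missing bins inside the domains and over
#' the rest of the nuclear genome; used to quantify rereplication-domain
#' enrichment.
#'
#' @param binned a [BinnedTrack-class].
#' @param domains `GRanges` of domains.
#' @return List with `inside`, `outside`, `fold`.
#' @export
domainSignalContrast <- function(binned, domains) {
  genome <- binned@genome
  nuclear <- setdiff(chromNames(genome), mitoName(genome))
  insideSum <- 0; insideW <- 0; outsideSum <- 0; outsideW <- 0
  for (chrom in nuclear) {
    v <- binned@values[[chrom]]
    bins <- .binRanges(genome, binned@binWidth, chrom)
    dom <- domains[as.character(GenomeInfoDb::seqnames(domains)) == chrom]
    inDom <- IRanges::overlapsAny(bins, IRanges::ranges(dom))
    wdt <- IRanges::width(bins)
    ok <- !is.na(v)
    insideSum <- insideSum + sum(v[ok & inDom] * wdt[ok & inDom])
    insideW <- insideW + sum(wdt[ok & inDom])
    outsideSum <- outsideSum + sum(v[ok & !inDom] * wdt[ok & !inDom])
    outsideW <- outsideW + sum(wdt[ok & !inDom])
  }
  inside <- if (insideW > 0) insideSum / insideW else NA_real_
  outside <- if (outsideW > 0) outsideSum / outsideW else NA_real_
  list(inside = inside, outside = outside,
       fold = if (!is.na(outside) && outside > 0) inside / outside else
         Inf)
}

#' High-signal runs of a binned track
#'
#' Maximal runs of adjacent non-missing bins whose value is strictly
#' greater than `mean + k * SD` of the non-missing nuclear bins; used to
#' delimit candidate rereplication domains and intersect them with
#' timing/TAD annotations.
#'
#' @param binned a [BinnedTrack-class].
#' @param k SD multiplier (default 1).
#' @return `GRanges` of runs, with the threshold in `attr(,
#'   "threshold")`.
#' @export
highSignalRuns <- function(binned, k = 1) {
  genome <- binned@genome
  nuclear <- setdiff(chromNames(genome), mitoName(genome))
  pooled <- unlist(binned@values[nuclear], use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  thr <- mean(pooled) + k * sqrt(mean((pooled - mean(pooled))^2))
  pieces <- lapply(nuclear, function(chrom) {
    v <- binned@values[[chrom]]
    hot <- !is.na(v) & v > thr
    if (!any(hot)) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(which(hot), width = 1L))
    w <- binned@binWidth
    len <- chromLengths(genome)[[chrom]]
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = (IRanges::start(r) - 1L) * w + 1L,
                       end = pmin(IRanges::end(r) * w, len)))
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  out <- if (length(pieces)) suppressWarnings(do.call(c, pieces)) else
    GenomicRanges::GRanges()
  GenomeInfoDb::seqlevels(out) <- chromNames(genome)
  GenomeInfoDb::seqinfo(out) <- genomeSeqinfo(genome)
  out <- GenomicRanges::sort(out)
  attr(out, "threshold") <- thr
  out
}

#' Count annotation boundaries crossed by intervals
#'
#' A boundary of an annotation interval is "crossed" if it falls strictly
#' inside one of the query intervals.
#'
#' @param runs query `GRanges` (e.g. detected high-signal runs).
#' @param annotation annotation `GRanges` (e.g. TADs, early/late
#'   domains).
#' @return Number of crossed boundaries.
#' @export
countBoundaryCrossings <- function(runs, annotation) {
  if (!length(runs) || !length(annotation)) return(0L)
  bounds <- c(
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(annotation),
      IRanges::IRanges(GenomicRanges::start(annotation), width = 1)),
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(annotation),
      IRanges::IRanges(GenomicRanges::end(annotation), width = 1)))
  inner <- GenomicRanges::resize(runs, pmax(GenomicRanges::width(runs) - 2L,
                                            1L), fix = "center")
  sum(IRanges::overlapsAny(bounds, inner))
}

#' Write the pipeline outputs to a directory
#'
#' Emits normalized and smoothed bedGraphs, the blacklist BED, the
#' per-condition averaged bedGraphs, the replicate QC table, and a run
#' log recording every parameter.
#'
#' @param result list from [rerepPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePipelineOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(result$normalized))
    writeBedGraph(result$normalized[[sid]],
                  file.path(dir, paste0(sid, ".normalized.bedGraph")))
  for (sid in names(result$smoothed))
    writeBedGraph(binnedToTrack(result$smoothed[[sid]]),
                  file.path(dir, paste0(sid, ".smoothed.bedGraph")))
  for (cond in names(result$averaged))
    writeBedGraph(binnedToTrack(result$averaged[[cond]]),
                  file.path(dir, paste0(cond, ".averaged.bedGraph")))
  writeBed(result$blacklist, file.path(dir, "blacklist.bed"))
  write.table(result$spearman, file.path(dir, "spearman_qc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log <- c(paste0("rerepseq pipeline run ",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           paste0("binWidth = ", result$params$binWidth),
           paste0("smoothWindow = ", result$params$smoothWindow),
           paste0("baselineCondition = ",
                  result$params$baselineCondition),
           paste0("samples = ",
                  paste(names(result$normalized), collapse = ", ")),
           paste0("mitoFactors = ",
                  paste(sprintf("%s:%.6g", names(result$mitoFactors),
                                result$mitoFactors), collapse = ", ")))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
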