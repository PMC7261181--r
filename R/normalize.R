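#' @include genome.R
#' @include coverage.R
#' @include binning.R
NULL

#' Reads-per-million normalization
#'
#' Multiplies every value by `1e6 / totalUnits`, where `totalUnits` is the
#' number of aligned reads (real data) or retained fragments (simulated
#' data) for the sample. Ratios between positions are unchanged.
#'
#' @param track a [CoverageTrack-class].
#' @param totalUnits positive total read/fragment count.
#' @return The normalized [CoverageTrack-class].
#' @export
rpmNormalize <- function(track, totalUnits) {
  if (!is.numeric(totalUnits) || length(totalUnits) != 1 ||
      is.na(totalUnits) || totalUnits <= 0)
    rerepError("totalUnits must be a positive number",
               "rerepError_badTotal")
  scaleTrack(track, 1e6 / totalUnits)
}

#' Mitochondrial internal-control scaling
#'
#' Mitochondrial DNA is fully BrdU-substituted on both strands in every
#' sample, so it is digested equally everywhere and its share of the signal
#' is a per-sample scale reference. Each sample `s` with mitochondrial
#' signal-mass fraction `f_s` is multiplied by `mean(f) / f_s`, bringing
#' every sample's scaled mitochondrial mass to the common value
#' `mean(f) * (pre-scaling total mass)`.
#'
#' @param tracks list of [CoverageTrack-class] objects on one genome.
#' @return List of scaled tracks, with the per-sample factors in
#'   `attr(, "factors")` and the input fractions in `attr(, "fractions")`.
#' @export
mitoScale <- function(tracks) {
  if (!length(tracks))
    rerepError("no tracks to scale", "rerepError_noTracks")
  fracs <- vapply(tracks, function(t) {
    m <- signalMass(t, mitoName(t@genome))
    if (m <= 0)
      rerepError(paste0("sample ", sampleId(t),
                        " has zero mitochondrial signal"),
                 "rerepError_zeroMito")
    m / signalMass(t)
  }, 0)
  factors <- mean(fracs) / fracs
  out <- mapply(scaleTrack, tracks, factors, SIMPLIFY = FALSE)
  names(out) <- vapply(tracks, sampleId, "")
  attr(out, "factors") <- factors
  attr(out, "fractions") <- fracs
  out
}

#' Build the baseline blacklist from time-point-0 replicates
#'
#' Bins are averaged across the time-point-0 replicates; over all
#' non-mitochondrial bins the grand mean `mu` and population standard
#' deviation `sigma` are computed, and the blacklist is the set of maximal
#' runs of adjacent bins whose averaged value is strictly greater than
#' `mu + sigma`. Mitochondrial bins are never blacklisted (they are the
#' normalizer) and are excluded from `mu` and `sigma`.
#'
#' @param t0Tracks list of [BinnedTrack-class] time-point-0 replicates on
#'   one bin grid.
#' @return A `GRanges` of blacklisted regions (label `"blacklist"`), with
#'   the threshold in `attr(, "threshold")`.
#' @export
makeBlacklist <- function(t0Tracks) {
  if (!length(t0Tracks))
    rerepError("need at least one time-point-0 replicate",
               "rerepError_noTracks")
  .assertSameGrids(t0Tracks)
  avg <- averageReplicates(t0Tracks, "t0mean")
  genome <- avg@genome
  nuclear <- setdiff(chromNames(genome), mitoName(genome))
  pooled <- unlist(avg@values[nuclear], use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  mu <- mean(pooled)
  sigma <- sqrt(mean((pooled - mu)^2))
  thr <- mu + sigma
  pieces <- lapply(nuclear, function(chrom) {
    v <- avg@values[[chrom]]
    hot <- !is.na(v) & v > thr
    if (!any(hot)) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(which(hot), width = 1L))
    w <- avg@binWidth
    len <- chromLengths(genome)[[chrom]]
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = (IRanges::start(r) - 1L) * w + 1L,
                       end = pmin(IRanges::end(r) * w, len)))
    gr
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  out <- if (length(pieces)) suppressWarnings(do.call(c, pieces)) else
    GenomicRanges::GRanges()
  GenomeInfoDb::seqlevels(out) <- chromNames(genome)
  GenomeInfoDb::seqinfo(out) <- genomeSeqinfo(genome)
  out <- GenomicRanges::sort(out)
  out$label <- rep("blacklist", length(out))
  attr(out, "threshold") <- thr
  out
}

#' Mask blacklisted bins in a binned track
#'
#' Every bin overlapping a blacklist interval (even partially) becomes
#' missing. Missing bins are excluded - not zeroed - from downstream
#' averaging and smoothing.
#'
#' @param binned a [BinnedTrack-class].
#' @param blacklist a `GRanges` of regions to mask.
#' @return The masked [BinnedTrack-class].
#' @export
applyBlacklist <- function(binned, blacklist) {
  if (!length(blacklist)) return(binned)
  genome <- binned@genome
  for (chrom in unique(as.character(GenomeInfoDb::seqnames(blacklist)))) {
    if (!chrom %in% chromNames(genome)) next
    bl <- IRanges::ranges(
      blacklist[as.character(GenomeInfoDb::seqnames(blacklist)) == chrom])
    hits <- IRanges::overlapsAny(
      .binRanges(genome, binned@binWidth, chrom), bl)
    binned@values[[chrom]][hits] <- NA_real_
  }
  binned
}

#' Spearman reproducibility of two replicate binned tracks
#'
#' Rank correlation (average-rank tie handling) over the bins that are
#' non-missing in both tracks; used as the replicate QC statistic.
#'
#' @param a,b two [BinnedTrack-class] objects on one grid.
#' @return Correlation in \[-1, 1\].
#' @export
replicateSpearman <- function(a, b) {
  .assertSameGrids(list(a, b))
  x <- unlist(a@values, use.names = FALSE)
  y <- unlist(b@values, use.names = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3)
    rerepError("fewer than 3 jointly non-missing bins",
               "rerepError_tooFewBins")
  cor(x[ok], y[ok], method = "spearman")
}
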