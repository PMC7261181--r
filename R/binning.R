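#' @include genome.R
#' @include coverage.R
NULL

#' Fixed-width binned representation of a coverage track
#'
#' Bins tile every chromosome from position 0 in steps of `binWidth`; the
#' last bin of each chromosome is truncated at the chromosome end. The bin
#' grid therefore depends only on the genome and the bin width, so tracks
#' binned on the same genome are directly comparable bin-by-bin. Bin values
#' are per-bp signal densities (length-weighted means); `NA` marks bins
#' removed by the blacklist.
#'
#' @slot binWidth bin width in bp.
#' @slot values named list (one numeric vector per chromosome) of bin
#'   values; `NA` = missing.
#' @slot genome the [RerepGenome-class].
#' @slot sampleId sample identifier.
#'
#' @export
setClass("BinnedTrack",
  representation(binWidth = "integer", values = "list",
                 genome = "RerepGenome", sampleId = "character"))

setValidity("BinnedTrack", function(object) {
  lens <- chromLengths(object@genome)
  msgs <- character()
  if (object@binWidth < 1L) msgs <- c(msgs, "binWidth must be >= 1")
  if (!identical(names(object@values), names(lens)))
    msgs <- c(msgs, "values must have one vector per genome chromosome")
  else {
    expected <- ceiling(lens / object@binWidth)
    got <- lengths(object@values)
    if (!all(got == expected))
      msgs <- c(msgs, "bin counts do not match ceiling(length / binWidth)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BinnedTrack-class bin width in bp.
#' @param x,object a `BinnedTrack`.
#' @export
binWidth <- function(x) x@binWidth

#' @describeIn BinnedTrack-class named list of per-chromosome bin values.
#' @export
binValues <- function(x) x@values

setMethod("show", "BinnedTrack", function(object) {
  n <- sum(lengths(object@values))
  nmiss <- sum(vapply(object@values, function(v) sum(is.na(v)), 0))
  cat("BinnedTrack '", object@sampleId, "': ", object@binWidth,
      " bp bins, ", n, " bins (", nmiss, " missing)\n", sep = "")
})

.sameGrid <- function(a, b) {
  a@binWidth == b@binWidth &&
    identical(lengths(a@values), lengths(b@values)) &&
    identical(chromNames(a@genome), chromNames(b@genome))
}

.assertSameGrids <- function(tracks) {
  if (length(tracks) > 1)
    for (t in tracks[-1])
      if (!.sameGrid(tracks[[1]], t))
        rerepError("binned tracks are on different bin grids",
                   "rerepError_gridMismatch")
  invisible(TRUE)
}

.binRanges <- function(genome, width, chrom) {
  len <- chromLengths(genome)[[chrom]]
  n <- ceiling(len / width)
  starts <- (seq_len(n) - 1L) * width + 1L
  IRanges::IRanges(start = starts, end = pmin(starts + width - 1L, len))
}

#' Bin a coverage track to a fixed-width grid
#'
#' The value of each bin is the length-weighted mean per-bp signal within
#' the bin (positions not covered by any interval count as 0), so bin
#' values keep the units of the input signal density and
#' `sum(bin value * bin length)` equals the track's signal mass exactly.
#'
#' @param track a [CoverageTrack-class].
#' @param width bin width in bp (>= 1).
#' @return A [BinnedTrack-class].
#' @export
binTrack <- function(track, width) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L)
    rerepError("bin width must be >= 1", "rerepError_badBinWidth")
  genome <- track@genome
  lens <- chromLengths(genome)
  cov <- GenomicRanges::coverage(track@ranges, weight = "score")
  vals <- lapply(names(lens), function(chrom) {
    rle <- if (chrom %in% names(cov)) cov[[chrom]] else
      S4Vectors::Rle(0, lens[[chrom]])
    v <- IRanges::Views(rle, .binRanges(genome, width, chrom))
    unname(IRanges::viewMeans(v))
  })
  names(vals) <- names(lens)
  new("BinnedTrack", binWidth = width, values = vals, genome = genome,
      sampleId = track@sampleId)
}

#' Smooth a binned track with a centered sliding window
#'
#' The window is `window` bp wide, coerced up to the nearest odd multiple
#' of the bin width. Interior bins (whose full centered window lies inside
#' the chromosome) get the mean of the non-missing bins in their window;
#' bins within half a window of either chromosome end are passed through
#' unsmoothed, so smoothing starts and stops half a window from the ends.
#' Windows containing only missing bins give a missing value.
#'
#' @param binned a [BinnedTrack-class].
#' @param window window width in bp (>= bin width).
#' @return A smoothed [BinnedTrack-class] on the same grid.
#' @export
smoothTrack <- function(binned, window) {
  w <- binned@binWidth
  if (window < w)
    rerepError("smoothing window must be >= bin width",
               "rerepError_badWindow")
  k <- ceiling(window / w)
  if (k %% 2 == 0) k <- k + 1L
  half <- (k - 1L) %/% 2L
  binned@values <- lapply(binned@values, function(v) {
    n <- length(v)
    if (n < k) return(v)
    s <- ifelse(is.na(v), 0, v)
    cnt <- as.numeric(!is.na(v))
    rs <- stats::filter(s, rep(1, k), sides = 2)
    rc <- stats::filter(cnt, rep(1, k), sides = 2)
    out <- as.numeric(rs / rc)
    out[!is.na(rc) & rc == 0] <- NA_real_
    idx <- c(seq_len(half), (n - half + 1L):n)
    out[idx] <- v[idx]
    out
  })
  binned
}

#' Average replicate binned tracks bin-by-bin
#'
#' Bins missing in any replicate are missing in the output; all tracks must
#' share the same bin grid.
#'
#' @param tracks list of [BinnedTrack-class] replicates.
#' @param sampleId identifier for the averaged track.
#' @return A [BinnedTrack-class].
#' @export
averageReplicates <- function(tracks, sampleId = "averaged") {
  if (!length(tracks))
    rerepError("no tracks to average", "rerepError_noTracks")
  .assertSameGrids(tracks)
  out <- tracks[[1]]
  out@values <- lapply(names(out@values), function(chrom) {
    m <- vapply(tracks, function(t) t@values[[chrom]],
                numeric(length(out@values[[chrom]])))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    rowMeans(m)
  })
  names(out@values) <- chromNames(out@genome)
  out@sampleId <- sampleId
  out
}

#' Convert a binned track back to a step-function coverage track
#'
#' Missing bins are dropped (emitting no interval, i.e. value 0 on write).
#'
#' @param binned a [BinnedTrack-class].
#' @param sampleId optional identifier for the resulting track.
#' @return A [CoverageTrack-class].
#' @export
binnedToTrack <- function(binned, sampleId = binned@sampleId) {
  genome <- binned@genome
  pieces <- lapply(chromNames(genome), function(chrom) {
    v <- binned@values[[chrom]]
    keep <- !is.na(v) & v != 0
    if (!any(keep)) return(NULL)
    r <- .binRanges(genome, binned@binWidth, chrom)[keep]
    gr <- GenomicRanges::GRanges(chrom, r)
    gr$score <- v[keep]
    gr
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  gr <- if (length(pieces)) suppressWarnings(do.call(c, pieces)) else {
    g <- GenomicRanges::GRanges(seqinfo = genomeSeqinfo(genome))
    g$score <- numeric(0)
    g
  }
  CoverageTrack(gr, genome, sampleId)
}

#' Signal mass of a binned track
#'
#' `sum(bin value * bin length)` over non-missing bins, optionally
#' restricted to chromosomes.
#'
#' @param binned a [BinnedTrack-class].
#' @param chroms optional chromosomes to restrict to.
#' @return A single number.
#' @export
binnedMass <- function(binned, chroms = NULL) {
  genome <- binned@genome
  if (is.null(chroms)) chroms <- chromNames(genome)
  sum(vapply(chroms, function(chrom) {
    v <- binned@values[[chrom]]
    widths <- IRanges::width(.binRanges(genome, binned@binWidth, chrom))
    sum(v * widths, na.rm = TRUE)
  }, 0))
}
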