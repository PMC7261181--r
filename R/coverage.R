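#' @include genome.R
NULL

#' Per-sample coverage track with bedGraph step-function semantics
#'
#' A `CoverageTrack` holds a non-negative signal as a step function over
#' half-open genomic intervals (bedGraph semantics: positions not covered by
#' any interval have value 0). Internally intervals are stored as a sorted,
#' disjoint `GRanges` in the usual Bioconductor 1-based closed convention;
#' conversion to and from the 0-based half-open file formats happens in
#' [readBedGraph()] / [writeBedGraph()].
#'
#' @slot ranges disjoint, sorted `GRanges` with a numeric `score` column.
#' @slot genome the [RerepGenome-class] the track lives on.
#' @slot sampleId sample identifier.
#'
#' @export
setClass("CoverageTrack",
  representation(ranges = "GRanges", genome = "RerepGenome",
                 sampleId = "character"))

setValidity("CoverageTrack", function(object) {
  gr <- object@ranges
  msgs <- character()
  if (is.null(gr$score) || !is.numeric(gr$score))
    msgs <- c(msgs, "ranges must carry a numeric score")
  else if (any(gr$score < 0))
    msgs <- c(msgs, "scores must be non-negative")
  if (length(gr)) {
    if (S4Vectors::isSorted(gr) == FALSE)
      msgs <- c(msgs, "ranges must be sorted")
    if (!GenomicRanges::isDisjoint(gr))
      msgs <- c(msgs, "ranges must be non-overlapping")
    lens <- chromLengths(object@genome)
    if (!all(as.character(GenomeInfoDb::seqnames(gr)) %in% names(lens)))
      msgs <- c(msgs, "ranges on chromosomes absent from genome")
    else {
      ends <- GenomicRanges::end(gr)
      if (any(ends > lens[as.character(GenomeInfoDb::seqnames(gr))]) ||
          any(GenomicRanges::start(gr) < 1L))
        msgs <- c(msgs, "ranges outside chromosome bounds")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a coverage track
#'
#' @param ranges a `GRanges` with a `score` metadata column (unsorted input
#'   is sorted; overlapping input is an error).
#' @param genome a [RerepGenome-class].
#' @param sampleId sample identifier.
#' @return A [CoverageTrack-class].
#' @export
CoverageTrack <- function(ranges, genome, sampleId = "sample") {
  seqn <- as.character(GenomeInfoDb::seqnames(ranges))
  bad <- setdiff(unique(seqn), chromNames(genome))
  if (length(bad))
    rerepError(paste0("unknown chromosome(s): ", paste(bad, collapse = ", ")),
               "rerepError_unknownChrom")
  GenomeInfoDb::seqlevels(ranges) <- chromNames(genome)
  GenomeInfoDb::seqinfo(ranges) <- genomeSeqinfo(genome)
  ranges <- GenomicRanges::sort(ranges)
  if (!GenomicRanges::isDisjoint(ranges))
    rerepError("overlapping intervals in coverage input",
               "rerepError_overlap")
  new("CoverageTrack", ranges = ranges, genome = genome,
      sampleId = as.character(sampleId))
}

#' @describeIn CoverageTrack-class the underlying `GRanges`.
#' @param x,object a `CoverageTrack`.
#' @export
trackRanges <- function(x) x@ranges

#' @describeIn CoverageTrack-class sample identifier.
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn CoverageTrack-class genome the track is defined on.
#' @export
trackGenome <- function(x) x@genome

#' Total signal mass of a track
#'
#' Mass is `sum(value * interval length)`, optionally restricted to a subset
#' of chromosomes.
#'
#' @param track a [CoverageTrack-class].
#' @param chroms optional character vector of chromosomes to restrict to.
#' @return A single number.
#' @export
signalMass <- function(track, chroms = NULL) {
  gr <- track@ranges
  if (!is.null(chroms))
    gr <- gr[as.character(GenomeInfoDb::seqnames(gr)) %in% chroms]
  sum(as.numeric(GenomicRanges::width(gr)) * gr$score)
}

#' Mitochondrial mass fraction of a track
#'
#' Fraction of total signal mass on the mitochondrial contig, the quantity
#' the mitochondrial scaling step equalizes across samples.
#'
#' @param track a [CoverageTrack-class].
#' @param total optional fixed denominator (signal mass); defaults to the
#'   track's own total mass.
#' @return A fraction in \[0, 1\].
#' @export
mitoMassFraction <- function(track, total = NULL) {
  if (is.null(total)) total <- signalMass(track)
  if (total <= 0)
    rerepError(paste0("track ", track@sampleId, " has zero total signal"),
               "rerepError_zeroSignal")
  signalMass(track, mitoName(track@genome)) / total
}

#' Multiply every value of a track by a constant
#'
#' @param track a [CoverageTrack-class].
#' @param factor positive scale factor.
#' @return The scaled [CoverageTrack-class].
#' @export
scaleTrack <- function(track, factor) {
  track@ranges$score <- track@ranges$score * factor
  track
}

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack '", object@sampleId, "': ", length(object@ranges),
      " intervals, total mass ", format(signalMass(object), digits = 6),
      "\n", sep = "")
})

# ---- bedGraph I/O ---------------------------------------------------------

.readWhitespaceTable <- function(path, what) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(NULL)
  con <- textConnection(lines)
  on.exit(close(con))
  read.table(con, header = FALSE, stringsAsFactors = FALSE,
             fill = TRUE, colClasses = NA)
}

.checkCoords <- function(chrom, start0, end0, genome, what) {
  lens <- chromLengths(genome)
  bad <- setdiff(unique(chrom), names(lens))
  if (length(bad))
    rerepError(paste0(what, ": unknown chromosome(s): ",
                      paste(bad, collapse = ", ")),
               "rerepError_unknownChrom")
  if (any(is.na(start0)) || any(is.na(end0)) ||
      any(start0 < 0) || any(end0 <= start0))
    rerepError(paste0(what, ": invalid interval coordinates ",
                      "(need 0 <= start < end)"),
               "rerepError_badInterval")
  if (any(end0 > lens[chrom]))
    rerepError(paste0(what, ": interval end beyond chromosome length"),
               "rerepError_outOfRange")
  invisible(TRUE)
}

#' Read a bedGraph file
#'
#' Four whitespace-delimited columns (`chrom start end value`, 0-based
#' half-open). `track`/`browser`/comment lines are skipped, unsorted input
#' is sorted; overlapping intervals, unknown chromosomes, out-of-range
#' coordinates and negative values are errors.
#'
#' @param path file path.
#' @param genome a [RerepGenome-class].
#' @param sampleId sample identifier for the returned track.
#' @return A [CoverageTrack-class].
#' @export
readBedGraph <- function(path, genome, sampleId = basename(path)) {
  tab <- .readWhitespaceTable(path)
  if (is.null(tab)) {
    gr <- GenomicRanges::GRanges(seqinfo = genomeSeqinfo(genome))
    gr$score <- numeric(0)
    return(CoverageTrack(gr, genome, sampleId))
  }
  if (ncol(tab) < 4)
    rerepError("bedGraph requires 4 columns", "rerepError_badFormat")
  chrom <- as.character(tab[[1]])
  start0 <- as.numeric(tab[[2]]); end0 <- as.numeric(tab[[3]])
  value <- as.numeric(tab[[4]])
  .checkCoords(chrom, start0, end0, genome, "bedGraph")
  if (any(is.na(value)) || any(value < 0))
    rerepError("bedGraph: negative or missing value",
               "rerepError_negativeValue")
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = start0 + 1, end = end0))
  gr$score <- value
  CoverageTrack(gr, genome, sampleId)
}

#' Write a track as bedGraph
#'
#' Values are printed with 6 significant digits; zero-value intervals are
#' omitted. Coordinates are written 0-based half-open.
#'
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  gr <- track@ranges
  gr <- gr[gr$score != 0]
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = formatC(gr$score, digits = 6, format = "g"))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    rerepError(paste0("failed to write ", path, ": ",
                      conditionMessage(ok)), "rerepError_io")
  invisible(path)
}

# ---- BED interval I/O -----------------------------------------------------

#' Read a BED file of labeled intervals
#'
#' 3-6 column BED (0-based half-open). The label is taken from the BED name
#' column, or `constantLabel` for 3-column files; column 5, when present, is
#' kept as `score`. Strand columns are ignored: Rerep-Seq coverage carries
#' no strand after fragmentation.
#'
#' @param path file path.
#' @param genome a [RerepGenome-class].
#' @param vocabulary optional character vector of admissible labels; labels
#'   outside it are an error.
#' @param constantLabel label applied when the file has no name column.
#' @return A `GRanges` with `label` (and optional `score`) metadata.
#' @export
readBed <- function(path, genome, vocabulary = NULL,
                    constantLabel = "region") {
  tab <- .readWhitespaceTable(path)
  if (is.null(tab)) {
    gr <- GenomicRanges::GRanges(seqinfo = genomeSeqinfo(genome))
    gr$label <- character(0)
    return(gr)
  }
  if (ncol(tab) < 3)
    rerepError("BED requires at least 3 columns", "rerepError_badFormat")
  chrom <- as.character(tab[[1]])
  start0 <- as.numeric(tab[[2]]); end0 <- as.numeric(tab[[3]])
  .checkCoords(chrom, start0, end0, genome, "BED")
  label <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
    rep(constantLabel, nrow(tab))
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(label), vocabulary)
    if (length(bad))
      rerepError(paste0("BED labels outside vocabulary: ",
                        paste(bad, collapse = ", ")),
                 "rerepError_badLabel")
  }
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = start0 + 1, end = end0))
  GenomeInfoDb::seqlevels(gr) <- chromNames(genome)
  GenomeInfoDb::seqinfo(gr) <- genomeSeqinfo(genome)
  gr$label <- label
  if (ncol(tab) >= 5) gr$score <- suppressWarnings(as.numeric(tab[[5]]))
  GenomicRanges::sort(gr)
}

#' Write labeled intervals as BED
#'
#' @param intervals a `GRanges`, optionally with `label` and `score`
#'   metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(intervals)),
                   start = GenomicRanges::start(intervals) - 1L,
                   end = GenomicRanges::end(intervals))
  if (!is.null(intervals$label)) {
    df$name <- intervals$label
    if (!is.null(intervals$score)) df$score <- intervals$score
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
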