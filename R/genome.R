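#' @useDynLib rerepseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor quantile rbinom runif sd var approx setNames
#'   ks.test aggregate median ave
#' @importFrom utils read.table write.table head tail combn
NULL

rerepError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rerepError")))
}

#' Genome definition with a designated mitochondrial contig
#'
#' A `RerepGenome` names the chromosomes of a (synthetic or real) genome,
#' their lengths, and which contig is the mitochondrial genome. The
#' mitochondrial contig acts as the internal control throughout the package:
#' mitochondrial DNA replicates continuously and is therefore fully
#' BrdU-substituted on both strands in every sample, making its signal a
#' per-sample scale reference.
#'
#' @slot chromNames character vector of unique chromosome names.
#' @slot chromLengths integer vector of chromosome lengths in bp (>= 1).
#' @slot mitoName name of the mitochondrial contig; must be a chromosome.
#'
#' @export
setClass("RerepGenome",
  representation(chromNames = "character", chromLengths = "integer",
                 mitoName = "character"))

setValidity("RerepGenome", function(object) {
  msgs <- character()
  if (anyDuplicated(object@chromNames))
    msgs <- c(msgs, "chromosome names must be unique")
  if (length(object@chromLengths) != length(object@chromNames))
    msgs <- c(msgs, "lengths and names differ in length")
  if (any(is.na(object@chromLengths)) || any(object@chromLengths < 1L))
    msgs <- c(msgs, "chromosome lengths must be >= 1")
  if (length(object@mitoName) != 1L ||
      !(object@mitoName %in% object@chromNames))
    msgs <- c(msgs, "mitoName must name exactly one chromosome")
  if (length(msgs)) msgs else TRUE
})

#' Construct a genome definition
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param mitoName name of the mitochondrial contig.
#' @return A [RerepGenome-class] object.
#' @examples
#' gn <- RerepGenome(c(chrI = 2e5, chrII = 1e5, chrM = 6e3), "chrM")
#' chromNames(gn)
#' @export
RerepGenome <- function(chromLengths, mitoName) {
  if (is.null(names(chromLengths)))
    rerepError("chromLengths must be named", "rerepError_badGenome")
  obj <- new("RerepGenome", chromNames = names(chromLengths),
             chromLengths = as.integer(chromLengths),
             mitoName = as.character(mitoName))
  obj
}

#' Read a two-column chromosome-sizes table
#'
#' Whitespace-delimited `name length` lines, as produced by `samtools faidx`
#' style tooling.
#'
#' @param path file path.
#' @param mitoName mitochondrial contig name (must be present in the file).
#' @return A [RerepGenome-class].
#' @export
readChromSizes <- function(path, mitoName) {
  tab <- read.table(path, header = FALSE, col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  RerepGenome(setNames(tab$length, tab$chrom), mitoName)
}

#' @describeIn RerepGenome-class chromosome names, in genome order.
#' @param x,object a `RerepGenome`.
#' @export
chromNames <- function(x) x@chromNames

#' @describeIn RerepGenome-class named vector of chromosome lengths (bp).
#' @export
chromLengths <- function(x) setNames(x@chromLengths, x@chromNames)

#' @describeIn RerepGenome-class name of the mitochondrial contig.
#' @export
mitoName <- function(x) x@mitoName

#' @describeIn RerepGenome-class `Seqinfo` view of the genome, for building
#'   `GRanges` on the same coordinate system.
#' @export
genomeSeqinfo <- function(x) {
  GenomeInfoDb::Seqinfo(seqnames = x@chromNames,
                        seqlengths = x@chromLengths)
}

setMethod("show", "RerepGenome", function(object) {
  cat("RerepGenome with", length(object@chromNames), "chromosomes;",
      "total", sum(object@chromLengths), "bp\n")
  cat("  mitochondrial contig:", object@mitoName, "\n")
  n <- min(length(object@chromNames), 6L)
  cat(paste0("  ", object@chromNames[seq_len(n)], ": ",
             object@chromLengths[seq_len(n)], " bp", collapse = "\n"), "\n")
  if (length(object@chromNames) > n) cat("  ...\n")
})
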