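#' @include genome.R
#' @include coverage.R
NULL

# qPCR quantification arithmetic. Amplicon coordinates follow the printed
# primer-table convention: 1-based inclusive, the only convention
# consistent with every declared amplicon length; conversion to 0-based
# half-open is (start - 1, end).

#' Read an amplicon/primer table
#'
#' Tab-delimited with columns `species, id, forward, reverse, chrom,
#' start, end, declared_length`; coordinates 1-based inclusive. The
#' packaged table (`ampliconTable()` with no argument) contains the seven
#' standard Rerep-Seq qPCR amplicons: yeast ACT1 (late region), ARS307
#' (early origin) and COX2 (mitochondrial normalizer), and human ACTb,
#' Tel16, HCN1 and hCOX2 (mitochondrial normalizer). Primer sequences are
#' validated against the DNA alphabet but not aligned to any genome.
#'
#' @param path table path; default: the packaged table.
#' @return data.frame of amplicon records.
#' @export
ampliconTable <- function(path = system.file("extdata",
                                             "qpcr_amplicons.tsv",
                                             package = "rerepseq")) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("species", "id", "forward", "reverse", "chrom", "start",
            "end", "declared_length")
  if (!all(need %in% names(tab)))
    rerepError("amplicon table missing required columns",
               "rerepError_badFormat")
  if (any(!grepl("^[ACGT]+$", tab$forward)) ||
      any(!grepl("^[ACGT]+$", tab$reverse)))
    rerepError("primer sequences must be non-empty A/C/G/T",
               "rerepError_badSequence")
  if (any(tab$start > tab$end))
    rerepError("amplicon start exceeds end", "rerepError_badInterval")
  tab
}

#' Amplicon span length from 1-based inclusive coordinates
#'
#' @param start,end 1-based inclusive coordinates (vectors allowed).
#' @return `end - start + 1`.
#' @export
ampliconSpanLength <- function(start, end) {
  if (any(start > end))
    rerepError("amplicon start exceeds end", "rerepError_badInterval")
  end - start + 1
}

#' Validate declared amplicon lengths against their coordinates
#'
#' @param tab amplicon table from [ampliconTable()].
#' @return The table with a `computed_length` column and a logical
#'   `length_ok` flag per record.
#' @export
validateAmplicons <- function(tab) {
  tab$computed_length <- ampliconSpanLength(tab$start, tab$end)
  tab$length_ok <- tab$computed_length == tab$declared_length
  tab
}

#' Average technical replicates to one Cq per sample and target
#'
#' @param cqTable data.frame with columns `sample_id`, `target_id`,
#'   `replicate`, `cq` (Cq > 0).
#' @return data.frame `(sample_id, target_id, cq)` with the arithmetic
#'   mean over technical replicates.
#' @export
collapseTechnicalReplicates <- function(cqTable) {
  need <- c("sample_id", "target_id", "cq")
  if (!all(need %in% names(cqTable)))
    rerepError("Cq table missing required columns",
               "rerepError_badFormat")
  if (any(cqTable$cq <= 0))
    rerepError("Cq values must be positive", "rerepError_badCq")
  agg <- aggregate(cq ~ sample_id + target_id, data = cqTable, FUN = mean)
  agg[order(agg$sample_id, agg$target_id), , drop = FALSE]
}

#' Mitochondria-normalized quantity from a pair of Cq values
#'
#' Template quantity is proportional to `2^-Cq`, so the target quantity
#' relative to the mitochondrial normalizer of the same sample is
#' `2^-Cq_target / 2^-Cq_normalizer = 2^(Cq_normalizer - Cq_target)`.
#' Adding any constant to both Cq values leaves the ratio unchanged.
#'
#' @param cqTarget,cqNormalizer positive Cq values (vectors allowed).
#' @return Ratio of target to normalizer quantity.
#' @export
normalizedQuantity <- function(cqTarget, cqNormalizer) {
  if (any(cqTarget <= 0) || any(cqNormalizer <= 0))
    rerepError("Cq values must be positive", "rerepError_badCq")
  2^(cqNormalizer - cqTarget)
}

#' Fold enrichment over a baseline sample
#'
#' @param ratios named vector of normalized quantities per sample.
#' @param baseline name of the baseline (e.g. T0) sample.
#' @return Named vector of folds; the baseline maps to 1.
#' @export
foldOverBaseline <- function(ratios, baseline) {
  if (!baseline %in% names(ratios))
    rerepError(paste0("baseline sample '", baseline, "' absent"),
               "rerepError_missingBaseline")
  if (ratios[[baseline]] <= 0)
    rerepError("baseline quantity is zero", "rerepError_zeroBaseline")
  ratios / ratios[[baseline]]
}

#' Mean and standard error over biological replicates
#'
#' @param x numeric vector of per-replicate values.
#' @return List with `mean`, `sem`, `n`.
#' @export
replicateSummary <- function(x) {
  n <- sum(!is.na(x))
  list(mean = mean(x, na.rm = TRUE),
       sem = if (n > 1) sd(x, na.rm = TRUE) / sqrt(n) else 0,
       n = n)
}

.meanCoverage <- function(track, chrom, start1, end1) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
  ov <- GenomicRanges::findOverlaps(gr, track@ranges)
  if (!length(ov)) return(0)
  hits <- track@ranges[S4Vectors::subjectHits(ov)]
  wt <- GenomicRanges::width(GenomicRanges::pintersect(
    rep(gr, length(hits)), hits))
  sum(hits$score * wt) / (end1 - start1 + 1)
}

#' In-silico qPCR read-out from a coverage track
#'
#' Mean coverage over the target amplicon divided by mean coverage over
#' the mitochondrial normalizer amplicon, bridging simulated coverage to
#' the qPCR quantification used on real digests.
#'
#' @param track a [CoverageTrack-class].
#' @param record,normalizerRecord single-row amplicon records (1-based
#'   inclusive `chrom`, `start`, `end`).
#' @return Target/normalizer coverage ratio.
#' @export
simulatedQpcrSignal <- function(track, record, normalizerRecord) {
  num <- .meanCoverage(track, record$chrom, record$start, record$end)
  den <- .meanCoverage(track, normalizerRecord$chrom,
                       normalizerRecord$start, normalizerRecord$end)
  if (den <= 0)
    rerepError("normalizer amplicon has zero coverage",
               "rerepError_zeroNormalizer")
  num / den
}
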