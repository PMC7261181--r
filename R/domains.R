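#' @include genome.R
#' @include binning.R
NULL

#' Classify early and late replicating regions from a timing profile
#'
#' The timing profile is a binned replication-timing signal on the
#' published 0-2 scale (2 = replicated, 1 = not replicated). Early regions
#' are maximal runs of adjacent bins with value at or above the 75th
#' percentile of bin values; late regions are maximal runs at or below the
#' 25th percentile (linear-interpolation percentiles). Missing bins break
#' runs.
#'
#' @param profile a [BinnedTrack-class] with values in \[0, 2\].
#' @return A `GRanges` with `label` in `{early, late}`; the quartile
#'   thresholds are attached as `attr(, "q25")` / `attr(, "q75")`.
#' @export
classifyTimingRegions <- function(profile) {
  vals <- unlist(profile@values, use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) < 4)
    rerepError("need at least 4 non-missing bins",
               "rerepError_tooFewBins")
  if (any(vals < 0 | vals > 2))
    rerepError("timing profile values must lie in [0, 2]",
               "rerepError_badTimingScale")
  if (diff(range(vals)) == 0)
    rerepError("all timing values identical: quartiles degenerate",
               "rerepError_degenerateQuartiles")
  q <- quantile(vals, c(0.25, 0.75), names = FALSE)
  genome <- profile@genome
  runsOf <- function(keep, chrom) {
    if (!any(keep, na.rm = TRUE)) return(NULL)
    keep[is.na(keep)] <- FALSE
    r <- IRanges::reduce(IRanges::IRanges(which(keep), width = 1L))
    w <- profile@binWidth
    len <- chromLengths(genome)[[chrom]]
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = (IRanges::start(r) - 1L) * w + 1L,
                       end = pmin(IRanges::end(r) * w, len)))
  }
  pieces <- list()
  for (chrom in chromNames(genome)) {
    v <- profile@values[[chrom]]
    e <- runsOf(v >= q[2], chrom)
    l <- runsOf(v <= q[1], chrom)
    if (!is.null(e)) { e$label <- rep("early", length(e));
      pieces[[length(pieces) + 1L]] <- e }
    if (!is.null(l)) { l$label <- rep("late", length(l));
      pieces[[length(pieces) + 1L]] <- l }
  }
  out <- if (length(pieces)) suppressWarnings(do.call(c, pieces)) else
    GenomicRanges::GRanges(label = character(0))
  GenomeInfoDb::seqlevels(out) <- chromNames(genome)
  GenomeInfoDb::seqinfo(out) <- genomeSeqinfo(genome)
  out <- GenomicRanges::sort(out)
  attr(out, "q25") <- q[1]
  attr(out, "q75") <- q[2]
  out
}

#' Feature-centered signal heatmap matrix
#'
#' One row per feature, covering `[mid - flank, mid + flank)` around the
#' feature midpoint (`floor((start + end) / 2)` in 0-based coordinates) at
#' bin resolution. Rows are sorted by row sum, descending; ties broken by
#' feature id, lexicographic. Columns extending past chromosome ends are
#' missing-padded. Row order is invariant to any global positive rescaling
#' of the track.
#'
#' @param track a [BinnedTrack-class].
#' @param centers `GRanges` of features; row names come from
#'   `centers$label`, `names(centers)`, or are generated.
#' @param flank half-width of the window in bp (> 0).
#' @return Numeric matrix with an attached `attr(, "rowOrder")` giving the
#'   feature ids in display order.
#' @export
featureHeatmap <- function(track, centers, flank) {
  if (!length(centers))
    rerepError("no features to center on", "rerepError_noFeatures")
  if (flank <= 0)
    rerepError("flank must be > 0", "rerepError_badFlank")
  w <- track@binWidth
  ids <- if (!is.null(centers$label)) centers$label
         else if (!is.null(names(centers))) names(centers)
         else sprintf("feature_%04d", seq_along(centers))
  ncol <- ceiling(2 * flank / w)
  rows <- matrix(NA_real_, nrow = length(centers), ncol = ncol,
                 dimnames = list(ids, NULL))
  lens <- chromLengths(track@genome)
  for (i in seq_along(centers)) {
    chrom <- as.character(GenomeInfoDb::seqnames(centers))[i]
    if (!chrom %in% names(lens)) next
    mid0 <- floor((GenomicRanges::start(centers)[i] - 1 +
                     GenomicRanges::end(centers)[i]) / 2)
    posLeft <- mid0 - flank
    binIdx <- floor((posLeft + (seq_len(ncol) - 1) * w) / w) + 1
    v <- track@values[[chrom]]
    ok <- binIdx >= 1 & binIdx <= length(v)
    rows[i, ok] <- v[binIdx[ok]]
  }
  sums <- rowSums(rows, na.rm = TRUE)
  ord <- order(-sums, ids)
  out <- rows[ord, , drop = FALSE]
  attr(out, "rowOrder") <- ids[ord]
  out
}

#' Extend timing domains to the midpoints of flanking transition zones
#'
#' In a replication-timing segmentation, early (ERD) and late (LRD)
#' domains alternate with transition zones (TZ). Each ERD/LRD boundary
#' that adjoins a TZ is moved to the midpoint of that TZ; boundaries with
#' no adjoining TZ (chromosome ends, or direct ERD/LRD contacts) are left
#' where they are. Extended domains on a chromosome abut exactly at TZ
#' midpoints and never overlap.
#'
#' @param domains `GRanges` with `label` in `{ERD, LRD, TZ}`,
#'   non-overlapping.
#' @return `GRanges` of extended ERD/LRD intervals (TZs consumed).
#' @export
extendDomainsToTzMidpoints <- function(domains) {
  if (!GenomicRanges::isDisjoint(domains))
    rerepError("input domains overlap", "rerepError_overlap")
  domains <- GenomicRanges::sort(domains)
  out <- list()
  for (chrom in unique(as.character(GenomeInfoDb::seqnames(domains)))) {
    d <- domains[as.character(GenomeInfoDb::seqnames(domains)) == chrom]
    lab <- d$label
    starts <- GenomicRanges::start(d)
    ends <- GenomicRanges::end(d)
    mid <- floor((starts + ends) / 2)
    for (i in which(lab %in% c("ERD", "LRD"))) {
      s <- starts[i]; e <- ends[i]
      if (i > 1 && lab[i - 1] == "TZ") s <- mid[i - 1] + 1L
      if (i < length(lab) && lab[i + 1] == "TZ") e <- mid[i + 1]
      gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
      gr$label <- lab[i]
      out[[length(out) + 1L]] <- gr
    }
  }
  res <- if (length(out)) suppressWarnings(do.call(c, out)) else
    GenomicRanges::GRanges(label = character(0))
  GenomeInfoDb::seqlevels(res) <- GenomeInfoDb::seqlevels(domains)
  GenomeInfoDb::seqinfo(res) <- GenomeInfoDb::seqinfo(domains)
  GenomicRanges::sort(res)
}

#' Size-normalized per-domain signal profiles and their meta-profile
#'
#' Each domain is rescaled to relative coordinates 0-100% and the binned
#' signal is linearly interpolated (between bin centers) at `nPoints`
#' equally spaced relative positions, so domains of very different sizes
#' become comparable rows. The meta-profile is the per-position mean over
#' domains, ignoring missing values.
#'
#' @param track a [BinnedTrack-class].
#' @param domains `GRanges` of (extended) domains.
#' @param nPoints number of relative positions (default 101, i.e. 0-100%).
#' @return List with `profiles` (matrix, one row per domain, sorted by row
#'   sum descending) and `meta` (length-`nPoints` mean profile).
#' @export
scaledDomainProfile <- function(track, domains, nPoints = 101) {
  if (nPoints < 2)
    rerepError("nPoints must be >= 2", "rerepError_badNPoints")
  w <- track@binWidth
  ids <- if (!is.null(domains$label))
    paste0(domains$label, "_", seq_along(domains)) else
    sprintf("domain_%04d", seq_along(domains))
  prof <- matrix(NA_real_, nrow = length(domains), ncol = nPoints,
                 dimnames = list(ids, NULL))
  lens <- chromLengths(track@genome)
  fracs <- seq(0, 1, length.out = nPoints)
  for (i in seq_along(domains)) {
    chrom <- as.character(GenomeInfoDb::seqnames(domains))[i]
    s0 <- GenomicRanges::start(domains)[i] - 1
    e0 <- GenomicRanges::end(domains)[i]
    if (e0 - s0 < 2 * w)
      rerepError("domain shorter than two bins", "rerepError_domainTooShort")
    v <- track@values[[chrom]]
    n <- length(v)
    centers <- (pmin(seq_len(n) * w, lens[[chrom]]) +
                  (seq_len(n) - 1) * w) / 2
    ok <- !is.na(v)
    if (sum(ok) < 2) next
    xout <- s0 + fracs * (e0 - s0)
    prof[i, ] <- approx(centers[ok], v[ok], xout = xout, rule = 2)$y
  }
  ord <- order(-rowSums(prof, na.rm = TRUE), ids)
  list(profiles = prof[ord, , drop = FALSE],
       meta = colMeans(prof, na.rm = TRUE))
}

#' Rank domains by mean signal
#'
#' The per-domain signal is the length-weighted mean of the non-missing
#' bins overlapping the domain. Domains are returned sorted by mean signal
#' descending, ties broken by domain id so the ranking is deterministic.
#'
#' @param track a [BinnedTrack-class].
#' @param domains `GRanges` of domains; ids from `domains$label` /
#'   `names(domains)` or generated.
#' @return data.frame `(domainId, meanSignal)` sorted descending.
#' @export
rankDomains <- function(track, domains) {
  ids <- if (!is.null(domains$label)) domains$label
         else if (!is.null(names(domains))) names(domains)
         else sprintf("domain_%04d", seq_along(domains))
  genome <- track@genome
  w <- track@binWidth
  sig <- vapply(seq_along(domains), function(i) {
    chrom <- as.character(GenomeInfoDb::seqnames(domains))[i]
    if (!chrom %in% chromNames(genome)) return(NA_real_)
    bins <- .binRanges(genome, w, chrom)
    ov <- IRanges::findOverlaps(IRanges::ranges(domains)[i], bins)
    idx <- S4Vectors::subjectHits(ov)
    v <- track@values[[chrom]][idx]
    wt <- IRanges::width(IRanges::pintersect(
      bins[idx], rep(IRanges::ranges(domains)[i], length(idx))))
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * wt[ok]) / sum(wt[ok])
  }, 0)
  df <- data.frame(domainId = ids, meanSignal = sig)
  df <- df[order(-df$meanSignal, df$domainId), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rank-based enrichment score with a permutation p-value
#'
#' The classic unweighted running-sum statistic over a ranked domain list:
#' walking down the ranking, members of the query set add `1/|query|`,
#' non-members subtract `1/(N - |query|)`; the enrichment score (ES) is
#' the extreme of the walk with the largest magnitude (ties in magnitude
#' resolve to the positive extreme). A query concentrated at the top of
#' the ranking gives ES near +1, at the bottom near -1. The p-value is the
#' add-one-smoothed fraction of label permutations with
#' `|ES_perm| >= |ES|`.
#'
#' @param ranked data.frame `(domainId, meanSignal)` as from
#'   [rankDomains()]; re-sorted internally for safety.
#' @param querySet character vector of member domain ids (non-empty,
#'   proper subset).
#' @param nPermutations number of label permutations.
#' @param seed optional RNG seed.
#' @return List with `es`, `pValue`, `nPermutations`.
#' @export
enrichmentScore <- function(ranked, querySet, nPermutations = 1000,
                            seed = NULL) {
  ranked <- ranked[order(-ranked$meanSignal, ranked$domainId), ,
                   drop = FALSE]
  member <- ranked$domainId %in% querySet
  if (!any(member) || all(member))
    rerepError("query set must be a non-empty proper subset",
               "rerepError_badQuerySet")
  es <- cpp_es(member)
  if (!is.null(seed)) set.seed(seed)
  perm <- cpp_es_perm(member, as.integer(nPermutations))
  p <- (1 + sum(abs(perm) >= abs(es))) / (nPermutations + 1)
  list(es = es, pValue = p, nPermutations = as.integer(nPermutations))
}
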