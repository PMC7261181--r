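# Shared fixtures, all generated in code.

tinyGenome <- function(chrI = 200, chrII = 150, chrM = 50) {
  RerepGenome(c(chrI = chrI, chrII = chrII, chrM = chrM), "chrM")
}

# a track from explicit 0-based half-open triples on one chromosome
stepTrack <- function(genome, chrom, start0, end0, value, id = "s") {
  if (length(chrom) == 1) chrom <- rep(chrom, length(start0))
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = start0 + 1, end = end0))
  gr$score <- value
  CoverageTrack(gr, genome, id)
}

# random valid coverage track: disjoint intervals per chromosome
randomTrack <- function(genome, meanIntervals = 8, id = "r",
                        maxValue = 10) {
  lens <- chromLengths(genome)
  pieces <- lapply(names(lens), function(chrom) {
    len <- lens[[chrom]]
    n <- max(1, rpois(1, meanIntervals))
    cuts <- sort(sample(0:len, min(2 * n, len), replace = FALSE))
    if (length(cuts) < 2) return(NULL)
    s <- cuts[seq(1, length(cuts) - 1, by = 2)]
    e <- cuts[seq(2, length(cuts), by = 2)]
    keep <- e > s
    if (!any(keep)) return(NULL)
    gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = s[keep] + 1, end = e[keep]))
    gr$score <- round(runif(sum(keep), 0, maxValue), 3)
    gr
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  gr <- suppressWarnings(do.call(c, pieces))
  CoverageTrack(gr, genome, id)
}

# binned track built directly from a per-chromosome value list
binnedFromValues <- function(genome, width, values, id = "b") {
  new("BinnedTrack", binWidth = as.integer(width), values = values,
      genome = genome, sampleId = id)
}

# uniform-constant binned track
constantBinned <- function(genome, width, value, id = "b") {
  lens <- chromLengths(genome)
  vals <- lapply(lens, function(len)
    rep(value, ceiling(len / width)))
  names(vals) <- names(lens)
  binnedFromValues(genome, width, vals, id)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  force(expr)
}

# independent recomputation of the baseline blacklist rule
bruteBlacklist <- function(valueList, width, genome) {
  nuclear <- setdiff(chromNames(genome), mitoName(genome))
  pooled <- unlist(valueList[nuclear], use.names = FALSE)
  mu <- mean(pooled)
  sigma <- sqrt(sum((pooled - mu)^2) / length(pooled))
  out <- list()
  for (chrom in nuclear) {
    v <- valueList[[chrom]]
    hot <- v > mu + sigma
    i <- 1
    while (i <= length(v)) {
      if (hot[i]) {
        j <- i
        while (j < length(v) && hot[j + 1]) j <- j + 1
        out[[length(out) + 1]] <- data.frame(chrom = chrom,
          start = (i - 1) * width + 1,
          end = min(j * width, chromLengths(genome)[[chrom]]))
        i <- j + 1
      } else i <- i + 1
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
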