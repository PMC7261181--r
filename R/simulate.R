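#' @include genome.R
#' @include coverage.R
NULL

# Simulator coordinates are 0-based half-open bp offsets (file convention);
# conversion to the 1-based GRanges world happens in fragmentsToTrack().

# interval matrices: 2 columns (start, end), 0-based half-open
.emptyIv <- function() matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("start", "end")))

.iv <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  m[m[, 2] > m[, 1], , drop = FALSE]
}

.ivToIR <- function(m) IRanges::IRanges(start = m[, 1] + 1, end = m[, 2])

.irToIv <- function(ir) .iv(IRanges::start(ir) - 1, IRanges::end(ir))

.ivUnion <- function(a, b) {
  if (!nrow(a)) return(b)
  if (!nrow(b)) return(a)
  .irToIv(IRanges::reduce(c(.ivToIR(a), .ivToIR(b))))
}

.ivSetdiff <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  .irToIv(IRanges::setdiff(.ivToIR(a), .ivToIR(b)))
}

#' Replication origins with firing times and a common fork speed
#'
#' Positions are 0-based bp; firing times are minutes from release into
#' S-phase. Forks proceed bidirectionally from each origin at `forkSpeed`
#' bp/minute, so at sampling time `t` an origin with firing time `f <= t`
#' has replicated `pos +/- forkSpeed * (t - f)`.
#'
#' @slot table data.frame with columns `chrom`, `pos`, `firingTime`.
#' @slot forkSpeed fork speed in bp/minute.
#'
#' @export
setClass("OriginMap",
  representation(table = "data.frame", forkSpeed = "numeric"))

setValidity("OriginMap", function(object) {
  tab <- object@table
  msgs <- character()
  if (!all(c("chrom", "pos", "firingTime") %in% names(tab)))
    msgs <- c(msgs, "table needs chrom, pos, firingTime columns")
  else {
    for (ch in unique(tab$chrom)) {
      p <- tab$pos[tab$chrom == ch]
      if (is.unsorted(p, strictly = TRUE))
        msgs <- c(msgs, paste0("positions not strictly increasing on ", ch))
    }
    if (any(tab$firingTime < 0))
      msgs <- c(msgs, "firing times must be >= 0")
  }
  if (length(object@forkSpeed) != 1 || object@forkSpeed <= 0)
    msgs <- c(msgs, "forkSpeed must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' Construct an origin map
#'
#' @param chrom,pos,firingTime parallel vectors of origin chromosome,
#'   0-based position (bp) and firing time (minutes).
#' @param forkSpeed fork speed in bp/minute.
#' @return An [OriginMap-class].
#' @export
OriginMap <- function(chrom, pos, firingTime, forkSpeed) {
  tab <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    firingTime = as.numeric(firingTime))
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  new("OriginMap", table = tab, forkSpeed = as.numeric(forkSpeed))
}

#' @describeIn OriginMap-class the origin table (chrom, pos, firingTime).
#' @param x,object an `OriginMap`.
#' @export
originTable <- function(x) x@table

#' @describeIn OriginMap-class fork speed in bp/minute.
#' @export
forkSpeed <- function(x) x@forkSpeed

setMethod("show", "OriginMap", function(object) {
  cat("OriginMap:", nrow(object@table), "origins on",
      length(unique(object@table$chrom)), "chromosomes; fork speed",
      object@forkSpeed, "bp/min\n")
})

#' Read origins from a BED file whose score column is the firing time
#'
#' The origin position is the interval midpoint.
#'
#' @param path BED path (needs >= 5 columns; column 5 = firing time).
#' @param genome a [RerepGenome-class].
#' @param forkSpeed fork speed in bp/minute.
#' @return An [OriginMap-class].
#' @export
readOriginsBed <- function(path, genome, forkSpeed) {
  gr <- readBed(path, genome, constantLabel = "origin")
  if (is.null(gr$score) || any(is.na(gr$score)))
    rerepError("origin BED needs a numeric score column (firing time)",
               "rerepError_badFormat")
  mid0 <- floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
  OriginMap(as.character(GenomeInfoDb::seqnames(gr)), mid0, gr$score,
            forkSpeed)
}

#' Region replicated by time t on one chromosome
#'
#' A position `x` has been replicated at sampling time `t` iff
#' `min over origins o of (firingTime(o) + |x - pos(o)| / forkSpeed) <= t`;
#' the result is the union of the per-origin fork intervals.
#'
#' @param origins an [OriginMap-class].
#' @param chrom chromosome name.
#' @param t sampling time in minutes.
#' @param chromLength chromosome length in bp.
#' @return Matrix of 0-based half-open intervals (columns start, end).
#' @export
replicatedRegions <- function(origins, chrom, t, chromLength) {
  tab <- origins@table[origins@table$chrom == chrom, , drop = FALSE]
  tab <- tab[tab$firingTime <= t, , drop = FALSE]
  if (!nrow(tab)) return(.emptyIv())
  span <- origins@forkSpeed * (t - tab$firingTime)
  m <- .iv(pmax(0, tab$pos - span), pmin(chromLength, tab$pos + span))
  if (!nrow(m)) return(m)
  .irToIv(IRanges::reduce(.ivToIR(m)))
}

#' A labeling schedule over successive cell-cycle phases
#'
#' Each phase is a full or partial S-phase; `brdu` says whether BrdU is in
#' the medium during that phase. `sampling` is `"complete"` for a full
#' cycle, a time in minutes for a phase interrupted by harvesting, or
#' `"asynchronous"` (final phase only) to draw each cell's sampling time
#' uniformly over `[0, cycleLength]`. `rerepDomains` marks regions that
#' re-fire a second time within the final phase, each producing an extra
#' fully double-labeled copy of the region per cell.
#'
#' @slot phases list of phases from [cyclePhase()].
#' @slot rerepDomains `GRanges` of rereplicating regions, or NULL-length.
#' @slot cycleLength cycle duration in minutes (for asynchronous sampling).
#'
#' @export
setClass("LabelSchedule",
  representation(phases = "list", rerepDomains = "GRanges",
                 cycleLength = "numeric"))

setValidity("LabelSchedule", function(object) {
  msgs <- character()
  if (length(object@phases) > 1) {
    for (p in object@phases[-length(object@phases)])
      if (!identical(p$sampling, "complete"))
        msgs <- c(msgs, "only the final phase may have a sampling time")
  }
  for (p in object@phases)
    if (!is.logical(p$brdu) ||
        !(identical(p$sampling, "complete") ||
          identical(p$sampling, "asynchronous") ||
          (is.numeric(p$sampling) && p$sampling >= 0)))
      msgs <- c(msgs, "malformed phase")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn LabelSchedule-class construct one cell-cycle phase.
#' @param brdu is BrdU present during the phase?
#' @param sampling `"complete"`, a sampling time in minutes, or
#'   `"asynchronous"`.
#' @export
cyclePhase <- function(brdu = TRUE, sampling = "complete") {
  list(brdu = isTRUE(brdu), sampling = sampling)
}

#' @describeIn LabelSchedule-class construct a schedule.
#' @param phases list of phases from [cyclePhase()].
#' @param rerepDomains optional `GRanges` of rereplicating regions.
#' @param cycleLength cycle duration in minutes.
#' @export
LabelSchedule <- function(phases, rerepDomains = NULL, cycleLength = 60) {
  if (is.null(rerepDomains)) rerepDomains <- GenomicRanges::GRanges()
  new("LabelSchedule", phases = phases, rerepDomains = rerepDomains,
      cycleLength = as.numeric(cycleLength))
}

setMethod("show", "LabelSchedule", function(object) {
  cat("LabelSchedule with", length(object@phases), "phases\n")
  for (i in seq_along(object@phases)) {
    p <- object@phases[[i]]
    cat("  phase ", i, ": BrdU ", if (p$brdu) "+" else "-", ", ",
        if (is.numeric(p$sampling)) paste0("sampled at ", p$sampling,
                                           " min") else p$sampling,
        "\n", sep = "")
  }
  if (length(object@rerepDomains))
    cat("  rereplicating domains:", length(object@rerepDomains),
        "intervals\n")
})

#' A double-stranded molecule with per-strand BrdU-labeled intervals
#'
#' Coordinates are 0-based half-open bp offsets on the genome. `top` and
#' `bottom` are interval matrices (columns start, end) marking
#' BrdU-substituted stretches of each strand.
#'
#' @slot chrom chromosome name.
#' @slot start,end molecule extent (0-based half-open).
#' @slot top,bottom labeled interval matrices, disjoint and sorted.
#'
#' @export
setClass("DuplexMolecule",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 top = "matrix", bottom = "matrix"))

setValidity("DuplexMolecule", function(object) {
  ok <- function(m) {
    !nrow(m) ||
      (all(m[, 1] >= object@start) && all(m[, 2] <= object@end) &&
       all(m[, 2] > m[, 1]) &&
       (nrow(m) == 1 || all(m[-1, 1] >= m[-nrow(m), 2])))
  }
  msgs <- character()
  if (object@end <= object@start) msgs <- c(msgs, "end must exceed start")
  if (!ok(object@top)) msgs <- c(msgs, "top labels invalid")
  if (!ok(object@bottom)) msgs <- c(msgs, "bottom labels invalid")
  if (length(msgs)) msgs else TRUE
})

#' Construct a duplex molecule
#'
#' @param chrom chromosome name.
#' @param start,end molecule extent, 0-based half-open.
#' @param top,bottom labeled intervals: 2-column matrices or
#'   `cbind(start, end)`-able vectors, 0-based half-open.
#' @return A [DuplexMolecule-class].
#' @export
DuplexMolecule <- function(chrom, start, end, top = NULL, bottom = NULL) {
  fix <- function(m) {
    if (is.null(m) || !length(m)) return(.emptyIv())
    m <- matrix(as.numeric(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    m[order(m[, 1]), , drop = FALSE]
  }
  new("DuplexMolecule", chrom = as.character(chrom),
      start = as.numeric(start), end = as.numeric(end),
      top = fix(top), bottom = fix(bottom))
}

setMethod("show", "DuplexMolecule", function(object) {
  lab <- function(m) if (nrow(m)) sum(m[, 2] - m[, 1]) else 0
  cat("DuplexMolecule ", object@chrom, ":[", object@start, ",", object@end,
      ") labeled top ", lab(object@top), " bp / bottom ",
      lab(object@bottom), " bp\n", sep = "")
})

#' Population of duplex molecules with per-type copy counts
#'
#' Cells following a deterministic schedule all carry the same set of
#' molecule label states, so the population is stored as distinct molecule
#' types with copy counts (`count` = number of physical copies across all
#' cells). Digestion treats every copy independently.
#'
#' @slot molecules data.frame: typeId, chrom, start, end, count.
#' @slot labels data.frame: typeId, strand ("top"/"bottom"), start, end.
#' @slot genome the [RerepGenome-class].
#' @slot nCells number of cells simulated.
#'
#' @export
setClass("DuplexPopulation",
  representation(molecules = "data.frame", labels = "data.frame",
                 genome = "RerepGenome", nCells = "integer"))

setMethod("show", "DuplexPopulation", function(object) {
  cat("DuplexPopulation:", sum(object@molecules$count), "molecules (",
      nrow(object@molecules), "types ) from", object@nCells, "cells\n")
})

#' @describeIn DuplexPopulation-class molecule type table.
#' @param x,object a `DuplexPopulation`.
#' @export
populationMolecules <- function(x) x@molecules

#' Fraction of nuclear duplexes labeled on both strands
#'
#' Exact population bookkeeping (copy counts, not sampling). After `n`
#' synchronous complete cycles in BrdU the fraction is `1 - 2^(1-n)`:
#' semiconservative replication always retains one parental strand, so a
#' duplex is double-labeled iff its parental strand was itself synthesized
#' in a labeled cycle.
#'
#' @param pop a [DuplexPopulation-class].
#' @param includeMito count mitochondrial molecules too (default FALSE;
#'   they are always double-labeled).
#' @return Fraction in \[0, 1\].
#' @export
doubleLabeledFraction <- function(pop, includeMito = FALSE) {
  mol <- pop@molecules
  if (!includeMito) mol <- mol[mol$chrom != mitoName(pop@genome), ,
                               drop = FALSE]
  lab <- pop@labels
  has <- function(strand) unique(lab$typeId[lab$strand == strand])
  double <- mol$typeId %in% has("top") & mol$typeId %in% has("bottom")
  sum(mol$count[double]) / sum(mol$count)
}

.applyPhase <- function(cellMols, phase, origins, genome, t = NULL) {
  out <- list()
  for (m in cellMols) {
    L <- chromLengths(genome)[[m$chrom]]
    if (identical(phase$sampling, "complete")) {
      R <- .iv(0, L)
    } else {
      R <- replicatedRegions(origins, m$chrom, t, L)
    }
    if (!nrow(R)) { # nothing replicated: molecule passes through unchanged
      out[[length(out) + 1L]] <- m
      next
    }
    nascent <- if (phase$brdu) R else .emptyIv()
    a <- list(chrom = m$chrom, top = m$top,
              bottom = .ivUnion(nascent, .ivSetdiff(m$bottom, R)))
    b <- list(chrom = m$chrom, bottom = m$bottom,
              top = .ivUnion(nascent, .ivSetdiff(m$top, R)))
    out[[length(out) + 1L]] <- a
    out[[length(out) + 1L]] <- b
  }
  out
}

.runSchedule <- function(genome, origins, schedule, t = NULL) {
  nuclear <- setdiff(chromNames(genome), mitoName(genome))
  cell <- lapply(nuclear, function(ch)
    list(chrom = ch, top = .emptyIv(), bottom = .emptyIv()))
  phases <- schedule@phases
  for (i in seq_along(phases)) {
    p <- phases[[i]]
    tt <- if (is.numeric(p$sampling)) p$sampling else t
    cell <- .applyPhase(cell, p, origins, genome, tt)
  }
  cell
}

#' Replicate a cell population through a labeling schedule
#'
#' Applies the semiconservative rule phase by phase: each replication pass
#' over a region turns one duplex into two, each keeping one parental
#' strand, with the nascent strand BrdU-labeled over exactly the region
#' replicated while BrdU was present. For a sampled S-phase at time `t`,
#' position `x` counts as replicated iff
#' `min over origins (firingTime + |x - pos|/forkSpeed) <= t`. Regions in
#' the schedule's `rerepDomains` fire a second time within the final
#' phase, adding one extra fully double-labeled copy of each region per
#' cell. The mitochondrial contig is always emitted fully double-labeled
#' on both strands in every cell (`mitoCopies` copies), since
#' mitochondrial DNA turns over continuously regardless of the cell cycle.
#'
#' @param genome a [RerepGenome-class].
#' @param origins an [OriginMap-class].
#' @param schedule a [LabelSchedule-class].
#' @param nCells number of cells (>= 1).
#' @param seed optional RNG seed (used only for asynchronous sampling).
#' @param mitoCopies mitochondrial genome copies per cell.
#' @return A [DuplexPopulation-class].
#' @export
replicatePopulation <- function(genome, origins, schedule, nCells,
                                seed = NULL, mitoCopies = 50) {
  if (!length(schedule@phases))
    rerepError("schedule has zero phases", "rerepError_emptySchedule")
  if (nCells < 1)
    rerepError("nCells must be >= 1", "rerepError_badNCells")
  if (!is.null(seed)) set.seed(seed)
  finalPhase <- schedule@phases[[length(schedule@phases)]]
  async <- identical(finalPhase$sampling, "asynchronous")
  cells <- if (async) {
    ts <- runif(nCells, 0, schedule@cycleLength)
    lapply(ts, function(t) list(mols = .runSchedule(genome, origins,
                                                    schedule, t),
                                count = 1L))
  } else {
    list(list(mols = .runSchedule(genome, origins, schedule),
              count = as.integer(nCells)))
  }
  mols <- list(); labs <- list(); typeId <- 0L
  addType <- function(chrom, start, end, top, bottom, count) {
    typeId <<- typeId + 1L
    mols[[typeId]] <<- data.frame(typeId = typeId, chrom = chrom,
                                  start = start, end = end, count = count)
    pieces <- list()
    if (nrow(top)) pieces$t <- data.frame(typeId = typeId, strand = "top",
                                          start = top[, 1], end = top[, 2])
    if (nrow(bottom)) pieces$b <- data.frame(typeId = typeId,
                                             strand = "bottom",
                                             start = bottom[, 1],
                                             end = bottom[, 2])
    if (length(pieces)) labs[[length(labs) + 1L]] <<-
        do.call(rbind, unname(pieces))
  }
  lens <- chromLengths(genome)
  for (cellGroup in cells) {
    for (m in cellGroup$mols)
      addType(m$chrom, 0, lens[[m$chrom]], m$top, m$bottom,
              cellGroup$count)
    # rereplicating regions: one extra double-labeled copy per cell
    rd <- schedule@rerepDomains
    if (length(rd)) {
      brdu <- finalPhase$brdu
      for (i in seq_along(rd)) {
        ch <- as.character(GenomeInfoDb::seqnames(rd))[i]
        s0 <- GenomicRanges::start(rd)[i] - 1
        e0 <- GenomicRanges::end(rd)[i]
        iv <- if (brdu) .iv(s0, e0) else .emptyIv()
        addType(ch, s0, e0, iv, iv, cellGroup$count)
      }
    }
  }
  # mitochondria: always fully double-labeled, every cell
  mch <- mitoName(genome)
  addType(mch, 0, lens[[mch]], .iv(0, lens[[mch]]), .iv(0, lens[[mch]]),
          as.integer(nCells) * as.integer(mitoCopies))
  new("DuplexPopulation",
      molecules = do.call(rbind, mols),
      labels = if (length(labs)) do.call(rbind, labs) else
        data.frame(typeId = integer(0), strand = character(0),
                   start = numeric(0), end = numeric(0)),
      genome = genome, nCells = as.integer(nCells))
}

# draw nick positions for label intervals replicated over `count` copies;
# exact per-copy-per-bp Bernoulli at rate `rate`. Returns data.frame
# (copy, pos, strand) with copy in 1..count.
.drawNicks <- function(labels, count, rate) {
  if (!nrow(labels) || rate <= 0)
    return(data.frame(copy = integer(0), pos = numeric(0),
                      strand = integer(0)))
  pieces <- lapply(seq_len(nrow(labels)), function(i) {
    len <- labels$end[i] - labels$start[i]
    slots <- count * len
    k <- rbinom(1, slots, rate)
    if (!k) return(NULL)
    idx <- sample(slots, k) - 1
    data.frame(copy = as.integer(idx %/% len) + 1L,
               pos = labels$start[i] + (idx %% len),
               strand = if (labels$strand[i] == "top") 0L else 1L)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces))
    return(data.frame(copy = integer(0), pos = numeric(0),
                      strand = integer(0)))
  do.call(rbind, pieces)
}

# breaks (sorted positions) + molecule extent -> fragment data.frame
.breaksToFragments <- function(breaks, start, end) {
  b <- sort(breaks)
  starts <- c(start, b)
  ends <- c(b, end)
  n <- length(starts)
  data.frame(start = starts, end = ends,
             terminal = seq_len(n) %in% c(1L, n))
}

#' Fragment-generation parameters for the selective digest
#'
#' BrdU-substituted positions are photolyzed and excised to nicks: each
#' labeled bp is a labelable site with probability `labelableDensity`
#' (thymidine-frequency proxy), and each site nicks with probability
#' `pNick` on its own strand. `pNick` is the single dial standing in for
#' UVA dose and digestion time. Two nicks on opposite strands no more than
#' `dsbMaxOffset` bp apart make a staggered double-strand break (greedy
#' left-to-right pairing, each nick used once; break at the midpoint,
#' rounded down). Gel size selection keeps internal fragments with length
#' in `[sizeMin, sizeMax]`.
#'
#' @slot pNick per-site nick probability in (0, 1].
#' @slot labelableDensity per-bp labelable-site probability in (0, 1].
#' @slot dsbMaxOffset maximum opposed-nick offset (bp) for a break.
#' @slot sizeMin,sizeMax retained fragment length window (bp).
#'
#' @export
setClass("DigestParams",
  representation(pNick = "numeric", labelableDensity = "numeric",
                 dsbMaxOffset = "numeric", sizeMin = "numeric",
                 sizeMax = "numeric"))

setValidity("DigestParams", function(object) {
  msgs <- character()
  if (object@pNick <= 0 || object@pNick > 1)
    msgs <- c(msgs, "pNick must be in (0,1]")
  if (object@labelableDensity <= 0 || object@labelableDensity > 1)
    msgs <- c(msgs, "labelableDensity must be in (0,1]")
  if (object@dsbMaxOffset <= 0) msgs <- c(msgs, "dsbMaxOffset must be > 0")
  if (object@sizeMin >= object@sizeMax)
    msgs <- c(msgs, "sizeMin must be < sizeMax")
  if (length(msgs)) msgs else TRUE
})

#' Construct digest parameters
#'
#' Defaults: `pNick = 0.03`, `labelableDensity = 0.3`,
#' `dsbMaxOffset = 16`, size window 100-3000 bp. At these settings
#' size-selected fragments from fully double-labeled DNA average roughly
#' 300-600 bp, the method's operating range.
#'
#' @param pNick per-site nick probability.
#' @param labelableDensity per-bp labelable-site probability.
#' @param dsbMaxOffset maximum opposed-nick offset in bp.
#' @param sizeMin,sizeMax size-selection window in bp.
#' @return A [DigestParams-class].
#' @export
DigestParams <- function(pNick = 0.03, labelableDensity = 0.3,
                         dsbMaxOffset = 16, sizeMin = 100, sizeMax = 3000) {
  new("DigestParams", pNick = pNick, labelableDensity = labelableDensity,
      dsbMaxOffset = dsbMaxOffset, sizeMin = sizeMin, sizeMax = sizeMax)
}

#' Digest one molecule into fragments
#'
#' Draws nicks on each labeled strand, pairs opposed nicks within
#' `dsbMaxOffset` bp into double-strand breaks (greedy left-to-right, each
#' nick used at most once, break at the rounded-down midpoint) and returns
#' the segments between consecutive breaks. Molecule ends are not breaks:
#' the first and last segment are flagged `terminal`. A molecule labeled
#' on only one strand can never yield an internal fragment.
#'
#' @param mol a [DuplexMolecule-class].
#' @param params a [DigestParams-class].
#' @param seed optional RNG seed.
#' @param topSites,bottomSites optional forced labelable-site positions
#'   (0-based bp) overriding random site placement; each still nicks with
#'   probability `pNick`.
#' @return data.frame with `start`, `end` (0-based half-open genomic
#'   coordinates) and `terminal`.
#' @export
digestMolecule <- function(mol, params, seed = NULL,
                           topSites = NULL, bottomSites = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- params@pNick * params@labelableDensity
  nick1 <- function(sites) sites[runif(length(sites)) <= params@pNick]
  if (is.null(topSites) && is.null(bottomSites)) {
    labs <- rbind(
      if (nrow(mol@top)) data.frame(strand = "top", start = mol@top[, 1],
                                    end = mol@top[, 2]),
      if (nrow(mol@bottom)) data.frame(strand = "bottom",
                                       start = mol@bottom[, 1],
                                       end = mol@bottom[, 2]))
    nk <- .drawNicks(if (is.null(labs))
      data.frame(strand = character(0), start = numeric(0),
                 end = numeric(0)) else labs, 1L, rate)
    top <- nk$pos[nk$strand == 0L]
    bottom <- nk$pos[nk$strand == 1L]
  } else {
    top <- nick1(as.numeric(topSites))
    bottom <- nick1(as.numeric(bottomSites))
  }
  pos <- c(top, bottom)
  strand <- c(rep(0L, length(top)), rep(1L, length(bottom)))
  o <- order(pos)
  res <- cpp_pair_breaks(rep(1L, length(pos)), pos[o], strand[o],
                         params@dsbMaxOffset)
  .breaksToFragments(res$brk, mol@start, mol@end)
}

#' Digest a whole population
#'
#' Each physical copy of each molecule type is digested independently,
#' with the same nick/break model as [digestMolecule()].
#'
#' @param pop a [DuplexPopulation-class].
#' @param params a [DigestParams-class].
#' @param seed optional RNG seed.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `terminal`.
#' @export
digestPopulation <- function(pop, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- params@pNick * params@labelableDensity
  mol <- pop@molecules
  lab <- pop@labels
  allFrags <- vector("list", nrow(mol))
  for (i in seq_len(nrow(mol))) {
    tid <- mol$typeId[i]
    li <- lab[lab$typeId == tid, , drop = FALSE]
    nk <- .drawNicks(li, mol$count[i], rate)
    if (!nrow(nk)) next
    o <- order(nk$copy, nk$pos)
    res <- cpp_pair_breaks(nk$copy[o], nk$pos[o], nk$strand[o],
                           params@dsbMaxOffset)
    if (!length(res$brk)) next
    # vectorized fragment construction across copies; breaks can come out
    # of pairing slightly out of positional order, so sort within copy
    ob <- order(res$gid, res$brk)
    brks <- res$brk[ob]
    kPer <- tabulate(res$gid, nbins = mol$count[i])
    withBrk <- which(kPer > 0L)
    k <- kPer[withBrk]
    off <- cumsum(c(0, head(k + 1L, -1L)))
    total <- sum(k + 1L)
    fs <- numeric(total); fe <- numeric(total)
    startIdx <- off + 1L
    endIdx <- off + k + 1L
    fs[startIdx] <- mol$start[i]
    fe[endIdx] <- mol$end[i]
    fs[setdiff(seq_len(total), startIdx)] <- brks
    fe[setdiff(seq_len(total), endIdx)] <- brks
    term <- logical(total)
    term[startIdx] <- TRUE
    term[endIdx] <- TRUE
    allFrags[[i]] <- data.frame(chrom = mol$chrom[i], start = fs, end = fe,
                                terminal = term)
  }
  allFrags <- allFrags[!vapply(allFrags, is.null, TRUE)]
  if (!length(allFrags))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), terminal = logical(0)))
  do.call(rbind, allFrags)
}

#' Gel size selection of digest fragments
#'
#' Keeps internal fragments (both ends made by breaks) whose length falls
#' in `[sizeMin, sizeMax]`; terminal fragments are excluded since at least
#' one of their ends is a molecule end rather than a break.
#'
#' @param fragments data.frame from [digestMolecule()] or
#'   [digestPopulation()].
#' @param params a [DigestParams-class].
#' @return The retained subset of `fragments`.
#' @export
sizeSelect <- function(fragments, params) {
  if (!nrow(fragments)) return(fragments)
  len <- fragments$end - fragments$start
  fragments[!fragments$terminal & len >= params@sizeMin &
              len <= params@sizeMax, , drop = FALSE]
}

#' Pile retained fragments into a coverage track
#'
#' The value at position `x` is the number of retained fragments
#' overlapping `x`, emulating aligned-read coverage. The fragment count is
#' attached as `attr(, "nFragments")` for RPM normalization.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genome a [RerepGenome-class].
#' @param sampleId sample identifier.
#' @return A [CoverageTrack-class].
#' @export
fragmentsToTrack <- function(fragments, genome, sampleId = "sim") {
  lens <- chromLengths(genome)
  if (nrow(fragments)) {
    bad <- setdiff(unique(fragments$chrom), names(lens))
    if (length(bad))
      rerepError(paste0("fragments on unknown chromosome(s): ",
                        paste(bad, collapse = ", ")),
                 "rerepError_unknownChrom")
    if (any(fragments$start < 0) ||
        any(fragments$end > lens[fragments$chrom]))
      rerepError("fragment outside chromosome bounds",
                 "rerepError_outOfRange")
  }
  gr <- GenomicRanges::GRanges(fragments$chrom,
          IRanges::IRanges(start = fragments$start + 1,
                           end = fragments$end),
          seqinfo = genomeSeqinfo(genome))
  cov <- GenomicRanges::coverage(gr)
  covGr <- GenomicRanges::GRanges(cov)
  covGr <- covGr[covGr$score > 0]
  track <- CoverageTrack(covGr, genome, sampleId)
  attr(track, "nFragments") <- nrow(fragments)
  track
}

#' Simulate one sequencing sample end to end
#'
#' Replicates the population through the schedule, digests it, size
#' selects, and piles fragments into coverage.
#'
#' @param genome,origins,schedule,nCells,mitoCopies see
#'   [replicatePopulation()].
#' @param params a [DigestParams-class].
#' @param seed RNG seed for the sample.
#' @param sampleId sample identifier.
#' @return List with `track` ([CoverageTrack-class]), `nFragments`
#'   (retained fragment count, the RPM denominator), and
#'   `meanFragmentLength`.
#' @export
simulateSample <- function(genome, origins, schedule, nCells, params,
                           seed = NULL, sampleId = "sim",
                           mitoCopies = 50) {
  if (!is.null(seed)) set.seed(seed)
  pop <- replicatePopulation(genome, origins, schedule, nCells,
                             mitoCopies = mitoCopies)
  frags <- digestPopulation(pop, params)
  kept <- sizeSelect(frags, params)
  track <- fragmentsToTrack(kept, genome, sampleId)
  list(track = track, nFragments = nrow(kept),
       meanFragmentLength = if (nrow(kept))
         mean(kept$end - kept$start) else NA_real_)
}
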