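demoParams <- function(...) DigestParams(...)

test_that("semiconservative labeling algebra is exact over full cycles", {
  gn <- tinyGenome()
  ori <- OriginMap("chrI", 100, 0, 1000)
  # after n complete BrdU cycles the double-labeled fraction is 1 - 2^(1-n)
  for (n in 1:4) {
    pop <- replicatePopulation(gn, ori, multiCycleSchedule(n), nCells = 3)
    expect_identical(doubleLabeledFraction(pop), 1 - 2^(1 - n))
  }
  # one cycle: every nuclear duplex has exactly one fully labeled strand
  pop1 <- replicatePopulation(gn, ori, multiCycleSchedule(1), nCells = 1)
  mol <- populationMolecules(pop1)
  nuc <- mol[mol$chrom != "chrM", ]
  lab <- pop1@labels
  for (tid in nuc$typeId) {
    strands <- lab$strand[lab$typeId == tid]
    expect_equal(length(strands), 1)
    row <- lab[lab$typeId == tid, ]
    expect_equal(row$end - row$start,
                 nuc$end[nuc$typeId == tid] - nuc$start[nuc$typeId == tid])
  }
  expect_error(replicatePopulation(gn, ori, LabelSchedule(list()), 1),
               class = "rerepError_emptySchedule")
})

test_that("fork arithmetic matches a per-bp brute-force replication rule", {
  # closed form: single origin at 0, 1 kb/min, sampled at 10 min -> [0,10kb)
  m <- replicatedRegions(OriginMap("c", 0, 0, 1000), "c", 10, 50000)
  expect_equal(unname(m), cbind(0, 10000), ignore_attr = TRUE)

  # brute force oracle: position replicated iff min_o(ft + |x-pos|/v) <= t
  withSeed(11, {
    for (rep in 1:10) {
      len <- 2000
      k <- sample(1:4, 1)
      pos <- sort(sample(0:(len - 1), k))
      ft <- round(runif(k, 0, 12), 2)
      v <- sample(c(50, 100, 250), 1)
      t <- runif(1, 0, 15)
      om <- OriginMap(rep("c", k), pos, ft, v)
      got <- replicatedRegions(om, "c", t, len)
      x <- 0:(len - 1)
      tRep <- Reduce(pmin, lapply(seq_len(k), function(i)
        ft[i] + abs(x - pos[i]) / v))
      inside <- logical(len)
      for (r in seq_len(nrow(got)))
        inside[x >= got[r, 1] & x < got[r, 2]] <- TRUE
      # brute-force indicator agrees everywhere except the half-open edge bp
      expect_lte(sum(inside != (tRep <= t)), 2 * k)
      if (nrow(got))
        expect_true(all(got[, 2] > got[, 1]))
    }
  })
})

test_that("opposed-nick pairing reproduces the hand-enumerated digest", {
  # double-labeled 1 kb molecule, forced sites: top {100,600}, bottom
  # {105,590}, offset 16 -> breaks at 102 and 595
  mol <- DuplexMolecule("chrI", 0, 1000, top = cbind(0, 1000),
                        bottom = cbind(0, 1000))
  par <- DigestParams(pNick = 1, dsbMaxOffset = 16)
  fr <- digestMolecule(mol, par, topSites = c(100, 600),
                       bottomSites = c(105, 590))
  expect_equal(fr$start, c(0, 102, 595))
  expect_equal(fr$end, c(102, 595, 1000))
  expect_equal(fr$terminal, c(TRUE, FALSE, TRUE))

  # size selection keeps exactly the internal fragment
  kept <- sizeSelect(fr, par)
  expect_equal(nrow(kept), 1)
  expect_equal(c(kept$start, kept$end), c(102, 595))
})

test_that("unlabeled and single-strand-labeled molecules never fragment", {
  par <- demoParams()
  bare <- DuplexMolecule("chrI", 0, 5000)
  fr <- digestMolecule(bare, par, seed = 1)
  expect_equal(nrow(fr), 1)
  expect_true(all(fr$terminal))
  expect_equal(c(fr$start, fr$end), c(0, 5000))

  # one strand fully labeled: nicks cannot oppose, so no internal breaks,
  # at any nick probability
  for (p in c(0.05, 0.5, 1)) {
    single <- DuplexMolecule("chrI", 0, 20000, top = cbind(0, 20000))
    fr <- digestMolecule(single, DigestParams(pNick = p), seed = p * 100)
    expect_equal(nrow(fr), 1)
    expect_equal(nrow(sizeSelect(fr, par)), 0)
  }
})

test_that("size selection applies the fragment-length window", {
  par <- demoParams()  # 100-3000 bp
  fr <- data.frame(start = c(0, 1000, 2000), end = c(50, 1500, 7000),
                   terminal = FALSE)
  kept <- sizeSelect(fr, par)
  expect_equal(kept$end - kept$start, 500)
  expect_equal(nrow(sizeSelect(fr[0, ], par)), 0)
})

test_that("fragment pileup produces valid stepwise coverage", {
  gn <- tinyGenome(200, 150, 50)
  fr <- data.frame(chrom = "chrI", start = 0, end = 100, terminal = FALSE)
  tr <- fragmentsToTrack(fr, gn)
  expect_equal(trackRanges(tr)$score, 1)
  expect_equal(signalMass(tr), 100)

  fr2 <- data.frame(chrom = c("chrI", "chrI"), start = c(0, 50),
                    end = c(100, 150), terminal = FALSE)
  tr2 <- fragmentsToTrack(fr2, gn)
  expect_equal(GenomicRanges::start(trackRanges(tr2)), c(1, 51, 101))
  expect_equal(trackRanges(tr2)$score, c(1, 2, 1))

  expect_equal(length(trackRanges(fragmentsToTrack(fr2[0, ], gn))), 0)
  bad <- data.frame(chrom = "chrI", start = 150, end = 300,
                    terminal = FALSE)
  expect_error(fragmentsToTrack(bad, gn), class = "rerepError_outOfRange")
})

test_that("population digestion agrees with per-molecule digestion in yield", {
  gn <- RerepGenome(c(chrI = 50000, chrM = 1000), "chrM")
  ori <- OriginMap("chrI", 25000, 0, 1000)
  par <- demoParams()
  pop <- replicatePopulation(gn, ori, multiCycleSchedule(2), nCells = 20,
                             mitoCopies = 2)
  kept <- sizeSelect(digestPopulation(pop, par, seed = 3), par)
  # per-molecule route on the same label states
  mol <- populationMolecules(pop)
  lab <- pop@labels
  set.seed(3)
  singles <- 0
  for (i in seq_len(nrow(mol))) {
    li <- lab[lab$typeId == mol$typeId[i], ]
    for (cp in seq_len(mol$count[i])) {
      dm <- DuplexMolecule(mol$chrom[i], mol$start[i], mol$end[i],
        top = as.matrix(li[li$strand == "top", c("start", "end")]),
        bottom = as.matrix(li[li$strand == "bottom", c("start", "end")]))
      singles <- singles + nrow(sizeSelect(digestMolecule(dm, par), par))
    }
  }
  # both are draws from the same generative model; compare mean yields
  expect_gt(nrow(kept), 0)
  expect_lt(abs(nrow(kept) - singles) / singles, 0.15)
})

test_that("expected fragment yield rises with nick probability", {
  par0 <- demoParams()
  yields <- vapply(c(0.01, 0.03, 0.06), function(p) {
    par <- DigestParams(pNick = p)
    n <- 0
    for (i in 1:10) {
      mol <- DuplexMolecule("chrI", 0, 50000, top = cbind(0, 50000),
                            bottom = cbind(0, 50000))
      n <- n + nrow(sizeSelect(digestMolecule(mol, par,
                                              seed = i + p * 1000), par))
    }
    n
  }, 0)
  expect_true(all(diff(yields) > 0))
})

test_that("simulation is reproducible bit-for-bit under a fixed seed", {
  gn <- RerepGenome(c(chrI = 20000, chrM = 500), "chrM")
  ori <- OriginMap("chrI", 10000, 0, 1000)
  a <- simulateSample(gn, ori, timingSchedule(5), nCells = 10,
                      demoParams(), seed = 99, mitoCopies = 3)
  b <- simulateSample(gn, ori, timingSchedule(5), nCells = 10,
                      demoParams(), seed = 99, mitoCopies = 3)
  expect_identical(trackRanges(a$track)$score, trackRanges(b$track)$score)
  expect_identical(a$nFragments, b$nFragments)
  c <- simulateSample(gn, ori, timingSchedule(5), nCells = 10,
                      demoParams(), seed = 100, mitoCopies = 3)
  expect_false(identical(trackRanges(a$track)$score,
                         trackRanges(c$track)$score))
})

test_that("mitochondria are always fully double-labeled", {
  gn <- tinyGenome()
  ori <- OriginMap("chrI", 100, 0, 1000)
  pop <- replicatePopulation(gn, ori, multiCycleSchedule(1), nCells = 2,
                             mitoCopies = 4)
  mol <- populationMolecules(pop)
  mito <- mol[mol$chrom == "chrM", ]
  expect_equal(sum(mito$count), 2 * 4)
  lab <- pop@labels[pop@labels$typeId %in% mito$typeId, ]
  expect_setequal(lab$strand, c("top", "bottom"))
  expect_true(all(lab$end - lab$start == chromLengths(gn)[["chrM"]]))
})
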