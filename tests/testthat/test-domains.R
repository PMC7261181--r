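# independent linear-interpolation percentile (type-7 formula, written out)
manualQuantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

test_that("quartile classification extracts early and late runs", {
  gn <- RerepGenome(c(chrA = 80, chrM = 20), "chrM")
  v <- c(2, 2, 1.9, 1.5, 1.4, 1.2, 1, 1)
  prof <- binnedFromValues(gn, 10, list(chrA = v,
                                        chrM = rep(NA_real_, 2)))
  cls <- classifyTimingRegions(prof)
  q75 <- manualQuantile(v, 0.75); q25 <- manualQuantile(v, 0.25)
  expect_equal(attr(cls, "q75"), q75)
  expect_equal(attr(cls, "q25"), q25)
  early <- cls[cls$label == "early"]
  late <- cls[cls$label == "late"]
  nEarlyBins <- sum(v >= q75)
  nLateBins <- sum(v <= q25)
  expect_equal(sum(GenomicRanges::width(early)) / 10, nEarlyBins)
  expect_equal(sum(GenomicRanges::width(late)) / 10, nLateBins)
  expect_equal(GenomicRanges::start(early)[1], 1)
  expect_equal(GenomicRanges::end(late)[length(late)], 80)

  # monotone ramp over 8 bins: exactly 2 early and 2 late bins, one run each
  ramp <- binnedFromValues(gn, 10,
    list(chrA = seq(1, 2, length.out = 8), chrM = rep(NA_real_, 2)))
  cr <- classifyTimingRegions(ramp)
  expect_equal(cr$label, c("late", "early"))
  expect_equal(GenomicRanges::width(cr), c(20, 20))

  # alternating values give singleton runs
  alt <- binnedFromValues(gn, 10,
    list(chrA = rep(c(2, 1), 4), chrM = rep(NA_real_, 2)))
  ca <- classifyTimingRegions(alt)
  expect_true(all(GenomicRanges::width(ca) == 10))

  flat <- binnedFromValues(gn, 10,
    list(chrA = rep(1, 8), chrM = rep(NA_real_, 2)))
  expect_error(classifyTimingRegions(flat),
               class = "rerepError_degenerateQuartiles")
})

test_that("feature heatmap rows are windowed, sorted and padded", {
  gn <- RerepGenome(c(chrA = 100000, chrM = 1000), "chrM")
  cb <- constantBinned(gn, 100, 3)
  f1 <- GenomicRanges::GRanges("chrA", IRanges::IRanges(50001, 50001))
  f1$label <- "mid"
  hm <- featureHeatmap(cb, f1, 5000)
  expect_equal(dim(hm), c(1, 100))
  expect_true(all(hm == 3))

  # rows sorted by row sum, descending
  vals <- rep(1, 1000); vals[100:200] <- 10
  bt <- binnedFromValues(gn, 100, list(chrA = vals, chrM = rep(0, 10)))
  f2 <- GenomicRanges::GRanges(c("chrA", "chrA"),
          IRanges::IRanges(c(70001, 15001), width = 1))
  f2$label <- c("lowF", "highF")
  hm2 <- featureHeatmap(bt, f2, 2000)
  expect_equal(attr(hm2, "rowOrder"), c("highF", "lowF"))

  # a feature 5 kb from the start with a 25 kb flank: left 20 kb missing
  f3 <- GenomicRanges::GRanges("chrA", IRanges::IRanges(5001, 5001))
  f3$label <- "edge"
  hm3 <- featureHeatmap(cb, f3, 25000)
  expect_true(all(is.na(hm3[1, 1:200])))
  expect_true(all(!is.na(hm3[1, 201:500])))

  expect_error(featureHeatmap(cb, f1[0], 5000),
               class = "rerepError_noFeatures")
  # row order invariant under global positive rescaling
  bt10 <- binnedFromValues(gn, 100,
    list(chrA = vals * 17, chrM = rep(0, 10)))
  expect_equal(attr(featureHeatmap(bt10, f2, 2000), "rowOrder"),
               attr(hm2, "rowOrder"))
})

test_that("domain boundaries move to transition-zone midpoints", {
  mkDom <- function(starts0, ends0, labels, chrom = "chrA") {
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(starts0 + 1, ends0))
    gr$label <- labels
    gr
  }
  d <- mkDom(c(1000, 2000, 3000), c(2000, 3000, 4000),
             c("ERD", "TZ", "LRD"))
  ext <- extendDomainsToTzMidpoints(d)
  expect_equal(ext$label, c("ERD", "LRD"))
  expect_equal(GenomicRanges::start(ext) - 1, c(1000, 2500))
  expect_equal(GenomicRanges::end(ext), c(2500, 4000))
  # extended domains abut exactly, never overlap
  expect_true(GenomicRanges::isDisjoint(ext))

  # ERD at the chromosome start keeps its left boundary
  d2 <- mkDom(c(0, 5000), c(5000, 6000), c("ERD", "TZ"))
  ext2 <- extendDomainsToTzMidpoints(d2)
  expect_equal(GenomicRanges::start(ext2) - 1, 0)
  expect_equal(GenomicRanges::end(ext2), 5500)

  # LRD between two symmetric TZs grows by half of each
  d3 <- mkDom(c(0, 1000, 2000), c(1000, 2000, 3000),
              c("TZ", "LRD", "TZ"))
  ext3 <- extendDomainsToTzMidpoints(d3)
  expect_equal(GenomicRanges::width(ext3), 1000 + 500 + 500)

  over <- mkDom(c(0, 500), c(1000, 1500), c("ERD", "TZ"))
  expect_error(extendDomainsToTzMidpoints(over),
               class = "rerepError_overlap")
})

test_that("scaled profiles size-normalize domains onto 0-100%", {
  gn <- RerepGenome(c(chrA = 200000, chrM = 1000), "chrM")
  cb <- constantBinned(gn, 100, 2.5)
  dom <- GenomicRanges::GRanges("chrA", IRanges::IRanges(10001, 50000))
  dom$label <- "D"
  sp <- scaledDomainProfile(cb, dom, nPoints = 101)
  expect_true(all(sp$profiles == 2.5))
  expect_equal(sp$meta, rep(2.5, 101))

  # a linear ramp maps to a straight line in relative coordinates
  n <- 2000
  ramp <- binnedFromValues(gn, 100,
    list(chrA = seq(0, 10, length.out = n), chrM = rep(0, 10)))
  spr <- scaledDomainProfile(ramp, dom, nPoints = 51)
  d1 <- diff(spr$profiles[1, ])
  expect_true(all(abs(d1 - d1[1]) < 1e-9))

  # two domains with the same shape after scaling give identical profiles
  shape <- function(frac) sin(pi * frac)^2
  v <- numeric(n)
  putDomain <- function(v, s0, len) {
    idx <- which((seq_len(n) - 0.5) * 100 > s0 &
                   (seq_len(n) - 0.5) * 100 <= s0 + len)
    v[idx] <- shape(((idx - 0.5) * 100 - s0) / len)
    v
  }
  v <- putDomain(v, 10000, 10000)
  v <- putDomain(v, 100000, 80000)
  two <- binnedFromValues(gn, 100, list(chrA = v, chrM = rep(0, 10)))
  doms <- GenomicRanges::GRanges("chrA",
    IRanges::IRanges(c(10001, 100001), c(20000, 180000)))
  doms$label <- c("small", "big")
  sp2 <- scaledDomainProfile(two, doms, nPoints = 41)
  expect_lt(max(abs(sp2$profiles[1, ] - sp2$profiles[2, ])), 0.05)

  shortDom <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 150))
  expect_error(scaledDomainProfile(cb, shortDom),
               class = "rerepError_domainTooShort")
})

test_that("domain ranking is a deterministic length-weighted mean", {
  gn <- RerepGenome(c(chrA = 1000, chrM = 100), "chrM")
  vals <- c(rep(1, 5), rep(9, 5))
  bt <- binnedFromValues(gn, 100, list(chrA = vals, chrM = 1))
  doms <- GenomicRanges::GRanges(c("chrA", "chrA"),
    IRanges::IRanges(c(1, 501), c(500, 1000)))
  doms$label <- c("lowD", "highD")
  rk <- rankDomains(bt, doms)
  expect_equal(rk$domainId, c("highD", "lowD"))
  expect_equal(rk$meanSignal, c(9, 1))
  # a domain straddling both halves gets the weighted mean
  mix <- GenomicRanges::GRanges("chrA", IRanges::IRanges(401, 600))
  mix$label <- "mix"
  expect_equal(rankDomains(bt, mix)$meanSignal, 5)
  # ties break by id so ranking is reproducible
  tie <- GenomicRanges::GRanges(c("chrA", "chrA"),
    IRanges::IRanges(c(1, 101), c(100, 200)))
  tie$label <- c("b_dom", "a_dom")
  expect_equal(rankDomains(bt, tie)$domainId, c("a_dom", "b_dom"))
})

test_that("enrichment score matches the running-sum oracle", {
  rk <- data.frame(domainId = letters[1:6], meanSignal = 6:1)
  # query at the extremes pins the score to +/-1
  expect_equal(enrichmentScore(rk, c("a", "b"), 99, seed = 1)$es, 1)
  expect_equal(enrichmentScore(rk, c("e", "f"), 99, seed = 1)$es, -1)
  # hand-enumerated walk for query {b, e}:
  # -1/4, +1/4, 0, -1/4, +1/4, 0 -> magnitude tie resolves positive
  expect_equal(enrichmentScore(rk, c("b", "e"), 99, seed = 1)$es, 0.25)
  expect_error(enrichmentScore(rk, character(0), 9),
               class = "rerepError_badQuerySet")
  expect_error(enrichmentScore(rk, letters[1:6], 9),
               class = "rerepError_badQuerySet")
})

test_that("enrichment score agrees with fgsea on tie-free cases", {
  skip_if_not_installed("fgsea")
  withSeed(71, {
    for (i in 1:25) {
      n <- sample(8:30, 1)
      k <- sample(2:(n - 3), 1)
      stats <- sort(runif(n, -5, 5), decreasing = TRUE)
      names(stats) <- sprintf("d%02d", seq_len(n))
      sel <- sort(sample(n, k))
      member <- seq_len(n) %in% sel
      ours <- rerepseq:::cpp_es(member)
      theirs <- fgsea::calcGseaStat(stats, selectedStats = sel,
                                    gseaParam = 0)
      # exact integer walk to detect magnitude ties, where conventions
      # for the returned sign legitimately differ
      walk <- cumsum(ifelse(member, n - k, -k))
      tied <- max(walk) == -min(walk)
      if (!tied) expect_equal(ours, theirs, tolerance = 1e-9)
    }
  })
})

test_that("enrichment score is centered with uniform p-values under null", {
  withSeed(101, {
    ids <- sprintf("d%02d", 1:40)
    rk <- data.frame(domainId = ids, meanSignal = 40:1)
    draws <- replicate(500, {
      q <- sample(ids, 8)
      enrichmentScore(rk, q, nPermutations = 99)$es
    })
    expect_lt(abs(mean(draws)), 0.05)
  })
})
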