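test_that("RPM scaling multiplies by 1e6 over the library size", {
  gn <- RerepGenome(c(chrI = 200, chrM = 50),
                    "chrM")
  tr <- stepTrack(gn, "chrI", 0, 100, 5)
  expect_equal(trackRanges(rpmNormalize(tr, 2e6))$score, 2.5)
  expect_equal(trackRanges(rpmNormalize(tr, 1e6))$score, 5)
  empty <- stepTrack(gn, "chrI", numeric(0), numeric(0), numeric(0))
  expect_equal(length(trackRanges(rpmNormalize(empty, 100))), 0)
  expect_error(rpmNormalize(tr, 0), class = "rerepError_badTotal")
  # ratios between positions are preserved
  tr2 <- stepTrack(gn, "chrI", c(0, 100), c(100, 200), c(4, 1))
  out <- rpmNormalize(tr2, 31337)
  expect_equal(trackRanges(out)$score[1] / trackRanges(out)$score[2], 4)
})

test_that("mitochondrial scaling factors follow mean-fraction / fraction", {
  gn <- RerepGenome(c(chrA = 1000, chrM = 100), "chrM")
  mk <- function(nuc, mito, id) {
    gr <- GenomicRanges::GRanges(c("chrA", "chrM"),
            IRanges::IRanges(c(1, 1), c(1000, 100)))
    gr$score <- c(nuc, mito)
    CoverageTrack(gr, gn, id)
  }
  # mito fractions 0.10 and 0.20 -> factors 1.5 and 0.75
  sc <- mitoScale(list(mk(0.9, 1, "a"), mk(0.8, 2, "b")))
  expect_equal(unname(attr(sc, "factors")), c(1.5, 0.75))
  # equal fractions -> all factors 1; single sample -> factor 1
  sc2 <- mitoScale(list(mk(0.9, 1, "a"), mk(1.8, 2, "b")))
  expect_equal(unname(attr(sc2, "factors")), c(1, 1))
  expect_equal(unname(attr(mitoScale(list(mk(1, 1, "a"))), "factors")), 1)
  # zero mito signal is a named error naming the sample
  expect_error(mitoScale(list(mk(1, 0, "weird"))),
               class = "rerepError_zeroMito")
  expect_error(mitoScale(list(mk(1, 0, "weird"))), "weird")
})

test_that("scaled mitochondrial mass is equalized relative to input totals", {
  gn <- RerepGenome(c(chrA = 5000, chrB = 3000, chrM = 500), "chrM")
  withSeed(5, {
    tracks <- lapply(1:4, function(i) randomTrack(gn, id = paste0("s", i)))
    totals <- vapply(tracks, signalMass, 0)
    sc <- mitoScale(tracks)
    fbar <- mean(attr(sc, "fractions"))
    scaledMito <- vapply(sc, function(t) signalMass(t, "chrM"), 0)
    # every sample's scaled mito mass / pre-scaling total equals the mean
    # input fraction, to machine precision
    expect_equal(unname(scaledMito / totals), rep(fbar, 4),
                 tolerance = 1e-13)
  })
})

test_that("blacklist construction matches its definition on small cases", {
  gn <- RerepGenome(c(chrA = 100, chrM = 20), "chrM")
  # constant track: sigma = 0 and the inequality is strict -> empty
  bt <- constantBinned(gn, 10, 3)
  expect_equal(length(makeBlacklist(list(bt))), 0)

  # ten bins [1,...,1,100]: mu = 10.9, sigma ~ 29.7, only bin 10 over
  vals <- list(chrA = c(rep(1, 9), 100), chrM = rep(1, 2))
  bl <- makeBlacklist(list(binnedFromValues(gn, 10, vals)))
  expect_equal(length(bl), 1)
  expect_equal(GenomicRanges::start(bl), 91)
  expect_equal(GenomicRanges::end(bl), 100)
  mu <- mean(vals$chrA); sigma <- sqrt(mean((vals$chrA - mu)^2))
  expect_equal(attr(bl, "threshold"), mu + sigma)

  # adjacent hot bins merge into one interval
  vals2 <- list(chrA = c(rep(1, 8), 100, 100), chrM = rep(1, 2))
  bl2 <- makeBlacklist(list(binnedFromValues(gn, 10, vals2)))
  expect_equal(length(bl2), 1)
  expect_equal(c(GenomicRanges::start(bl2), GenomicRanges::end(bl2)),
               c(81, 100))
})

test_that("blacklist application masks overlapping bins only", {
  gn <- RerepGenome(c(chrA = 100, chrM = 20), "chrM")
  vals <- list(chrA = c(rep(1, 9), 100), chrM = rep(1, 2))
  bt <- binnedFromValues(gn, 10, vals)
  bl <- makeBlacklist(list(bt))
  masked <- applyBlacklist(bt, bl)
  expect_true(is.na(binValues(masked)$chrA[10]))
  expect_equal(binValues(masked)$chrA[1:9], rep(1, 9))
  # empty blacklist is the identity
  expect_equal(binValues(applyBlacklist(bt, GenomicRanges::GRanges())),
               binValues(bt))
  # an interval straddling two bins masks both
  straddle <- GenomicRanges::GRanges("chrA", IRanges::IRanges(25, 35))
  masked2 <- applyBlacklist(bt, straddle)
  expect_true(all(is.na(binValues(masked2)$chrA[3:4])))
  expect_false(anyNA(binValues(masked2)$chrA[c(1:2, 5:10)]))
})

test_that("replicate averaging propagates missingness", {
  gn <- RerepGenome(c(chrA = 40, chrM = 20), "chrM")
  a <- binnedFromValues(gn, 20, list(chrA = c(1, 2), chrM = 1))
  b <- binnedFromValues(gn, 20, list(chrA = c(3, 4), chrM = 3))
  avg <- averageReplicates(list(a, b))
  expect_equal(binValues(avg)$chrA, c(2, 3))
  expect_equal(binValues(averageReplicates(list(a)))$chrA, c(1, 2))
  aMiss <- binnedFromValues(gn, 20, list(chrA = c(NA, 2), chrM = 1))
  expect_true(is.na(binValues(averageReplicates(list(aMiss, b)))$chrA[1]))
  wrongGrid <- binnedFromValues(gn, 10,
    list(chrA = rep(1, 4), chrM = rep(1, 2)))
  expect_error(averageReplicates(list(a, wrongGrid)),
               class = "rerepError_gridMismatch")
})

test_that("masking then averaging commutes with averaging then masking", {
  gn <- RerepGenome(c(chrA = 100, chrM = 20), "chrM")
  withSeed(21, {
    for (i in 1:5) {
      mk <- function() binnedFromValues(gn, 10,
        list(chrA = runif(10, 0, 5), chrM = runif(2, 0, 5)))
      reps <- list(mk(), mk(), mk())
      bl <- GenomicRanges::GRanges("chrA",
        IRanges::IRanges(sample(1:90, 1), width = 15))
      viaA <- averageReplicates(lapply(reps, applyBlacklist,
                                       blacklist = bl))
      viaB <- applyBlacklist(averageReplicates(reps), bl)
      expect_equal(binValues(viaA), binValues(viaB))
    }
  })
})

test_that("replicate Spearman matches the rank formula and edge cases", {
  gn <- RerepGenome(c(chrA = 80, chrM = 20), "chrM")
  mk <- function(v) binnedFromValues(gn, 20,
    list(chrA = v, chrM = rep(NA_real_, 1)))
  a <- mk(c(1, 2, 3, 4))
  expect_equal(replicateSpearman(a, a), 1)
  expect_equal(replicateSpearman(a, mk(c(4, 3, 2, 1))), -1)
  # d^2 sum = 2 -> rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(replicateSpearman(a, mk(c(1, 3, 2, 4))), 0.8)
  tooFew <- mk(c(1, NA, NA, 2))
  expect_error(replicateSpearman(tooFew, tooFew),
               class = "rerepError_tooFewBins")
})
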