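test_that("binned coverage counts every overlapped bin, per strand", {
  gm <- GenomeModel(c(chr1 = 1000),
                    data.frame(chrom = "chr1", pos = 10, b6 = "A",
                               cast = "G"))
  fr <- GRanges("chr1", IRanges(101, 250), strand = "+")  # BED [100,250)
  cov <- computeCoverage(fr, 100, gm)
  expect_equal(cov$chr1[, "F"], c(0L, 1L, 1L, rep(0L, 7)))
  expect_equal(sum(cov$chr1[, "R"]), 0L)

  empty <- computeCoverage(GRanges(), 100, gm)
  expect_true(all(empty$chr1 == 0))

  expect_error(computeCoverage(GRanges("chr9", IRanges(1, 10), strand = "+"),
                               100, gm), "unknown chromosome")

  # 300 random fragments against per-base brute force on an odd binsize
  set.seed(21)
  st <- sample.int(19000, 300)
  frR <- GRanges("chr1", IRanges(st, width = sample(50:400, 300,
                                                    replace = TRUE)),
                 strand = sample(c("+", "-"), 300, replace = TRUE))
  gm2 <- GenomeModel(c(chr1 = 20000),
                     data.frame(chrom = "chr1", pos = 10, b6 = "A",
                                cast = "G"))
  got <- computeCoverage(frR, 73, gm2)$chr1
  want <- oracleCoverage(frR, 73, 20000)
  expect_equal(got, want)
  # sum over bins >= number of fragments
  expect_gte(sum(got), length(frR))
})

test_that("background rate estimation is exact arithmetic and recovers truth", {
  gm <- gridGenome(1e6)
  set.seed(3)
  fr <- GRanges("chr1", IRanges(sample.int(999000, 1000), width = 150),
                strand = "+")
  expect_equal(estimateBackground(fr, GRanges(), gm), 0.001)

  mask <- GRanges("chr1", IRanges(1, 1e6))
  expect_error(estimateBackground(fr, mask, gm), "no unmasked")

  maskHalf <- GRanges("chr1", IRanges(1, 999000 + 151))
  expect_warning(rho0 <- estimateBackground(fr, maskHalf, gm),
                 "half the genome")
  expect_equal(rho0, 0)

  # recovery from a simulated sample with signal masked out
  gm2 <- gridGenome(2e6)
  hs <- gridHotspots(n = 20, spacing = 90000, first = 100000, fTrue = 0.5)
  cfg <- presetConfig("DMC1KO", "RPA", nSignalFragments = 2e4,
                      backgroundRate = 0.05, seed = 22)
  fr2 <- simulateFragments(gm2, hs, cfg)   # ~1e5 background fragments
  rho <- estimateBackground(fr2, hs + 5000, gm2)
  expect_lt(abs(rho - 0.05) / 0.05, 0.05)
})

test_that("an extreme cluster yields exactly one covering peak", {
  gm <- gridGenome(1e5)
  set.seed(4)
  bg <- GRanges("chr1", IRanges(sample.int(99000, 100), width = 150),
                strand = "+")
  cl <- GRanges("chr1", IRanges(round(rnorm(200, 10000, 300)), width = 150),
                strand = "+")
  pk <- callPeaks(suppressWarnings(c(bg, cl)), gm, rho = 1e-3)
  expect_equal(length(pk), 1L)
  expect_true(start(pk) <= 10000 && end(pk) >= 10000)
  expect_gt(mcols(pk)$correctedIntensity, 150)
})

test_that("pure background stays below the nominal false-peak rate", {
  gm <- GenomeModel(c(chr1 = 1e7),
                    data.frame(chrom = "chr1", pos = 100, b6 = "A",
                               cast = "G"))
  set.seed(5)
  n <- rpois(1, 1e-3 * 1e7)
  fr <- GRanges("chr1", IRanges(sample.int(1e7 - 200, n), width = 150),
                strand = sample(c("+", "-"), n, replace = TRUE))
  pk <- callPeaks(fr, gm, rho = 1e-3, qMax = 0.01)
  expect_lte(length(pk) / metadata(pk)$nWindows, 0.01)
})

test_that("simulated hotspots are recovered near their centers", {
  gm <- gridGenome(2e6)
  hs <- gridHotspots(n = 50, spacing = 35000, first = 50000, fTrue = 0.5)
  cfg <- presetConfig("DMC1KO", "RPA", nSignalFragments = 5000,
                      backgroundRate = 1e-5, seed = 23)
  fr <- simulateFragments(gm, hs, cfg)   # ~100 fragments per hotspot
  rho <- estimateBackground(fr, hs + 5000, gm)
  pk <- callPeaks(fr, gm, rho = max(rho, 1e-6))
  ctr <- GRanges("chr1", IRanges(mcols(hs)$center, width = 1))
  dd <- GenomicRanges::distanceToNearest(ctr, pk)
  hit <- mean(mcols(dd)$distance <= 1000)
  expect_gte(hit, 0.95)
})

test_that("corrected intensity follows its defining arithmetic", {
  pk <- GRanges("chr1", IRanges(1, 2000))
  fr <- GRanges("chr1", IRanges(rep(900, 100), width = 150), strand = "+")
  expect_equal(correctedIntensity(pk, fr, 0.01), 80)
  expect_equal(correctedIntensity(GRanges("chr1", IRanges(3001, 3500)),
                                  fr, 0.01), -5)
  expect_equal(correctedIntensity(pk, fr, 0), 100)

  # linear in n, invariant under fragment permutation
  set.seed(6)
  frR <- GRanges("chr1", IRanges(sample.int(1900, 500, replace = TRUE),
                                 width = 120), strand = "+")
  i1 <- correctedIntensity(pk, frR, 0.02)
  i2 <- correctedIntensity(pk, suppressWarnings(c(frR, frR)), 0.02)
  expect_equal(i2 + 0.02 * 2000, 2 * (i1 + 0.02 * 2000))
  expect_equal(correctedIntensity(pk, frR[sample(500)], 0.02), i1)
})

test_that("peak calling is deterministic for fixed input", {
  gm <- gridGenome(5e5)
  hs <- gridHotspots(n = 5, spacing = 80000, first = 50000, fTrue = 0.5)
  fr <- simulateFragments(gm, hs,
                          presetConfig("DMC1KO", "RPA",
                                       nSignalFragments = 3000,
                                       backgroundRate = 1e-4, seed = 24))
  p1 <- callPeaks(fr, gm, rho = 1e-4)
  p2 <- callPeaks(fr, gm, rho = 1e-4)
  expect_identical(start(p1), start(p2))
  expect_identical(mcols(p1)$q, mcols(p2)$q)
})
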