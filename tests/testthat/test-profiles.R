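test_that("a single fragment lands in the documented bin, with mirror law", {
  gm <- gridGenome(2e4, 200)
  # center at 0-based 5000 (internal 5001)
  hsP <- makeHotspots("chr1", start = 4001, end = 6001, center = 5001,
                      heat = 1, fTrue = 0.97, orientation = "+")
  sym <- S4Vectors::DataFrame(hotspotId = "hs00001",
                              label = "asymmetric_B6")
  fr <- GRanges("chr1", IRanges(4001, 4150), strand = "+",  # BED [4000,4150)
                fragmentId = "f1", truthHaplotype = "B6")
  calls <- S4Vectors::DataFrame(fragmentId = "f1", call = "B6",
                                nB6 = 1L, nCast = 0L)
  prof <- aggregateProfile(fr, calls, hsP, sym, binsize = 40,
                           halfWidth = 2400)
  v <- profileValues(prof)
  bs <- binStarts(prof)
  # midpoint offset -925 falls in the bin starting at -960
  expect_equal(sum(v), 1)
  expect_equal(v[bs == -960, "F.dsb_initiating"], 1,
               ignore_attr = TRUE)

  # orientation "-": the distance mirrors to +925 and the strand flips to R
  hsM <- makeHotspots("chr1", start = 4001, end = 6001, center = 5001,
                      heat = 1, fTrue = 0.97, orientation = "-")
  profM <- aggregateProfile(fr, calls, hsM, sym, binsize = 40,
                            halfWidth = 2400)
  vM <- profileValues(profM)
  expect_equal(vM[bs == 920, "R.dsb_initiating"], 1, ignore_attr = TRUE)
  expect_equal(sum(vM), 1)
})

test_that("vectorized binning equals the per-fragment brute force", {
  gs <- simulateGenome(nChroms = 1, chromLen = 2e6, nHotspots = 30,
                       fDist = list(pSymmetric = 0.3, pAsymB6 = 0.4,
                                    pAsymCast = 0.3, fSymmetric = 0.5,
                                    fAsymB6 = 0.97, fAsymCast = 0.03),
                       xFraction = 0, minSeparation = 20000, seed = 31)
  fr <- simulateFragments(gs$genome, gs$hotspots,
                          presetConfig("WT", "RPA", nSignalFragments = 10000,
                                       backgroundRate = 2e-5, seed = 32))
  calls <- assignHaplotype(fr, gs$genome, seed = 33)
  sym <- truthSymmetry(gs$hotspots)
  prof <- aggregateProfile(fr, calls, gs$hotspots, sym, binsize = 80,
                           halfWidth = 2400)
  want <- oracleProfile(fr, calls, gs$hotspots, sym, 80, 2400)
  expect_equal(profileValues(prof), want$values)
  expect_equal(prof@nFragments, want$nFragments)
  # mass conservation
  expect_equal(sum(profileValues(prof)) * prof@nHotspots,
               prof@nFragments)
})

test_that("repair-template panels are dominated by true template fragments", {
  gs <- simulateGenome(nChroms = 1, chromLen = 4e6, nHotspots = 60,
                       fDist = list(pSymmetric = 0, pAsymB6 = 0.5,
                                    pAsymCast = 0.5, fSymmetric = 0.5,
                                    fAsymB6 = 0.97, fAsymCast = 0.03),
                       xFraction = 0, minSeparation = 30000, seed = 34)
  # equal DSB/template shares: template-panel contamination is then the 3%
  # minor-homolog DSB share (a smaller template share scales it up by
  # (1 - w) / w, which is why the preset's w = 0.3 sits near 93%)
  cfg <- presetConfig("WT", "RPA", nSignalFragments = 1e5,
                      backgroundRate = 1e-5, seed = 35)
  cfg@weights[] <- 0
  cfg@weights[c("filament_full", "repair_template")] <- 0.5
  fr <- simulateFragments(gs$genome, gs$hotspots, cfg)
  calls <- truthCalls(fr)   # perfect haplotyping
  sym <- truthSymmetry(gs$hotspots)
  full <- aggregateProfile(fr, calls, gs$hotspots, sym)
  tplOnly <- mcols(fr)$truthRole == "repair_template"
  tpl <- aggregateProfile(fr[tplOnly], calls[tplOnly, ], gs$hotspots, sym)
  panels <- c("F.repair_template", "R.repair_template")
  purity <- sum(profileValues(tpl)[, panels]) /
    sum(profileValues(full)[, panels])
  expect_gte(purity, 0.95)
})

test_that("knockout template panels sit at background while WT peaks", {
  gs <- simulateGenome(nChroms = 1, chromLen = 4e6, nHotspots = 60,
                       fDist = list(pSymmetric = 0, pAsymB6 = 0.5,
                                    pAsymCast = 0.5, fSymmetric = 0.5,
                                    fAsymB6 = 1, fAsymCast = 0),
                       xFraction = 0, minSeparation = 30000, seed = 36)
  bgRate <- 5e-5
  mkProf <- function(genotype, seed) {
    fr <- simulateFragments(gs$genome, gs$hotspots,
                            presetConfig(genotype, "RPA",
                                         nSignalFragments = 1e5,
                                         backgroundRate = bgRate,
                                         seed = seed))
    aggregateProfile(fr, assignHaplotype(fr, gs$genome, seed = seed + 1),
                     gs$hotspots, truthSymmetry(gs$hotspots))
  }
  profKO <- mkProf("DMC1KO", 37)
  profWT <- mkProf("WT", 39)
  pInf <- informativeProbability(snpSpacing = 200)
  ko <- templateBackgroundTest(profKO, bgRate, pInf)
  wt <- templateBackgroundTest(profWT, bgRate, pInf)
  expect_gt(ko$pValue, 0.01)       # indistinguishable from background
  expect_lt(wt$pValue, 1e-10)      # template signal demands strand exchange
  expect_gt(wt$excessRatio, 5)
})

test_that("mirror check quantifies wrong-polarity mass", {
  gs <- simulateGenome(nChroms = 1, chromLen = 4e6, nHotspots = 60,
                       fDist = list(pSymmetric = 0, pAsymB6 = 0.5,
                                    pAsymCast = 0.5, fSymmetric = 0.5,
                                    fAsymB6 = 1, fAsymCast = 0),
                       xFraction = 0, minSeparation = 30000, seed = 41)
  mkProf <- function(genotype, seed, bg = 1e-5) {
    fr <- simulateFragments(gs$genome, gs$hotspots,
                            presetConfig(genotype, "RPA",
                                         nSignalFragments = 5e4,
                                         backgroundRate = bg, seed = seed))
    aggregateProfile(fr, assignHaplotype(fr, gs$genome, seed = seed + 1),
                     gs$hotspots, truthSymmetry(gs$hotspots))
  }
  # profiles are center-referenced, so the break-position spread (SD 150)
  # bleeds ~4% of mass across zero even without a wrong-polarity
  # component; beyond 4 SD of that spread the knockout carries essentially
  # nothing while the WT wrong-polarity component still shows
  mKO <- profileMirrorCheck(mkProf("DMC1KO", 42), tolerance = 600)
  expect_true(all(mKO$fracWrong < 0.01))
  mWT <- profileMirrorCheck(mkProf("WT", 43), tolerance = 600)
  expect_true(all(mWT$fracWrong > 0.005))
  expect_gt(min(mWT$fracWrong) / max(mKO$fracWrong), 3)

  # pure uniform background splits its mass evenly between the sides
  gm <- gridGenome(1e6, 200)
  hsU <- gridHotspots(n = 5, spacing = 100000, first = 100000, fTrue = 1)
  symU <- S4Vectors::DataFrame(hotspotId = mcols(hsU)$hotspotId,
                               label = "asymmetric_B6")
  frU <- simulateFragments(gm, hsU,
                           presetConfig("DMC1KO", "RPA",
                                        nSignalFragments = 0,
                                        backgroundRate = 0.02, seed = 44))
  profU <- aggregateProfile(frU, assignHaplotype(frU, gm, seed = 45),
                            hsU, symU)
  mU <- profileMirrorCheck(profU)
  total <- mU$massCorrect + mU$massWrong
  # binomial 4-sigma band around an even split
  tol <- 4 * 0.5 / sqrt(total * profU@nHotspots)
  expect_true(all(abs(mU$fracWrong - 0.5) < tol))
})
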