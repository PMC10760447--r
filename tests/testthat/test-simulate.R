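test_that("presets encode the genotype/protein contrasts", {
  koRpa <- presetConfig("DMC1KO", "RPA")
  expect_equal(unname(koRpa@weights["repair_template"]), 0)
  expect_equal(unname(koRpa@weights["return_binding"]), 0)
  expect_equal(unname(koRpa@weights["wrong_polarity"]), 0)

  wtRpa <- presetConfig("WT", "RPA")
  expect_equal(wtRpa@returnBindingOffset, 750)
  expect_gt(unname(wtRpa@weights["repair_template"]), 0)

  # DMC1 occupies the break-proximal filament, so WT RAD51 has none
  expect_equal(unname(presetConfig("WT", "RAD51")@weights["filament_proximal"]),
               0)
  expect_equal(unname(presetConfig("DMC1KO", "RAD51")@weights["filament_full"]),
               1)
  expect_error(presetConfig("DMC1KO", "DMC1"), "knockout")

  # knockouts cannot carry strand-exchange-dependent components at all
  expect_error(SimulationConfig(genotype = "DMC1KO",
                                weights = c(filament_full = 0.7,
                                            repair_template = 0.3)),
               "strand-exchange")
  expect_error(SimulationConfig(weights = c(filament_full = 0.5)),
               "sum to 1")
})

test_that("strand-exchange-defective genotypes emit zero repair-template fragments", {
  gm <- gridGenome(1e6)
  hs <- gridHotspots(n = 10, fTrue = c(0.5, 0.97))
  for (protein in c("RPA", "RAD51")) {
    fr <- simulateFragments(gm, hs,
                            presetConfig("DMC1KO", protein,
                                         nSignalFragments = 10000, seed = 11))
    expect_equal(sum(mcols(fr)$truthRole == "repair_template"), 0L,
                 info = protein)
  }
})

test_that("haplotype of origin follows the per-hotspot B6 fraction", {
  gm <- gridGenome(1e5)
  hs1 <- gridHotspots(n = 1, first = 50000, fTrue = 1)
  fr <- simulateFragments(gm, hs1,
                          presetConfig("WT", "RPA", nSignalFragments = 10000,
                                       backgroundRate = 0, seed = 3))
  dsb <- mcols(fr)$truthRole == "dsb_initiating"
  expect_true(all(mcols(fr)$truthHaplotype[dsb] == "B6"))
  # at f = 1 the repair template is always the CAST homolog
  expect_true(all(mcols(fr)$truthHaplotype[!dsb] == "CAST"))

  hs07 <- gridHotspots(n = 1, first = 50000, fTrue = 0.7)
  fr2 <- simulateFragments(gm, hs07,
                           presetConfig("DMC1KO", "RPA",
                                        nSignalFragments = 10000,
                                        backgroundRate = 0, seed = 4))
  nB6 <- sum(mcols(fr2)$truthHaplotype == "B6")
  # exact binomial 99% central interval around p = 0.7
  expect_gte(nB6, qbinom(0.005, 10000, 0.7))
  expect_lte(nB6, qbinom(0.995, 10000, 0.7))
})

test_that("strand polarity law holds for DSB-initiating fragments", {
  gm <- gridGenome(2e6)
  hs <- gridHotspots(n = 20, spacing = 90000, first = 100000, fTrue = 0.5)
  # KO preset: no wrong-polarity component
  fr <- simulateFragments(gm, hs,
                          presetConfig("DMC1KO", "RPA",
                                       nSignalFragments = 20000,
                                       backgroundRate = 0, seed = 6))
  dsb <- mcols(fr)$truthRole == "dsb_initiating"
  fwd <- as.character(strand(fr)) == "+"
  brk <- mcols(fr)$truthBreak
  # forward-strand ssDNA ends at or left of its break
  expect_true(all(end(fr)[dsb & fwd] < brk[dsb & fwd]))
  # reverse-strand ssDNA starts at or right of its break
  expect_true(all(start(fr)[dsb & !fwd] >= brk[dsb & !fwd]))
})

test_that("per-hotspot fragment counts are proportional to heat", {
  gm <- gridGenome(2e6)
  set.seed(99)
  heats <- rgamma(50, shape = 2, rate = 2)
  hs <- gridHotspots(n = 50, spacing = 30000, first = 50000, fTrue = 0.5,
                     heat = heats)
  fr <- simulateFragments(gm, hs,
                          presetConfig("DMC1KO", "RPA",
                                       nSignalFragments = 1e5,
                                       backgroundRate = 0, seed = 7))
  counts <- table(factor(mcols(fr)$truthHotspot,
                         levels = mcols(hs)$hotspotId))
  gof <- chisq.test(as.numeric(counts), p = heats / sum(heats))
  expect_gt(gof$p.value, 0.01)
})

test_that("X non-PAR hotspots never yield repair-template fragments", {
  gmX <- GenomeModel(
    c(chr1 = 1e6, chrX = 1e6),
    data.frame(chrom = rep(c("chr1", "chrX"), each = 100),
               pos = rep(seq(5000, 995000, by = 10000), 2),
               b6 = "A", cast = "G"),
    xNonPar = GRanges("chrX", IRanges(1, 1e6)))
  hs <- suppressWarnings(
    c(gridHotspots(chrom = "chr1", n = 5, fTrue = 0.97),
      gridHotspots(chrom = "chrX", n = 5, fTrue = 1, onXNonPar = TRUE)))
  mcols(hs)$hotspotId <- sprintf("hs%05d", seq_along(hs))
  fr <- simulateFragments(gmX, hs,
                          presetConfig("WT", "RPA", nSignalFragments = 20000,
                                       backgroundRate = 0, seed = 8))
  xIds <- mcols(hs)$hotspotId[mcols(hs)$onXNonPar]
  onX <- mcols(fr)$truthHotspot %in% xIds
  expect_gt(sum(onX), 0)
  expect_true(all(mcols(fr)$truthRole[onX] != "repair_template"))
  expect_true(all(mcols(fr)$truthHaplotype[onX] == "B6"))
})

test_that("fragment simulation is deterministic and counts truncations", {
  gm <- gridGenome(1e5)
  hs <- gridHotspots(n = 1, first = 1500, fTrue = 0.5, halfWidth = 1000)
  cfg <- presetConfig("DMC1KO", "RPA", nSignalFragments = 5000,
                      backgroundRate = 1e-4, seed = 10)
  a <- simulateFragments(gm, hs, cfg)
  b <- simulateFragments(gm, hs, cfg)
  expect_identical(start(a), start(b))
  expect_identical(as.character(strand(a)), as.character(strand(b)))
  expect_identical(mcols(a)$truthHaplotype, mcols(b)$truthHaplotype)
  md <- metadata(a)
  # hotspot sits 1.5 kb from the chromosome start; resection tails overrun
  expect_gt(md$nTruncated, 0)
  expect_equal(length(a), md$nSignal + md$nBackground)
  expect_true(all(start(a) >= 1 & end(a) <= 1e5))
})
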