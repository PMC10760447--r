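.pipelineDefaults <- function() {
  list(
    seed = 1,
    protein = "RPA",
    genome = list(nChroms = 2, chromLen = 2e6, snpSpacing = 200,
                  nHotspots = 100, xFraction = 0.1, minSeparation = 10000,
                  hotspotHalfWidth = 1000),
    simulate = list(nSignalFragments = 2e5, backgroundRate = 5e-5,
                    interHomologLifespanMultiplier = 1, dsbSd = 150),
    h3k4me3 = list(n = 1e5, spreadSd = 300),
    peaks = list(window = 1000, mergeGap = 500, qMax = 0.01, minCount = 5,
                 maskPad = 3000),
    haplotype = list(epsilon = 0, nMin = 10),
    profile = list(binsize = 40, halfWidth = 2400),
    deconv = list(lambda = 0),
    compare = list(nBoot = 2000))
}

.mergeConfig <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]))
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' YAML with blocks `genome`, `simulate`, `h3k4me3`, `peaks`, `haplotype`,
#' `profile`, `deconv`, `compare` plus top-level `seed` and `protein`;
#' unspecified parameters take the documented defaults. Stage seeds are
#' derived from the global seed by stage-index offset.
#'
#' @param path YAML file path (or a list already in config shape).
#' @return full configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- .mergeConfig(.pipelineDefaults(), user)
  if (!cfg$protein %in% c("RPA", "RAD51", "DMC1"))
    stop("config: unknown protein", call. = FALSE)
  cfg
}

.writeSignalTsv <- function(tab, path) {
  tab$intensity <- .fmtNum(tab$intensity)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writePeaksTsv <- function(peaks, path) {
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                  start = BiocGenerics::start(peaks) - 1,
                  end = BiocGenerics::end(peaks),
                  n = S4Vectors::mcols(peaks)$n,
                  mu = .fmtNum(S4Vectors::mcols(peaks)$mu),
                  correctedIntensity =
                    .fmtNum(S4Vectors::mcols(peaks)$correctedIntensity),
                  p = .fmtNum(S4Vectors::mcols(peaks)$p),
                  q = .fmtNum(S4Vectors::mcols(peaks)$q))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# two-pass background estimate: conservative first-pass peaks from the
# naive genome-wide rate, then rho from fragments outside the padded peaks
.estimateRho <- function(fragments, genome, pk) {
  rho0 <- length(fragments) / genomeLength(genome)
  p1 <- callPeaks(fragments, genome, rho = rho0, window = pk$window,
                  mergeGap = pk$mergeGap, qMax = pk$qMax,
                  minCount = pk$minCount)
  mask <- if (length(p1) == 0) GenomicRanges::GRanges() else
    p1 + pk$maskPad
  estimateBackground(fragments, mask, genome)
}

#' Run the full simulate-to-compare pipeline
#'
#' Orchestrates one end-to-end in-silico experiment: simulate an F1-hybrid
#' genome and hotspots; simulate SSDS fragments for the wild type and the
#' strand-exchange-defective knockout plus an H3K4me3-like set for f;
#' estimate the background rate and call peaks per genotype; assign
#' haplotypes; classify hotspot symmetry from the H3K4me3-like fragments;
#' build strand/role-resolved profiles and deconvolve footprints; compute
#' background-corrected per-hotspot intensities; and compare intensity
#' classes across genotypes. All artifacts are written to `outDir` and a
#' SHA-256 manifest is produced; rerunning with the same configuration
#' reproduces the manifest byte-identically.
#'
#' @param config configuration list or YAML path (see
#'   [readPipelineConfig()]).
#' @param outDir output directory (created if absent).
#' @return invisibly, `list(manifest, summary, files)`.
#' @export
runPipeline <- function(config, outDir) {
  cfg <- readPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  files <- character(0)
  emit <- function(name) {
    p <- file.path(outDir, name)
    files <<- c(files, p)
    p
  }

  g <- cfg$genome
  gsArgs <- list(nChroms = g$nChroms, chromLen = g$chromLen,
                 snpSpacing = g$snpSpacing, nHotspots = g$nHotspots,
                 xFraction = g$xFraction,
                 hotspotHalfWidth = g$hotspotHalfWidth,
                 minSeparation = g$minSeparation,
                 seed = .stageSeed(seed, 1))
  if (!is.null(g$fDist)) gsArgs$fDist <- g$fDist
  if (!is.null(g$heatDist)) gsArgs$heatDist <- g$heatDist
  gs <- do.call(simulateGenome, gsArgs)
  genome <- gs$genome
  hs <- gs$hotspots
  writeSnpsTsv(snps(genome), emit("snps.tsv"))
  writeHotspotsBed(hs, emit("hotspots.bed"))

  s <- cfg$simulate
  cfgWT <- presetConfig("WT", cfg$protein, seed = .stageSeed(seed, 2),
                        nSignalFragments = s$nSignalFragments,
                        backgroundRate = s$backgroundRate, dsbSd = s$dsbSd,
                        interHomologLifespanMultiplier =
                          s$interHomologLifespanMultiplier)
  cfgKO <- presetConfig("DMC1KO", ifelse(cfg$protein == "DMC1", "RAD51",
                                         cfg$protein),
                        seed = .stageSeed(seed, 3),
                        nSignalFragments = s$nSignalFragments,
                        backgroundRate = s$backgroundRate, dsbSd = s$dsbSd)
  frWT <- simulateFragments(genome, hs, cfgWT)
  frKO <- simulateFragments(genome, hs, cfgKO)
  frH3 <- simulateH3k4me3(genome, hs, n = cfg$h3k4me3$n,
                          seed = .stageSeed(seed, 4),
                          spreadSd = cfg$h3k4me3$spreadSd)
  writeFragmentsBed(frWT, emit("wt.fragments.bed"))
  writeFragmentsBed(frKO, emit("ko.fragments.bed"))
  writeFragmentsBed(frH3, emit("h3k4.fragments.bed"))

  pk <- cfg$peaks
  rhoWT <- .estimateRho(frWT, genome, pk)
  rhoKO <- .estimateRho(frKO, genome, pk)
  peaksWT <- callPeaks(frWT, genome, rho = rhoWT, window = pk$window,
                       mergeGap = pk$mergeGap, qMax = pk$qMax,
                       minCount = pk$minCount)
  peaksKO <- callPeaks(frKO, genome, rho = rhoKO, window = pk$window,
                       mergeGap = pk$mergeGap, qMax = pk$qMax,
                       minCount = pk$minCount)
  .writePeaksTsv(peaksWT, emit("wt.peaks.tsv"))
  .writePeaksTsv(peaksKO, emit("ko.peaks.tsv"))

  hp <- cfg$haplotype
  callsWT <- assignHaplotype(frWT, genome, epsilon = hp$epsilon,
                             seed = .stageSeed(seed, 5))
  callsKO <- assignHaplotype(frKO, genome, epsilon = hp$epsilon,
                             seed = .stageSeed(seed, 6))
  callsH3 <- assignHaplotype(frH3, genome, epsilon = hp$epsilon,
                             seed = .stageSeed(seed, 7))
  symmetry <- estimateF(hs, callsH3, frH3, nMin = hp$nMin)
  sdf <- as.data.frame(symmetry)
  for (cc in c("fHat", "ciLow", "ciHigh")) sdf[[cc]] <- .fmtNum(sdf[[cc]])
  write.table(sdf, emit("symmetry.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  pr <- cfg$profile
  profWT <- aggregateProfile(frWT, callsWT, hs, symmetry,
                             binsize = pr$binsize, halfWidth = pr$halfWidth)
  profKO <- aggregateProfile(frKO, callsKO, hs, symmetry,
                             binsize = pr$binsize, halfWidth = pr$halfWidth)
  writeProfileTsv(profWT, emit("wt.profile.tsv"))
  writeProfileTsv(profKO, emit("ko.profile.tsv"))

  kern <- dsbLocationKernel(s$dsbSd, pr$binsize)
  fpWT <- footprintPipeline(profWT, kern, lambda = cfg$deconv$lambda)
  fpKO <- footprintPipeline(profKO, kern, lambda = cfg$deconv$lambda)
  writeFootprintTsv(fpWT, emit("wt.footprint.tsv"))
  writeFootprintTsv(fpKO, emit("ko.footprint.tsv"))

  tabWT <- data.frame(hotspotId = S4Vectors::mcols(hs)$hotspotId,
                      intensity = correctedIntensity(hs, frWT, rhoWT))
  tabKO <- data.frame(hotspotId = S4Vectors::mcols(hs)$hotspotId,
                      intensity = correctedIntensity(hs, frKO, rhoKO))
  .writeSignalTsv(tabWT, emit("wt.signal.tsv"))
  .writeSignalTsv(tabKO, emit("ko.signal.tsv"))

  comparison <- compareClasses(tabWT, tabKO, symmetry, hs,
                               seed = .stageSeed(seed, 8),
                               nBoot = cfg$compare$nBoot)
  cmp <- comparison
  for (cc in c("medianLog2Ratio", "ciLow", "ciHigh"))
    cmp[[cc]] <- .fmtNum(cmp[[cc]])
  write.table(cmp, emit("comparison.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # template-panel mass vs the analytic uniform-background expectation
  pInf <- informativeProbability(snpSpacing = g$snpSpacing)
  dWT <- templateBackgroundTest(profWT, rhoWT, pInf)
  dKO <- templateBackgroundTest(profKO, rhoKO, pInf)
  summary <- list(
    protein = cfg$protein,
    nFragmentsWT = length(frWT), nFragmentsKO = length(frKO),
    rhoWT = rhoWT, rhoKO = rhoKO,
    nPeaksWT = length(peaksWT), nPeaksKO = length(peaksKO),
    nAsymmetric = sum(symmetry$label %in%
                      c("asymmetric_B6", "asymmetric_CAST")),
    wtTemplateExcessRatio = dWT$excessRatio,
    koTemplateExcessRatio = dKO$excessRatio,
    koTemplateAboveBackground = dKO$pValue < 0.01 && dKO$excessRatio > 1,
    comparison = lapply(seq_len(nrow(comparison)), function(i)
      as.list(comparison[i, ])))
  yaml::write_yaml(summary, emit("summary.yaml"))

  manifest <- data.frame(
    file = basename(files),
    sha256 = unname(vapply(files, function(f)
      digest::digest(file = f, algo = "sha256"), character(1))))
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, summary = summary, files = files))
}
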