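#' Simulate a toy F1-hybrid genome with DSB hotspots
#'
#' Builds a diploid genome model (chromosome sizes, a grid of SNPs
#' distinguishing the B6 and CAST haplotypes, an X non-PAR region) and a set
#' of non-overlapping DSB hotspots with heats, B6 DSB fractions, PRDM9-class
#' labels and orientations. SNPs are placed on a regular grid (spacing
#' `snpSpacing`, phase `snpSpacing %/% 2`), so a chromosome of length L
#' carries exactly `floor(L / snpSpacing)` SNPs. Hotspot centers are
#' rejection-sampled to keep at least `minSeparation` bp apart.
#'
#' The B6 DSB fraction of each autosomal hotspot is drawn from a three-class
#' mixture (symmetric, asymmetric towards B6, asymmetric towards CAST) so
#' that all symmetry classes are represented; X non-PAR hotspots have no
#' homolog, are forced to `fTrue = 1` (the single X in males is maternal,
#' i.e. B6) and flagged `onXNonPar`.
#'
#' @param nChroms number of autosomes (named chr1..chrN).
#' @param chromLen autosome length (bp); chrX, when present, has the same
#'   length and is entirely non-PAR in this toy model.
#' @param snpSpacing SNP grid spacing (bp).
#' @param nHotspots total number of hotspots.
#' @param heatDist list; `shape` of the gamma heat distribution (mean 1).
#' @param fDist list with mixture probabilities `pSymmetric`, `pAsymB6`,
#'   `pAsymCast` and class values `fSymmetric`, `fAsymB6`, `fAsymCast`.
#' @param xFraction share of hotspots placed on the X non-PAR (0 disables
#'   the X chromosome entirely).
#' @param hotspotHalfWidth half-width of the hotspot interval around the
#'   center (bp).
#' @param minSeparation minimal center-to-center distance (bp).
#' @param seed RNG seed; the output is deterministic given it.
#' @return `list(genome = GenomeModel, hotspots = GRanges)`.
#' @examples
#' gs <- simulateGenome(nChroms = 1, chromLen = 1e6, nHotspots = 10, seed = 1)
#' gs$genome
#' @export
simulateGenome <- function(nChroms = 2, chromLen = 2e6, snpSpacing = 200,
    nHotspots = 100, heatDist = list(shape = 2),
    fDist = list(pSymmetric = 0.6, pAsymB6 = 0.2, pAsymCast = 0.2,
                 fSymmetric = 0.5, fAsymB6 = 0.97, fAsymCast = 0.03),
    xFraction = 0.1, hotspotHalfWidth = 1000, minSeparation = 10000,
    seed = 1) {
  stopifnot(snpSpacing > 0, nChroms >= 1, chromLen > 2 * hotspotHalfWidth)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    chroms <- sprintf("chr%d", seq_len(nChroms))
    sizes <- structure(rep(chromLen, nChroms), names = chroms)
    hasX <- xFraction > 0
    if (hasX) sizes <- c(sizes, chrX = chromLen)
    xNonPar <- if (hasX)
      GenomicRanges::GRanges("chrX", IRanges::IRanges(1, chromLen))
    else GenomicRanges::GRanges()

    # SNP grid per chromosome with random distinct allele pairs
    snpList <- lapply(names(sizes), function(ch) {
      k <- sizes[[ch]] %/% snpSpacing
      pos0 <- snpSpacing * (seq_len(k) - 1L) + snpSpacing %/% 2L
      b6 <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      shift <- sample(1:3, k, replace = TRUE)
      cast <- c("A", "C", "G", "T")[(match(b6, c("A", "C", "G", "T")) - 1L +
                                     shift) %% 4L + 1L]
      GenomicRanges::GRanges(ch, IRanges::IRanges(start = pos0 + 1, width = 1L),
                             b6 = b6, cast = cast)
    })
    snpsGr <- suppressWarnings(do.call(c, snpList))
    genome <- new("GenomeModel", chromSizes = sizes, snps = snpsGr,
                  xNonPar = xNonPar)

    # hotspot placement with minimal separation (rejection sampling)
    nX <- if (hasX) round(xFraction * nHotspots) else 0L
    nAuto <- nHotspots - nX
    placeOn <- c(sample(chroms, nAuto, replace = TRUE),
                 rep("chrX", nX))
    centers <- numeric(nHotspots)
    placedByChrom <- split(seq_len(nHotspots), placeOn)
    lo <- hotspotHalfWidth + 1
    hi <- chromLen - hotspotHalfWidth
    for (ch in names(placedByChrom)) {
      idx <- placedByChrom[[ch]]
      kept <- numeric(0)
      tries <- 0L
      maxTries <- 200L * length(idx)
      while (length(kept) < length(idx)) {
        tries <- tries + 1L
        if (tries > maxTries)
          stop(sprintf(
            "cannot place %d hotspots on %s with %d bp separation",
            length(idx), ch, minSeparation), call. = FALSE)
        cand <- round(runif(1, lo, hi))
        if (all(abs(cand - kept) >= minSeparation))
          kept <- c(kept, cand)
      }
      centers[idx] <- kept
    }

    onX <- placeOn == "chrX"
    cls <- sample(c("symmetric", "asymB6", "asymCast"), nHotspots,
                  replace = TRUE,
                  prob = c(fDist$pSymmetric, fDist$pAsymB6, fDist$pAsymCast))
    fTrue <- c(symmetric = fDist$fSymmetric, asymB6 = fDist$fAsymB6,
               asymCast = fDist$fAsymCast)[cls]
    fTrue[onX] <- 1
    heat <- rgamma(nHotspots, shape = heatDist$shape,
                   rate = heatDist$shape)
    prdm9 <- sample(c("CAST", "HUM", "independent"), nHotspots,
                    replace = TRUE, prob = c(0.65, 0.29, 0.06))
    orientation <- sample(c("+", "-"), nHotspots, replace = TRUE)
    hs <- makeHotspots(chrom = placeOn,
                       start = centers - hotspotHalfWidth,
                       end = centers + hotspotHalfWidth,
                       center = centers, heat = heat, fTrue = unname(fTrue),
                       orientation = orientation, prdm9Class = prdm9,
                       onXNonPar = onX)
    hs <- BiocGenerics::sort(hs, ignore.strand = TRUE)
    S4Vectors::mcols(hs)$hotspotId <- sprintf("hs%05d", seq_along(hs))
    list(genome = genome, hotspots = hs)
  })
}
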