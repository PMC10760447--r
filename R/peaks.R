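#' Strand-resolved binned fragment coverage
#'
#' Counts fragments per fixed-width bin, per chromosome and strand; a
#' fragment increments every bin it overlaps (so the bin total is at least
#' the fragment count). The last partial bin is included.
#'
#' @param fragments fragments `GRanges`.
#' @param binsize bin width in bp (>= 1).
#' @param genome a [GenomeModel-class] (or named vector of chromosome
#'   sizes).
#' @return named list per chromosome of matrices (bins x strands `F`,`R`).
#' @export
computeCoverage <- function(fragments, binsize, genome) {
  stopifnot(binsize >= 1)
  sizes <- if (is(genome, "GenomeModel")) chromSizes(genome) else genome
  frChrom <- as.character(GenomeInfoDb::seqnames(fragments))
  if (!all(frChrom %in% names(sizes)))
    stop("fragment on unknown chromosome: ",
         setdiff(frChrom, names(sizes))[1], call. = FALSE)
  lapply(structure(names(sizes), names = names(sizes)), function(ch) {
    nb <- as.integer(ceiling(sizes[[ch]] / binsize))
    bins <- GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = (seq_len(nb) - 1L) * binsize + 1L,
      end = pmin(seq_len(nb) * binsize, sizes[[ch]])))
    sel <- fragments[frChrom == ch]
    fw <- GenomicRanges::countOverlaps(bins,
      sel[BiocGenerics::strand(sel) == "+"], ignore.strand = TRUE)
    rv <- GenomicRanges::countOverlaps(bins,
      sel[BiocGenerics::strand(sel) == "-"], ignore.strand = TRUE)
    cbind(F = fw, R = rv)
  })
}

#' Estimate the genome-wide background fragment rate
#'
#' The background rate rho (fragments per bp) is the number of fragments
#' lying entirely outside the hotspot mask divided by the unmasked genome
#' length. This is the "background read frequency" used to correct per-peak
#' intensities.
#'
#' @param fragments fragments `GRanges`.
#' @param mask `GRanges` of regions to exclude (e.g. hotspots, called
#'   peaks); may be empty.
#' @param genome a [GenomeModel-class].
#' @return rho, fragments per bp.
#' @export
estimateBackground <- function(fragments, mask, genome) {
  stopifnot(is(genome, "GenomeModel"))
  sizes <- chromSizes(genome)
  total <- sum(sizes)
  maskBp <- if (length(mask) == 0) 0 else {
    red <- GenomicRanges::reduce(mask, ignore.strand = TRUE)
    keep <- as.character(GenomeInfoDb::seqnames(red)) %in% names(sizes)
    red <- red[keep]
    sum(pmin(BiocGenerics::end(red),
             sizes[as.character(GenomeInfoDb::seqnames(red))]) -
        pmax(BiocGenerics::start(red), 1) + 1)
  }
  unmasked <- total - maskBp
  if (unmasked <= 0) stop("no unmasked genome left", call. = FALSE)
  if (maskBp > 0.5 * total)
    warning("hotspot mask covers more than half the genome", call. = FALSE)
  outside <- if (length(mask) == 0) length(fragments) else
    sum(GenomicRanges::countOverlaps(fragments, mask,
                                     ignore.strand = TRUE) == 0)
  outside / unmasked
}

#' Call enriched peaks by a sliding-window Poisson test
#'
#' Slides windows of width `window` (step `step`) across each chromosome,
#' pools both strands (breaks produce signal on both flanks), counts
#' fragment midpoints per window, and tests each count against
#' Poisson(rho * window) with Benjamini-Hochberg correction over all tested
#' windows. Significant windows (`q <= qMax` and count >= `minCount`) are
#' merged when separated by at most `mergeGap` bp and the merged intervals
#' are re-scored (count, background expectation mu, corrected intensity
#' n - mu, Poisson p, BH q over the merged set).
#'
#' @param fragments fragments `GRanges`.
#' @param genome a [GenomeModel-class].
#' @param rho background rate, fragments per bp (> 0); see
#'   [estimateBackground()].
#' @param window window width in bp.
#' @param step window step in bp (default `window / 2`).
#' @param mergeGap maximal gap between significant windows to merge (bp).
#' @param qMax BH FDR threshold.
#' @param minCount minimal fragment count per window.
#' @return `GRanges` of non-overlapping peaks, sorted, with metadata
#'   columns `n`, `mu`, `correctedIntensity`, `p`, `q`.
#' @export
callPeaks <- function(fragments, genome, rho, window = 1000,
                      step = max(1, window %/% 2), mergeGap = 500,
                      qMax = 0.01, minCount = 5) {
  stopifnot(is(genome, "GenomeModel"), rho > 0, window >= 1, step >= 1)
  sizes <- chromSizes(genome)
  mids <- .midGRanges(fragments)
  winList <- lapply(names(sizes), function(ch) {
    starts <- seq(1, max(1, sizes[[ch]] - window + 1), by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window - 1, sizes[[ch]]))
  })
  wd <- do.call(rbind, winList)
  wins <- GenomicRanges::GRanges(wd$chrom,
                                 IRanges::IRanges(wd$start, wd$end))
  cnt <- GenomicRanges::countOverlaps(wins, mids, ignore.strand = TRUE)
  mu <- rho * BiocGenerics::width(wins)
  p <- ppois(cnt - 1, mu, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- wins[q <= qMax & cnt >= minCount]
  if (length(sig) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::metadata(out) <- list(nWindows = length(wins))
    return(out)
  }
  peaks <- GenomicRanges::reduce(sig, min.gapwidth = mergeGap + 1L,
                                 ignore.strand = TRUE)
  n2 <- GenomicRanges::countOverlaps(peaks, mids, ignore.strand = TRUE)
  mu2 <- rho * BiocGenerics::width(peaks)
  p2 <- ppois(n2 - 1, mu2, lower.tail = FALSE)
  S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(
    n = n2, mu = mu2, correctedIntensity = n2 - mu2, p = p2,
    q = p.adjust(p2, method = "BH"))
  peaks <- BiocGenerics::sort(peaks, ignore.strand = TRUE)
  S4Vectors::metadata(peaks) <- list(nWindows = length(wins))
  peaks
}

#' Background-corrected peak intensity
#'
#' Counts the fragments whose midpoint lies inside each peak (a fragment is
#' thereby counted in at most one peak) and subtracts the background
#' expectation `rho * width`. Negative values are retained: clamping would
#' bias downstream class comparisons.
#'
#' @param peaks peak `GRanges` (e.g. hotspot intervals or [callPeaks()]
#'   output).
#' @param fragments fragments `GRanges`.
#' @param rho background rate, fragments per bp (>= 0).
#' @return numeric vector of corrected intensities, one per peak.
#' @examples
#' pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rep(900, 100),
#'                                                       width = 150),
#'                              strand = "+")
#' correctedIntensity(pk, fr, 0.01)  # 100 - 0.01*2000 = 80
#' @export
correctedIntensity <- function(peaks, fragments, rho) {
  stopifnot(rho >= 0)
  mids <- .midGRanges(fragments)
  n <- GenomicRanges::countOverlaps(peaks, mids, ignore.strand = TRUE)
  n - rho * BiocGenerics::width(peaks)
}
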