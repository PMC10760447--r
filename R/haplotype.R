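#' Assign fragments to parental haplotypes via SNP alleles
#'
#' Tallies the alleles a fragment carries at the SNPs it overlaps and calls
#' the fragment `B6` or `CAST` only when every observed allele agrees
#' (strict rule: any minority allele makes the call `conflicting`); a
#' fragment overlapping no SNP is `unassigned`. In simulation mode no
#' sequence exists, so alleles are looked up from the truth haplotype,
#' emulating a perfect genotyper with an optional per-SNP miscall rate
#' `epsilon`; background fragments derive from one (unknown) homolog, which
#' is drawn fairly per fragment.
#'
#' @param fragments fragments `GRanges` (with `truthHaplotype` metadata).
#' @param genome a [GenomeModel-class] providing the SNP table.
#' @param epsilon per-SNP allele miscall rate (default 0).
#' @param seed RNG seed for background-haplotype draws and miscalls.
#' @return [S4Vectors::DataFrame] aligned with `fragments`: `fragmentId`,
#'   `call` (`B6`/`CAST`/`unassigned`/`conflicting`), `nB6`, `nCast`.
#' @examples
#' gm <- GenomeModel(c(chr1 = 1000),
#'                   data.frame(chrom = "chr1", pos = 500, b6 = "A",
#'                              cast = "G"))
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(450, 550),
#'                              strand = "+", fragmentId = "f1",
#'                              truthHaplotype = "B6")
#' assignHaplotype(fr, gm)$call
#' @export
assignHaplotype <- function(fragments, genome, epsilon = 0, seed = 1) {
  stopifnot(is(genome, "GenomeModel"), epsilon >= 0, epsilon <= 1)
  sn <- snps(genome)
  n <- length(fragments)
  mc <- S4Vectors::mcols(fragments)
  truth <- if (!is.null(mc$truthHaplotype)) mc$truthHaplotype
           else rep("background", n)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    latentB6 <- truth == "B6"
    unknown <- !truth %in% c("B6", "CAST")
    latentB6[unknown] <- runif(sum(unknown)) < 0.5
    ov <- GenomicRanges::findOverlaps(fragments, sn, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    obsB6 <- latentB6[qh]
    if (epsilon > 0) {
      flip <- runif(length(qh)) < epsilon
      obsB6 <- xor(obsB6, flip)
    }
    nB6 <- tabulate(qh[obsB6], nbins = n)
    nCast <- tabulate(qh[!obsB6], nbins = n)
    call <- ifelse(nB6 > 0 & nCast == 0, "B6",
            ifelse(nCast > 0 & nB6 == 0, "CAST",
            ifelse(nB6 > 0 & nCast > 0, "conflicting", "unassigned")))
    S4Vectors::DataFrame(fragmentId = if (!is.null(mc$fragmentId))
                           mc$fragmentId else sprintf("frag%07d", seq_len(n)),
                         call = call, nB6 = nB6, nCast = nCast)
  })
}

# Clopper-Pearson exact binomial 95% CI via the beta quantile identity
.clopperPearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Estimate the per-hotspot B6 fraction f and classify symmetry
#'
#' For each hotspot, counts informative fragments (haplotype call B6 or
#' CAST, fragment midpoint inside the hotspot interval), estimates
#' `fHat = nB6 / (nB6 + nCast)` with an exact (Clopper-Pearson) 95%
#' confidence interval, and labels the hotspot by the inclusive threshold
#' rule: `fHat >= 0.9` is `asymmetric_B6`, `fHat <= 0.1` is
#' `asymmetric_CAST`, anything between is `symmetric`; hotspots with fewer
#' than `nMin` informative fragments are `undetermined`.
#'
#' @param hotspots hotspot `GRanges`.
#' @param calls haplotype calls from [assignHaplotype()], aligned with
#'   `fragments`.
#' @param fragments the fragments the calls refer to.
#' @param nMin minimal informative count for a defined label (default 10).
#' @return [S4Vectors::DataFrame]: `hotspotId`, `nInformative`, `nB6`,
#'   `nCast`, `fHat`, `ciLow`, `ciHigh`, `label`.
#' @export
estimateF <- function(hotspots, calls, fragments, nMin = 10) {
  .checkHotspots(hotspots)
  stopifnot(length(fragments) == nrow(calls))
  mids <- .midGRanges(fragments)
  ov <- GenomicRanges::findOverlaps(mids, hotspots, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  isB6 <- calls$call[qh] == "B6"
  isCast <- calls$call[qh] == "CAST"
  nH <- length(hotspots)
  nB6 <- tabulate(sh[isB6], nbins = nH)
  nCast <- tabulate(sh[isCast], nbins = nH)
  nInf <- nB6 + nCast
  fHat <- ifelse(nInf > 0, nB6 / nInf, NA_real_)
  ci <- t(vapply(seq_len(nH), function(i) {
    if (nInf[i] == 0) c(NA_real_, NA_real_)
    else .clopperPearson(nB6[i], nInf[i])
  }, numeric(2)))
  label <- vapply(seq_len(nH), function(i)
    classifySymmetry(fHat[i], nInf[i], nMin), character(1))
  S4Vectors::DataFrame(hotspotId = S4Vectors::mcols(hotspots)$hotspotId,
                       nInformative = nInf, nB6 = nB6, nCast = nCast,
                       fHat = fHat, ciLow = ci[, 1], ciHigh = ci[, 2],
                       label = label)
}

#' @rdname estimateF
#' @param fHat estimated B6 fraction (or `NA`).
#' @param nInformative number of informative fragments behind `fHat`.
#' @return `classifySymmetry`: one of `"symmetric"`, `"asymmetric_B6"`,
#'   `"asymmetric_CAST"`, `"undetermined"`.
#' @examples
#' classifySymmetry(0.9, 50)   # boundary inclusive -> asymmetric_B6
#' classifySymmetry(0.5, 50)   # symmetric
#' @export
classifySymmetry <- function(fHat, nInformative, nMin = 10) {
  stopifnot(nMin >= 1)
  if (is.na(fHat) || nInformative < nMin) return("undetermined")
  if (fHat >= 0.9) return("asymmetric_B6")
  if (fHat <= 0.1) return("asymmetric_CAST")
  "symmetric"
}
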