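suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# genome with SNPs on a regular grid (B6 allele A, CAST allele G throughout)
gridGenome <- function(len = 1e5, spacing = 200, chrom = "chr1",
                       xNonPar = NULL) {
  k <- len %/% spacing
  pos0 <- spacing * (seq_len(k) - 1L) + spacing %/% 2L
  GenomeModel(structure(len, names = chrom),
              data.frame(chrom = chrom, pos = pos0, b6 = "A", cast = "G"),
              xNonPar = xNonPar)
}

# evenly spaced hotspots with given f values, all oriented "+"
gridHotspots <- function(chrom = "chr1", n = 10, spacing = 20000,
                         first = 20000, fTrue = 0.5, heat = 1,
                         halfWidth = 1000, onXNonPar = FALSE,
                         orientation = "+") {
  centers <- first + spacing * (seq_len(n) - 1L)
  makeHotspots(chrom = rep(chrom, n), start = centers - halfWidth,
               end = centers + halfWidth, center = centers,
               heat = rep(heat, length.out = n),
               fTrue = rep(fTrue, length.out = n),
               orientation = orientation, onXNonPar = onXNonPar)
}

# symmetry table fabricated from truth f (bypasses the estimation path when
# a test only needs labels)
truthSymmetry <- function(hotspots) {
  mc <- S4Vectors::mcols(hotspots)
  S4Vectors::DataFrame(
    hotspotId = mc$hotspotId,
    nInformative = 1000L,
    fHat = mc$fTrue,
    label = vapply(mc$fTrue, classifySymmetry, character(1),
                   nInformative = 1000L))
}

# calls table fabricated from simulation truth (perfect genotyper shortcut)
truthCalls <- function(fragments) {
  mc <- S4Vectors::mcols(fragments)
  call <- ifelse(mc$truthHaplotype %in% c("B6", "CAST"), mc$truthHaplotype,
                 "unassigned")
  S4Vectors::DataFrame(fragmentId = mc$fragmentId, call = call,
                       nB6 = as.integer(call == "B6"),
                       nCast = as.integer(call == "CAST"))
}
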