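#' Simulate strand-specific ssDNA fragments from meiotic DSB processing
#'
#' Forward generator of SSDS fragments in an F1 hybrid. For each signal
#' fragment: a hotspot is chosen proportionally to its (effective) heat; the
#' broken homolog is B6 with probability `fTrue` (forced on the X non-PAR,
#' where no homolog exists); the true break position is drawn around the
#' hotspot center (normal, SD `dsbSd` -- the DSB-location kernel inverted
#' later by deconvolution); a binding-geometry component is drawn from the
#' preset mixture; a resection length L ~ gamma and a fragment length are
#' drawn; and the fragment is laid down with SSDS strand polarity: ssDNA
#' recovered from the left break end maps to the forward strand, ending at
#' `break - d`, and from the right end to the reverse strand, starting at
#' `break + d`, where `d` is the component's anchor distance (both ends are
#' recovered with equal probability). Repair-template (D-loop) fragments go
#' on the other homolog with opposite-role polarity; wrong-polarity
#' fragments stay on the broken homolog with reversed strand. Uniform
#' background fragments (Poisson, `backgroundRate` per bp) are appended with
#' random strand.
#'
#' Strand-exchange-defective genotypes (`DMC1KO`) produce no
#' repair-template, return-binding or wrong-polarity fragments at all; X
#' non-PAR hotspots never produce repair-template fragments in any genotype
#' (sister-chromatid repair). Fragments running past a chromosome end are
#' truncated, never silently dropped; counts are reported in
#' `metadata()` of the result.
#'
#' @param genome a [GenomeModel-class].
#' @param hotspots hotspot `GRanges` (see [makeHotspots()]).
#' @param config a [SimulationConfig-class], typically from
#'   [presetConfig()].
#' @return `GRanges` of fragments with strand and truth metadata columns
#'   `fragmentId`, `truthHaplotype` (B6/CAST/background), `truthRole`
#'   (dsb_initiating/repair_template/background), `truthHotspot`,
#'   `truthBreak` (1-based break coordinate, NA for background);
#'   `S4Vectors::metadata()` carries `nTruncated`, `nDropped`,
#'   `nSignal`, `nBackground`.
#' @examples
#' gs <- simulateGenome(nChroms = 1, chromLen = 5e5, nHotspots = 5,
#'                      xFraction = 0, seed = 1)
#' fr <- simulateFragments(gs$genome, gs$hotspots,
#'                         presetConfig("DMC1KO", "RPA",
#'                                      nSignalFragments = 1000, seed = 2))
#' table(S4Vectors::mcols(fr)$truthRole)
#' @export
simulateFragments <- function(genome, hotspots, config) {
  stopifnot(is(genome, "GenomeModel"), is(config, "SimulationConfig"))
  methods::validObject(config)
  .checkHotspots(hotspots)
  sizes <- chromSizes(genome)
  hsChrom <- as.character(GenomeInfoDb::seqnames(hotspots))
  if (!all(hsChrom %in% names(sizes)))
    stop("hotspot on chromosome absent from the genome model", call. = FALSE)
  mc <- S4Vectors::mcols(hotspots)

  withr::with_seed(config@seed %% .Machine$integer.max, {
    n <- config@nSignalFragments
    w <- config@weights

    # effective heat: symmetric autosomal hotspots in WT carry the
    # inter-homolog intermediate lifespan multiplier
    heatEff <- mc$heat
    if (config@genotype == "WT" &&
        config@interHomologLifespanMultiplier != 1) {
      sym <- !mc$onXNonPar & mc$fTrue > 0.1 & mc$fTrue < 0.9
      heatEff[sym] <- heatEff[sym] * config@interHomologLifespanMultiplier
    }
    if (n > 0 && sum(heatEff) <= 0)
      stop("all hotspot heats are zero", call. = FALSE)

    if (n > 0) {
      idx <- sample.int(length(hotspots), n, replace = TRUE, prob = heatEff)
      isX <- mc$onXNonPar[idx]
      hapB6 <- runif(n) < mc$fTrue[idx]
      hapB6[isX] <- TRUE
      center0 <- mc$center[idx] - 1
      break0 <- center0 + round(rnorm(n, 0, config@dsbSd))

      compLevels <- names(w)[w > 0]
      comp <- if (length(compLevels) == 1L) rep(compLevels, n)
              else sample(names(w), n, replace = TRUE, prob = w)
      # X non-PAR: no homolog, so no D-loop with it; redraw those events
      redo <- isX & comp == "repair_template"
      if (any(redo)) {
        w2 <- w
        w2["repair_template"] <- 0
        if (sum(w2) <= 0)
          stop("X non-PAR hotspots require a non-template component",
               call. = FALSE)
        comp[redo] <- sample(names(w2), sum(redo), replace = TRUE, prob = w2)
      }

      L <- rgamma(n, shape = config@resectionShape,
                  scale = config@resectionMean / config@resectionShape)
      len <- pmax(config@fragLenMin, round(rnorm(n, config@fragLenMean,
                                                 config@fragLenSd)))
      side <- sample(c(-1, 1), n, replace = TRUE)

      u <- runif(n)
      cF <- config@distalFraction
      d <- numeric(n)
      d[comp == "filament_full"] <- (u * L)[comp == "filament_full"]
      d[comp == "filament_proximal"] <- (u * cF * L)[comp == "filament_proximal"]
      d[comp == "filament_distal"] <-
        ((cF + u * (1 - cF)) * L)[comp == "filament_distal"]
      zRet <- rnorm(n, config@returnBindingOffset, config@returnBindingWidth)
      d[comp == "return_binding"] <-
        pmax(0, zRet - len / 2)[comp == "return_binding"]
      d[comp == "wrong_polarity"] <-
        (u * config@wrongPolarityMax)[comp == "wrong_polarity"]
      d <- round(d)
      mTpl <- side * round(rnorm(n, config@dloopOffsetMean,
                                 config@dloopOffsetSd))

      isTpl <- comp == "repair_template"
      isWrong <- comp == "wrong_polarity"
      role <- ifelse(isTpl, "repair_template", "dsb_initiating")
      hap <- ifelse(xor(hapB6, isTpl), "B6", "CAST")

      start0 <- ifelse(side < 0, break0 - d - len, break0 + d)
      # template fragments are midpoint-anchored around break + offset
      start0[isTpl] <- round(break0[isTpl] + mTpl[isTpl] - len[isTpl] / 2)
      end0 <- start0 + len
      # strand polarity: correct components F-left/R-right; wrong polarity
      # reversed; template carries opposite-role polarity (F on the right)
      strandSig <- ifelse(side < 0, "+", "-")
      strandSig[isWrong] <- ifelse(side[isWrong] < 0, "-", "+")
      strandSig[isTpl] <- ifelse(side[isTpl] < 0, "-", "+")

      chromSig <- hsChrom[idx]
      sigDf <- data.frame(chrom = chromSig, start0 = start0, end0 = end0,
                          strand = strandSig, hap = hap, role = role,
                          hs = mc$hotspotId[idx], brk1 = break0 + 1)
    } else {
      sigDf <- NULL
    }

    nBg <- rpois(1, config@backgroundRate * sum(sizes))
    if (nBg > 0) {
      chB <- sample(names(sizes), nBg, replace = TRUE,
                    prob = sizes / sum(sizes))
      lenB <- pmax(config@fragLenMin, round(rnorm(nBg, config@fragLenMean,
                                                  config@fragLenSd)))
      startB <- floor(runif(nBg) * (sizes[chB] - 1))
      bgDf <- data.frame(chrom = chB, start0 = startB, end0 = startB + lenB,
                         strand = sample(c("+", "-"), nBg, replace = TRUE),
                         hap = "background", role = "background",
                         hs = NA_character_, brk1 = NA_real_)
    } else {
      bgDf <- NULL
    }

    d <- rbind(sigDf, bgDf)
    if (is.null(d) || nrow(d) == 0) {
      out <- GenomicRanges::GRanges()
      S4Vectors::metadata(out) <- list(nTruncated = 0L, nDropped = 0L,
                                       nSignal = 0L, nBackground = 0L)
      return(out)
    }
    lim <- sizes[d$chrom]
    s0 <- pmax(0, d$start0)
    e0 <- pmin(lim, d$end0)
    truncated <- (s0 != d$start0) | (e0 != d$end0)
    keep <- s0 < e0
    nDropped <- sum(!keep)
    nTruncated <- sum(truncated & keep)
    d <- d[keep, , drop = FALSE]
    out <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(start = s0[keep] + 1, end = e0[keep]),
      strand = d$strand,
      fragmentId = sprintf("frag%07d", seq_len(nrow(d))),
      truthHaplotype = d$hap, truthRole = d$role, truthHotspot = d$hs,
      truthBreak = d$brk1)
    S4Vectors::metadata(out) <- list(
      nTruncated = as.integer(nTruncated), nDropped = as.integer(nDropped),
      nSignal = sum(d$role != "background"),
      nBackground = sum(d$role == "background"))
    out
  })
}

#' Simulate an H3K4me3-like fragment set for estimating f
#'
#' PRDM9-dependent H3K4me3 marks both homologs in proportion to PRDM9
#' binding; the per-hotspot B6 read fraction of this assay defines the
#' symmetry statistic f. This generator is protein-agnostic: fragment
#' midpoints are normally spread about hotspot centers, the haplotype is B6
#' with probability `fTrue`, and there is no resection geometry or role
#' structure.
#'
#' @param genome a [GenomeModel-class].
#' @param hotspots hotspot `GRanges`.
#' @param n number of signal fragments.
#' @param seed RNG seed.
#' @param spreadSd SD (bp) of midpoints about the center.
#' @param fragLenMean,fragLenSd,fragLenMin fragment length model.
#' @param backgroundRate uniform background rate (fragments per bp).
#' @return fragments `GRanges` with truth metadata (`truthRole` is
#'   `"h3k4me3"` for signal).
#' @export
simulateH3k4me3 <- function(genome, hotspots, n = 1e5, seed = 1,
                            spreadSd = 300, fragLenMean = 150,
                            fragLenSd = 30, fragLenMin = 50,
                            backgroundRate = 0) {
  stopifnot(is(genome, "GenomeModel"))
  .checkHotspots(hotspots)
  sizes <- chromSizes(genome)
  mc <- S4Vectors::mcols(hotspots)
  hsChrom <- as.character(GenomeInfoDb::seqnames(hotspots))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    idx <- sample.int(length(hotspots), n, replace = TRUE, prob = mc$heat)
    hapB6 <- runif(n) < mc$fTrue[idx]
    mid0 <- (mc$center[idx] - 1) + round(rnorm(n, 0, spreadSd))
    len <- pmax(fragLenMin, round(rnorm(n, fragLenMean, fragLenSd)))
    start0 <- round(mid0 - len / 2)
    d <- data.frame(chrom = hsChrom[idx], start0 = start0,
                    end0 = start0 + len,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    hap = ifelse(hapB6, "B6", "CAST"), role = "h3k4me3",
                    hs = mc$hotspotId[idx], brk1 = NA_real_)
    nBg <- if (backgroundRate > 0) rpois(1, backgroundRate * sum(sizes)) else 0
    if (nBg > 0) {
      chB <- sample(names(sizes), nBg, replace = TRUE,
                    prob = sizes / sum(sizes))
      lenB <- pmax(fragLenMin, round(rnorm(nBg, fragLenMean, fragLenSd)))
      startB <- floor(runif(nBg) * (sizes[chB] - 1))
      d <- rbind(d, data.frame(chrom = chB, start0 = startB,
                               end0 = startB + lenB,
                               strand = sample(c("+", "-"), nBg,
                                               replace = TRUE),
                               hap = "background", role = "background",
                               hs = NA_character_, brk1 = NA_real_))
    }
    lim <- sizes[d$chrom]
    s0 <- pmax(0, d$start0)
    e0 <- pmin(lim, d$end0)
    keep <- s0 < e0
    d <- d[keep, , drop = FALSE]
    out <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(start = s0[keep] + 1, end = e0[keep]),
      strand = d$strand,
      fragmentId = sprintf("h3k%07d", seq_len(nrow(d))),
      truthHaplotype = d$hap, truthRole = d$role, truthHotspot = d$hs,
      truthBreak = d$brk1)
    S4Vectors::metadata(out) <- list(nSignal = sum(d$role == "h3k4me3"),
                                     nBackground = sum(d$role == "background"))
    out
  })
}
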