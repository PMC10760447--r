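#' Aggregate strand- and homolog-role-resolved profile around hotspot centers
#'
#' Builds the break-centred metaprofile underlying homolog-resolved SSDS
#' plots. Only asymmetric hotspots (label `asymmetric_B6` or
#' `asymmetric_CAST`) are used, because only there does the haplotype of a
#' fragment identify its repair role: at an `asymmetric_B6` hotspot
#' B6-called fragments report binding on the DSB-initiating chromosome and
#' CAST-called fragments on the repair template (mirrored at
#' `asymmetric_CAST`); unassigned and conflicting fragments are dropped.
#' Each fragment contributes one count at its midpoint's signed distance
#' from the hotspot center, binned on a grid of `binsize` bp covering
#' `[-W, W)`. For orientation `-` hotspots the distance sign is mirrored
#' and the strand label swapped, so the strand-polarity law (forward-strand
#' ssDNA left of the break) reads identically in the oriented frame. Counts
#' are divided by the number of asymmetric hotspots, giving fragments per
#' hotspot per bin.
#'
#' @param fragments fragments `GRanges`.
#' @param calls haplotype calls from [assignHaplotype()], aligned with
#'   `fragments`.
#' @param hotspots hotspot `GRanges`.
#' @param symmetry symmetry table from [estimateF()] (per hotspot, same
#'   order).
#' X non-PAR hotspots are excluded even when their f is extreme: without a
#' homolog there is no repair-template role to resolve.
#'
#' @param binsize bin width in bp.
#' @param halfWidth half window width W in bp (multiple of `binsize`).
#' @return a [StrandProfile-class].
#' @export
aggregateProfile <- function(fragments, calls, hotspots, symmetry,
                             binsize = 40, halfWidth = 2400) {
  .checkHotspots(hotspots)
  stopifnot(length(fragments) == nrow(calls),
            length(hotspots) == nrow(symmetry),
            halfWidth %% binsize == 0)
  asym <- symmetry$label %in% c("asymmetric_B6", "asymmetric_CAST") &
    !S4Vectors::mcols(hotspots)$onXNonPar
  if (!any(asym))
    stop("no asymmetric hotspots with a defined label", call. = FALSE)
  hs <- hotspots[asym]
  lab <- symmetry$label[asym]
  centers <- S4Vectors::mcols(hs)$center
  orient <- as.character(BiocGenerics::strand(hs))

  informative <- calls$call %in% c("B6", "CAST")
  fr <- fragments[informative]
  frCall <- calls$call[informative]

  winGr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(hs),
    IRanges::IRanges(start = pmax(1, centers - halfWidth),
                     end = centers + halfWidth))
  mids <- .midGRanges(fr)
  ov <- GenomicRanges::findOverlaps(mids, winGr, ignore.strand = TRUE,
                                    select = "first")
  hit <- !is.na(ov)
  fIdx <- which(hit)
  hIdx <- ov[hit]

  dist <- .mid1(fr)[fIdx] - centers[hIdx]
  strandF <- as.character(BiocGenerics::strand(fr))[fIdx] == "+"
  flip <- orient[hIdx] == "-"
  dist[flip] <- -dist[flip]
  strandF[flip] <- !strandF[flip]

  # role by haplotype relative to the asymmetric direction
  b6Called <- frCall[fIdx] == "B6"
  dsbRole <- ifelse(lab[hIdx] == "asymmetric_B6", b6Called, !b6Called)

  inWin <- dist >= -halfWidth & dist < halfWidth
  dist <- dist[inWin]
  strandF <- strandF[inWin]
  dsbRole <- dsbRole[inWin]

  nb <- 2L * halfWidth %/% binsize
  binIdx <- (dist + halfWidth) %/% binsize + 1L
  panel <- 1L + (!strandF) + 2L * (!dsbRole)  # F.dsb, R.dsb, F.tpl, R.tpl
  counts <- matrix(0, nb, 4L, dimnames = list(NULL, .panelNames))
  tab <- table(factor(binIdx, levels = seq_len(nb)),
               factor(panel, levels = 1:4))
  counts[] <- as.numeric(tab)
  new("StrandProfile", binsize = as.integer(binsize),
      halfWidth = as.integer(halfWidth),
      values = counts / length(hs), nHotspots = length(hs),
      nFragments = length(dist))
}

#' Probability that a fragment overlaps at least one grid SNP
#'
#' For SNPs on a regular grid of spacing `s` and a fragment of length `L`
#' at uniform phase, the coverage probability is `min(L/s, 1)`; this
#' integrates that quantity over the truncated-normal fragment length
#' model. Used to convert a background fragment rate into an expected
#' informative-fragment rate.
#'
#' @param fragLenMean,fragLenSd,fragLenMin fragment length model (bp).
#' @param snpSpacing SNP grid spacing (bp).
#' @return probability in [0, 1].
#' @export
informativeProbability <- function(fragLenMean = 150, fragLenSd = 30,
                                   fragLenMin = 50, snpSpacing = 200) {
  f <- function(x) {
    len <- pmax(x, fragLenMin)
    pmin(len / snpSpacing, 1) * dnorm(x, fragLenMean, fragLenSd)
  }
  integrate(f, -Inf, Inf)$value
}

#' Poisson test of repair-template profile mass against uniform background
#'
#' Under the no-strand-exchange null, the repair-template panels of an
#' aggregate profile contain only uniform background: informative
#' background fragments fall into a template panel at rate
#' `rho / 2 * binsize * pInformative / 2` per hotspot per bin (half the
#' fragments per strand, half of the informative ones called on the
#' template-side homolog). This compares the total observed template-panel
#' count to that expectation with an exact two-sided Poisson test.
#'
#' @param profile a [StrandProfile-class].
#' @param rho background fragment rate (fragments per bp, both strands).
#' @param pInformative probability a background fragment overlaps a SNP
#'   (see [informativeProbability()]).
#' @return list: `observed` (total template-panel count), `expected`,
#'   `excessRatio`, `pValue`.
#' @export
templateBackgroundTest <- function(profile, rho, pInformative) {
  v <- profileValues(profile)[, c("F.repair_template", "R.repair_template")]
  obs <- sum(v) * profile@nHotspots
  nb <- nrow(v)
  expPerBin <- rho / 2 * profile@binsize * pInformative / 2
  expected <- expPerBin * nb * 2 * profile@nHotspots
  p <- stats::poisson.test(round(obs), expected)$p.value
  list(observed = obs, expected = expected,
       excessRatio = if (expected > 0) obs / expected else Inf, pValue = p)
}

#' Check the strand-polarity law of a profile
#'
#' On the DSB-initiating chromosome, resected ssDNA maps to the forward
#' strand left of the break and to the reverse strand right of it. This
#' report measures the mass each DSB-initiating panel carries on its wrong
#' side (F at distances > `tolerance`, R at distances < `-tolerance`); for
#' a simulation without a wrong-polarity component that mass should be
#' background only.
#'
#' @param profile a [StrandProfile-class].
#' @param tolerance distance tolerance in bp (default 0).
#' @return data.frame with one row per DSB-initiating strand panel:
#'   `panel`, `massCorrect`, `massWrong`, `fracWrong`.
#' @export
profileMirrorCheck <- function(profile, tolerance = 0) {
  bs <- binStarts(profile)
  binMid <- bs + profile@binsize / 2
  v <- profileValues(profile)
  res <- lapply(c("F.dsb_initiating", "R.dsb_initiating"), function(p) {
    wrong <- if (startsWith(p, "F")) binMid > tolerance else binMid < -tolerance
    mw <- sum(v[wrong, p])
    mc <- sum(v[!wrong, p])
    data.frame(panel = p, massCorrect = mc, massWrong = mw,
               fracWrong = if (mw + mc > 0) mw / (mw + mc) else NA_real_)
  })
  do.call(rbind, res)
}
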