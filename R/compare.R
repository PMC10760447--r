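#' Library-size scaling of two per-hotspot signal tables
#'
#' Divides each sample's corrected intensities by its total over the shared
#' autosomal hotspots and multiplies by the geometric mean of the two
#' totals, so both samples are on a common scale while the overall
#' magnitude is preserved.
#'
#' @param signalsA,signalsB data.frames with columns `hotspotId` and
#'   `intensity`, covering the same hotspots.
#' @param autosomalIds hotspot ids to use for the totals (default: all
#'   shared ids).
#' @return list with scaled data.frames `a` and `b` and the `factors`
#'   applied.
#' @export
scaleLibraries <- function(signalsA, signalsB, autosomalIds = NULL) {
  shared <- intersect(signalsA$hotspotId, signalsB$hotspotId)
  if (is.null(autosomalIds)) autosomalIds <- shared
  aui <- intersect(shared, autosomalIds)
  totA <- sum(signalsA$intensity[match(aui, signalsA$hotspotId)])
  totB <- sum(signalsB$intensity[match(aui, signalsB$hotspotId)])
  if (totA <= 0 || totB <= 0)
    stop("nonpositive library total; cannot scale", call. = FALSE)
  g <- sqrt(totA * totB)
  a <- signalsA
  b <- signalsB
  a$intensity <- a$intensity / totA * g
  b$intensity <- b$intensity / totB * g
  list(a = a, b = b, factors = c(a = g / totA, b = g / totB))
}

#' Pearson correlation of two per-hotspot signal vectors
#'
#' Standard product-moment correlation over paired per-hotspot intensities
#' (the genome-wide check that knockout maps still cluster at wild-type
#' hotspots). Zero variance in either vector yields `NA` rather than an
#' error.
#'
#' @param signalsA,signalsB numeric vectors, paired by hotspot.
#' @return Pearson r (or `NA` if undefined).
#' @export
correlateSignals <- function(signalsA, signalsB) {
  ok <- is.finite(signalsA) & is.finite(signalsB)
  if (sum(ok) < 3) stop("need at least 3 paired finite values", call. = FALSE)
  a <- signalsA[ok]
  b <- signalsB[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Cross-genotype intensity comparison by hotspot symmetry class
#'
#' Reproduces the symmetric / asymmetric / X non-PAR contrast of
#' background-corrected hotspot intensities between two genotypes. Hotspot
#' classes: `x_nonpar` from the hotspot flags; otherwise `symmetric` or
#' `asymmetric` (both directions pooled) from the symmetry labels;
#' `undetermined` hotspots are excluded. Intensities are library-scaled
#' (see [scaleLibraries()], over autosomal hotspots), hotspots with
#' nonpositive intensity in either sample are excluded (log ratio
#' undefined) and counted, and each class is summarized by the median
#' log2(WT/KO) ratio with a seeded 2000-replicate bootstrap percentile CI.
#' A class with fewer than 5 usable hotspots is reported `undetermined`.
#'
#' @param signalsWt,signalsKo data.frames with `hotspotId`, `intensity`.
#' @param symmetry symmetry table from [estimateF()] (same hotspot order as
#'   `hotspots`).
#' @param hotspots hotspot `GRanges` (provides `onXNonPar`).
#' @param seed bootstrap seed.
#' @param nBoot bootstrap replicates.
#' @return data.frame with one row per class: `class`, `nHotspots`,
#'   `nExcluded`, `medianLog2Ratio`, `ciLow`, `ciHigh`, `status`.
#' @export
compareClasses <- function(signalsWt, signalsKo, symmetry, hotspots,
                           seed = 7, nBoot = 2000) {
  .checkHotspots(hotspots)
  stopifnot(length(hotspots) == nrow(symmetry))
  mc <- S4Vectors::mcols(hotspots)
  cls <- ifelse(mc$onXNonPar, "x_nonpar",
         ifelse(symmetry$label == "symmetric", "symmetric",
         ifelse(symmetry$label %in% c("asymmetric_B6", "asymmetric_CAST"),
                "asymmetric", NA_character_)))
  names(cls) <- mc$hotspotId

  autosomal <- mc$hotspotId[!mc$onXNonPar]
  sc <- scaleLibraries(signalsWt, signalsKo, autosomalIds = autosomal)
  wt <- sc$a$intensity[match(names(cls), sc$a$hotspotId)]
  ko <- sc$b$intensity[match(names(cls), sc$b$hotspotId)]

  out <- lapply(c("symmetric", "asymmetric", "x_nonpar"), function(cl) {
    sel <- which(cls == cl & !is.na(wt) & !is.na(ko))
    usable <- sel[wt[sel] > 0 & ko[sel] > 0]
    nExcl <- length(sel) - length(usable)
    ratios <- log2(wt[usable] / ko[usable])
    if (length(usable) < 5)
      return(data.frame(class = cl, nHotspots = length(usable),
                        nExcluded = nExcl, medianLog2Ratio = NA_real_,
                        ciLow = NA_real_, ciHigh = NA_real_,
                        status = "undetermined"))
    med <- median(ratios)
    ci <- bootstrapMedianCI(ratios, seed = .stageSeed(seed,
                              match(cl, c("symmetric", "asymmetric",
                                          "x_nonpar"))), nBoot = nBoot)
    data.frame(class = cl, nHotspots = length(usable), nExcluded = nExcl,
               medianLog2Ratio = med, ciLow = ci[1], ciHigh = ci[2],
               status = "ok")
  })
  do.call(rbind, out)
}

#' Seeded bootstrap percentile CI of the median
#'
#' Draws `nBoot` resamples with replacement (all indices drawn in one
#' seeded block, so the replicate set is reproducible and can be
#' re-derived independently) and returns the 2.5% and 97.5% quantiles of
#' the resampled medians.
#'
#' @param x numeric vector.
#' @param seed RNG seed.
#' @param nBoot number of replicates.
#' @param conf confidence level.
#' @return numeric length-2 vector (low, high).
#' @export
bootstrapMedianCI <- function(x, seed = 1, nBoot = 2000, conf = 0.95) {
  n <- length(x)
  meds <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = nBoot)
    apply(idx, 1, function(i) median(x[i]))
  })
  a <- (1 - conf) / 2
  unname(quantile(meds, c(a, 1 - a), type = 7))
}
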