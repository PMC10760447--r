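#' Construct a hotspot set
#'
#' Hotspots are represented as a [GenomicRanges::GRanges] whose strand holds
#' the hotspot orientation (PRDM9 motif strand) and whose metadata columns
#' carry: `hotspotId`, `center` (1-based coordinate of the modal break
#' position), `heat` (nonnegative relative DSB rate), `fTrue` (fraction of
#' DSBs occurring on the B6 homolog, in [0,1]), `prdm9Class` (one of
#' `"CAST"`, `"HUM"`, `"independent"`) and `onXNonPar` (logical; such
#' hotspots lack a homolog and repair from the sister chromatid).
#'
#' @param chrom,start,end interval (1-based closed, as GRanges); `start <=
#'   center <= end` required.
#' @param center 1-based modal break coordinate.
#' @param heat nonnegative relative DSB rate.
#' @param fTrue per-hotspot B6 DSB fraction in [0, 1].
#' @param orientation `"+"` or `"-"`.
#' @param prdm9Class PRDM9 class label.
#' @param onXNonPar logical flag.
#' @param hotspotId unique ids (generated when `NULL`).
#' @return `GRanges` of hotspots.
#' @export
makeHotspots <- function(chrom, start, end, center, heat, fTrue,
                         orientation = "+", prdm9Class = "CAST",
                         onXNonPar = FALSE, hotspotId = NULL) {
  n <- length(start)
  if (is.null(hotspotId)) hotspotId <- sprintf("hs%05d", seq_len(n))
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start, end = end),
    strand = rep(orientation, length.out = n),
    hotspotId = hotspotId,
    center = as.numeric(center),
    heat = as.numeric(heat),
    fTrue = as.numeric(fTrue),
    prdm9Class = rep(as.character(prdm9Class), length.out = n),
    onXNonPar = rep(as.logical(onXNonPar), length.out = n))
  .checkHotspots(gr)
  gr
}

# validity contract for a hotspot GRanges; consumers call this on entry
.checkHotspots <- function(hs) {
  mc <- S4Vectors::mcols(hs)
  need <- c("hotspotId", "center", "heat", "fTrue", "prdm9Class", "onXNonPar")
  if (!all(need %in% names(mc)))
    stop("hotspots must carry metadata columns: ",
         paste(setdiff(need, names(mc)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(mc$hotspotId)) stop("duplicate hotspot ids", call. = FALSE)
  if (any(mc$heat < 0)) stop("hotspot heat must be >= 0", call. = FALSE)
  if (any(mc$fTrue < 0 | mc$fTrue > 1))
    stop("fTrue must lie in [0, 1]", call. = FALSE)
  if (any(mc$center < BiocGenerics::start(hs) |
          mc$center > BiocGenerics::end(hs)))
    stop("hotspot center must lie within its interval", call. = FALSE)
  if (!all(mc$prdm9Class %in% c("CAST", "HUM", "independent")))
    stop("unknown prdm9Class", call. = FALSE)
  if (any(!as.character(BiocGenerics::strand(hs)) %in% c("+", "-")))
    stop("hotspot orientation must be '+' or '-'", call. = FALSE)
  invisible(hs)
}
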