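#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats median qbeta rnorm runif rgamma rpois p.adjust ppois
#'   pbinom qbinom dnorm pnorm cor quantile pgamma integrate
#' @importFrom utils read.table write.table count.fields
NULL

#' Toy diploid genome model for an F1 hybrid
#'
#' Holds chromosome sizes, the SNP table distinguishing the two parental
#' haplotypes (B6 and CAST), and the non-pseudoautosomal X interval, which in
#' males lacks a homolog so that break repair there must use the sister
#' chromatid.
#'
#' @slot chromSizes named numeric vector of chromosome lengths in bp.
#' @slot snps [GenomicRanges::GRanges] of width-1 SNP positions with metadata
#'   columns `b6` and `cast` (single distinct bases).
#' @slot xNonPar [GenomicRanges::GRanges] (possibly empty) marking the
#'   non-pseudoautosomal X region.
#'
#' @seealso [GenomeModel()], [simulateGenome()]
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(chromSizes = "numeric", snps = "GRanges", xNonPar = "GRanges"))

setValidity("GenomeModel", function(object) {
  cs <- object@chromSizes
  msgs <- character()
  if (length(cs) == 0 || is.null(names(cs)) || anyDuplicated(names(cs)) ||
      any(!is.finite(cs)) || any(cs <= 0))
    msgs <- c(msgs, "chromSizes must be a named vector of positive lengths")
  sn <- object@snps
  if (length(sn) > 0) {
    if (!all(c("b6", "cast") %in% names(S4Vectors::mcols(sn))))
      return("snps must carry 'b6' and 'cast' metadata columns")
    if (!all(as.character(GenomeInfoDb::seqnames(sn)) %in% names(cs)))
      msgs <- c(msgs, "SNP on unknown chromosome")
    else if (any(BiocGenerics::end(sn) >
                 cs[as.character(GenomeInfoDb::seqnames(sn))]))
      msgs <- c(msgs, "SNP position beyond chromosome length")
    if (any(BiocGenerics::width(sn) != 1L))
      msgs <- c(msgs, "SNPs must have width 1")
    b6 <- S4Vectors::mcols(sn)$b6
    ca <- S4Vectors::mcols(sn)$cast
    bases <- c("A", "C", "G", "T")
    if (!all(b6 %in% bases) || !all(ca %in% bases))
      msgs <- c(msgs, "alleles must be single bases A/C/G/T")
    if (any(b6 == ca))
      msgs <- c(msgs, "B6 and CAST alleles must differ at every SNP")
    # strictly increasing positions within chromosome
    sp <- split(BiocGenerics::start(sn),
                as.character(GenomeInfoDb::seqnames(sn)))
    if (any(vapply(sp, function(p) is.unsorted(p, strictly = TRUE), logical(1))))
      msgs <- c(msgs, "SNP positions must be strictly increasing per chromosome")
  }
  xp <- object@xNonPar
  if (length(xp) > 0) {
    if (!all(as.character(GenomeInfoDb::seqnames(xp)) %in% names(cs)))
      msgs <- c(msgs, "xNonPar on unknown chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeModel
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param snps either a `GRanges` with `b6`/`cast` metadata columns, or a
#'   data.frame with columns `chrom`, `pos` (0-based), `b6`, `cast`.
#' @param xNonPar optional `GRanges` (or `NULL`) marking the X non-PAR
#'   interval.
#' @return A validated [GenomeModel-class] object.
#' @examples
#' gm <- GenomeModel(c(chr1 = 1e6),
#'                   data.frame(chrom = "chr1", pos = c(100, 300),
#'                              b6 = c("A", "C"), cast = c("G", "T")))
#' @export
GenomeModel <- function(chromSizes, snps, xNonPar = NULL) {
  if (is.data.frame(snps)) {
    snps <- GenomicRanges::GRanges(
      snps$chrom,
      IRanges::IRanges(start = as.integer(snps$pos) + 1L, width = 1L),
      b6 = as.character(snps$b6), cast = as.character(snps$cast))
  }
  if (is.null(xNonPar)) xNonPar <- GenomicRanges::GRanges()
  new("GenomeModel", chromSizes = chromSizes, snps = snps, xNonPar = xNonPar)
}

#' @describeIn GenomeModel chromosome sizes accessor
#' @param x a `GenomeModel`
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname GenomeModel
#' @export
setMethod("chromSizes", "GenomeModel", function(x) x@chromSizes)

#' @rdname GenomeModel
#' @export
setGeneric("snps", function(x) standardGeneric("snps"))

#' @rdname GenomeModel
#' @export
setMethod("snps", "GenomeModel", function(x) x@snps)

#' @rdname GenomeModel
#' @export
setGeneric("xNonPar", function(x) standardGeneric("xNonPar"))

#' @rdname GenomeModel
#' @export
setMethod("xNonPar", "GenomeModel", function(x) x@xNonPar)

#' @rdname GenomeModel
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname GenomeModel
#' @export
setMethod("genomeLength", "GenomeModel", function(x) sum(x@chromSizes))

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel with", length(object@chromSizes), "chromosome(s),",
      sum(object@chromSizes), "bp,", length(object@snps), "SNPs\n")
  if (length(object@xNonPar) > 0)
    cat("  X non-PAR:",
        as.character(GenomeInfoDb::seqnames(object@xNonPar))[1], "\n")
})

#' Strand- and homolog-role-resolved aggregate binding profile
#'
#' Per-hotspot-averaged fragment midpoint counts around hotspot centers,
#' resolved by sequencing strand (F/R) and by repair role of the homolog the
#' fragment was assigned to (DSB-initiating vs repair-template). This is the
#' data structure behind break-centred metaplots of RPA/DMC1/RAD51 SSDS
#' signal at asymmetric hotspots.
#'
#' @slot binsize bin width in bp.
#' @slot halfWidth half window width W in bp; bins tile [-W, W).
#' @slot values matrix (bins x 4 panels) of fragments per hotspot per bin;
#'   panels `F.dsb_initiating`, `R.dsb_initiating`, `F.repair_template`,
#'   `R.repair_template`.
#' @slot nHotspots number of (asymmetric) hotspots averaged over.
#' @slot nFragments number of fragments contributing to the profile.
#'
#' @exportClass StrandProfile
setClass("StrandProfile",
  representation(binsize = "integer", halfWidth = "integer",
                 values = "matrix", nHotspots = "integer",
                 nFragments = "integer"))

setValidity("StrandProfile", function(object) {
  nb <- 2L * object@halfWidth %/% object@binsize
  msgs <- character()
  if (object@binsize < 1L) msgs <- c(msgs, "binsize must be >= 1")
  if (object@halfWidth %% object@binsize != 0L)
    msgs <- c(msgs, "halfWidth must be a multiple of binsize")
  if (nrow(object@values) != nb)
    msgs <- c(msgs, "values must have 2*halfWidth/binsize rows")
  if (!identical(colnames(object@values), .panelNames))
    msgs <- c(msgs, "values must have the four canonical panel columns")
  if (any(object@values < 0)) msgs <- c(msgs, "profile values must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname StrandProfile-class
#' @param x a `StrandProfile` or `FootprintModel`
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname StrandProfile-class
#' @export
setMethod("profileValues", "StrandProfile", function(x) x@values)

#' @rdname StrandProfile-class
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))

#' @rdname StrandProfile-class
#' @export
setMethod("binStarts", "StrandProfile", function(x)
  seq(-x@halfWidth, x@halfWidth - x@binsize, by = x@binsize))

setMethod("show", "StrandProfile", function(object) {
  cat("StrandProfile:", nrow(object@values), "bins of", object@binsize,
      "bp over [-", object@halfWidth, ",", object@halfWidth, "), averaged over",
      object@nHotspots, "hotspot(s);", object@nFragments,
      "contributing fragments\n")
})

#' Per-break protein binding footprint from nonnegative deconvolution
#'
#' The nonnegative binding density of a protein as a function of signed
#' distance from the break, one column per (strand x homolog-role) panel,
#' obtained by inverting the within-hotspot break-position blur of an
#' aggregate [StrandProfile-class] under a nonnegativity constraint.
#'
#' @slot values matrix (bins x panels) of nonnegative densities.
#' @slot residuals named numeric, Euclidean residual norm of the fit per panel.
#' @slot lambda ridge penalty used (0 for plain NNLS).
#' @slot binsize,halfWidth bin grid, as in [StrandProfile-class].
#'
#' @exportClass FootprintModel
setClass("FootprintModel",
  representation(values = "matrix", residuals = "numeric", lambda = "numeric",
                 binsize = "integer", halfWidth = "integer"))

setValidity("FootprintModel", function(object) {
  msgs <- character()
  if (any(object@values < 0)) msgs <- c(msgs, "footprint values must be >= 0")
  if (object@lambda < 0) msgs <- c(msgs, "lambda must be >= 0")
  if (length(object@residuals) != ncol(object@values))
    msgs <- c(msgs, "one residual per panel required")
  if (length(msgs)) msgs else TRUE
})

#' @rdname FootprintModel-class
#' @param x a `FootprintModel`
#' @export
setGeneric("footprintValues", function(x) standardGeneric("footprintValues"))

#' @rdname FootprintModel-class
#' @export
setMethod("footprintValues", "FootprintModel", function(x) x@values)

#' @rdname FootprintModel-class
#' @export
setGeneric("residualNorms", function(x) standardGeneric("residualNorms"))

#' @rdname FootprintModel-class
#' @export
setMethod("residualNorms", "FootprintModel", function(x) x@residuals)

#' @rdname FootprintModel-class
#' @export
setMethod("binStarts", "FootprintModel", function(x)
  seq(-x@halfWidth, x@halfWidth - x@binsize, by = x@binsize))

setMethod("show", "FootprintModel", function(object) {
  cat("FootprintModel:", nrow(object@values), "bins x", ncol(object@values),
      "panel(s), lambda =", object@lambda, "\n  residual norms:",
      paste(sprintf("%s=%.4g", names(object@residuals), object@residuals),
            collapse = ", "), "\n")
})
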