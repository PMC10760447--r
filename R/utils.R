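# Internal helpers shared across modules.

# Stage seeds are derived from the global seed by stage-index offset so that
# every stage of a pipeline run is reproducible in isolation.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) + as.integer(stage)) %% .Machine$integer.max
}

# 1-based coordinate of a fragment midpoint, defined so that it equals the
# floor-midpoint of the 0-based half-open interval plus one. For [4000,4150)
# (BED) the midpoint offset used throughout is 4075.
.mid1 <- function(gr) {
  (BiocGenerics::start(gr) + BiocGenerics::end(gr) + 1L) %/% 2L
}

.midGRanges <- function(gr) {
  GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr),
    IRanges::IRanges(start = .mid1(gr), width = 1L)
  )
}

.fmtNum <- function(x) sprintf("%.17g", x)

.panelNames <- c("F.dsb_initiating", "R.dsb_initiating",
                 "F.repair_template", "R.repair_template")

.assertScalarNumber <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("'%s' must be a single finite number >= %g", name, min),
         call. = FALSE)
  invisible(x)
}

# cosine similarity between two nonnegative vectors; NA if either is all-zero
.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
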