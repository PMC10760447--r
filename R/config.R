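.componentNames <- c("filament_full", "filament_proximal", "filament_distal",
                     "return_binding", "repair_template", "wrong_polarity")

#' Simulation configuration for the SSDS fragment generator
#'
#' Parameterizes one simulated SSDS assay: which genotype (wild type or a
#' strand-exchange-defective knockout, for which `DMC1KO` stands), which
#' protein is assayed, how many signal fragments to draw, the uniform
#' background rate, the resection-length and fragment-length distributions,
#' and the mixture of binding-geometry components that places each fragment
#' relative to its break.
#'
#' Components (weights sum to 1):
#' \describe{
#'   \item{filament_full}{anchor distance d uniform over the whole resected
#'     filament, d ~ U(0, L): RPA coating the full resection tract, or RAD51
#'     covering the whole filament when DMC1 is absent.}
#'   \item{filament_proximal}{d ~ U(0, c L): break-proximal binding (DMC1 in
#'     wild type); c = `distalFraction`.}
#'   \item{filament_distal}{d ~ U(c L, L): binding near the ssDNA/dsDNA
#'     junction (RAD51 in wild type).}
#'   \item{return_binding}{renewed RPA binding of the DSB-initiating
#'     chromosome after strand invasion; fragment midpoints peak at
#'     `returnBindingOffset` bp (default 750, the midpoint of the reported
#'     700-800 bp band) from the break.}
#'   \item{repair_template}{D-loop signal on the other homolog, absent in
#'     strand-exchange-defective genotypes and at X non-PAR hotspots;
#'     midpoint offset ~ +/- N(`dloopOffsetMean`, `dloopOffsetSd`), with
#'     opposite-role strand polarity (forward strand right of the break).}
#'   \item{wrong_polarity}{signal on the DSB-initiating homolog with
#'     reversed polarity (newly synthesized DNA after strand exchange);
#'     absent in knockouts.}
#' }
#'
#' @slot seed RNG seed; the generator is fully deterministic given it.
#' @slot genotype `"WT"` or `"DMC1KO"`.
#' @slot protein `"RPA"`, `"RAD51"` or `"DMC1"`.
#' @slot nSignalFragments number of signal fragments to draw.
#' @slot backgroundRate uniform background, fragments per bp genome-wide.
#' @slot resectionShape,resectionMean gamma resection-length model (bp).
#' @slot fragLenMean,fragLenSd,fragLenMin normal fragment-length model,
#'   truncated below at `fragLenMin` (bp).
#' @slot dsbSd SD (bp) of the true break position about the hotspot center
#'   (the DSB-location kernel used later in deconvolution).
#' @slot weights named numeric over the six components above; sums to 1.
#' @slot returnBindingOffset,returnBindingWidth return-binding peak (bp).
#' @slot dloopOffsetMean,dloopOffsetSd D-loop midpoint offset model (bp).
#' @slot wrongPolarityMax maximal anchor distance of wrong-polarity signal.
#' @slot distalFraction proximal/distal split point of the filament.
#' @slot interHomologLifespanMultiplier multiplies the effective heat of
#'   symmetric autosomal hotspots in WT: inter-homolog intermediates persist
#'   longer and accumulate more ssDNA-bound protein.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(seed = "integer", genotype = "character",
                 protein = "character", nSignalFragments = "integer",
                 backgroundRate = "numeric",
                 resectionShape = "numeric", resectionMean = "numeric",
                 fragLenMean = "numeric", fragLenSd = "numeric",
                 fragLenMin = "numeric", dsbSd = "numeric",
                 weights = "numeric",
                 returnBindingOffset = "numeric",
                 returnBindingWidth = "numeric",
                 dloopOffsetMean = "numeric", dloopOffsetSd = "numeric",
                 wrongPolarityMax = "numeric", distalFraction = "numeric",
                 interHomologLifespanMultiplier = "numeric"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (!object@genotype %in% c("WT", "DMC1KO"))
    msgs <- c(msgs, "genotype must be 'WT' or 'DMC1KO'")
  if (!object@protein %in% c("RPA", "RAD51", "DMC1"))
    msgs <- c(msgs, "protein must be 'RPA', 'RAD51' or 'DMC1'")
  w <- object@weights
  if (!identical(sort(names(w)), sort(.componentNames)))
    msgs <- c(msgs, "weights must be named by the six components")
  else {
    if (any(w < 0)) msgs <- c(msgs, "component weights must be >= 0")
    if (abs(sum(w) - 1) > 1e-9) msgs <- c(msgs, "component weights must sum to 1")
    if (object@genotype == "DMC1KO" &&
        any(w[c("repair_template", "return_binding", "wrong_polarity")] > 0))
      msgs <- c(msgs, paste("strand-exchange-defective genotype cannot have",
                            "repair_template, return_binding or wrong_polarity",
                            "components"))
  }
  for (s in c("backgroundRate", "resectionShape", "resectionMean",
              "fragLenMean", "fragLenSd", "fragLenMin", "dsbSd",
              "returnBindingOffset", "returnBindingWidth", "dloopOffsetMean",
              "dloopOffsetSd", "wrongPolarityMax"))
    if (methods::slot(object, s) < 0)
      msgs <- c(msgs, sprintf("%s must be >= 0", s))
  if (object@distalFraction < 0 || object@distalFraction > 1)
    msgs <- c(msgs, "distalFraction must lie in [0, 1]")
  if (object@interHomologLifespanMultiplier <= 0)
    msgs <- c(msgs, "interHomologLifespanMultiplier must be > 0")
  if (object@nSignalFragments < 0)
    msgs <- c(msgs, "nSignalFragments must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed integer RNG seed.
#' @param genotype `"WT"` or `"DMC1KO"`.
#' @param protein `"RPA"`, `"RAD51"` or `"DMC1"`.
#' @param nSignalFragments number of signal fragments.
#' @param backgroundRate background fragments per bp genome-wide.
#' @param weights named component weights (see
#'   [SimulationConfig-class]); must sum to 1.
#' @param resectionShape,resectionMean gamma resection model (default
#'   shape 4, mean 1000 bp).
#' @param fragLenMean,fragLenSd,fragLenMin fragment length model (default
#'   150 +/- 30, min 50 bp).
#' @param dsbSd SD of break position about hotspot center (bp).
#' @param returnBindingOffset,returnBindingWidth return-binding midpoint
#'   peak position and width (bp).
#' @param dloopOffsetMean,dloopOffsetSd D-loop midpoint offset (bp).
#' @param wrongPolarityMax max anchor distance of wrong-polarity signal (bp).
#' @param distalFraction filament proximal/distal split point.
#' @param interHomologLifespanMultiplier WT heat multiplier for symmetric
#'   autosomal hotspots.
#' @return a validated [SimulationConfig-class].
#' @export
SimulationConfig <- function(seed = 1L, genotype = "WT", protein = "RPA",
    nSignalFragments = 1e5, backgroundRate = 5e-5,
    weights = c(filament_full = 1, filament_proximal = 0,
                filament_distal = 0, return_binding = 0,
                repair_template = 0, wrong_polarity = 0),
    resectionShape = 4, resectionMean = 1000,
    fragLenMean = 150, fragLenSd = 30, fragLenMin = 50,
    dsbSd = 150, returnBindingOffset = 750, returnBindingWidth = 100,
    dloopOffsetMean = 300, dloopOffsetSd = 150,
    wrongPolarityMax = 500, distalFraction = 0.5,
    interHomologLifespanMultiplier = 1) {
  w <- structure(numeric(length(.componentNames)), names = .componentNames)
  w[names(weights)] <- weights
  new("SimulationConfig", seed = as.integer(seed), genotype = genotype,
      protein = protein, nSignalFragments = as.integer(nSignalFragments),
      backgroundRate = backgroundRate, resectionShape = resectionShape,
      resectionMean = resectionMean, fragLenMean = fragLenMean,
      fragLenSd = fragLenSd, fragLenMin = fragLenMin, dsbSd = dsbSd,
      weights = w, returnBindingOffset = returnBindingOffset,
      returnBindingWidth = returnBindingWidth,
      dloopOffsetMean = dloopOffsetMean, dloopOffsetSd = dloopOffsetSd,
      wrongPolarityMax = wrongPolarityMax, distalFraction = distalFraction,
      interHomologLifespanMultiplier = interHomologLifespanMultiplier)
}

setMethod("show", "SimulationConfig", function(object) {
  w <- object@weights
  cat(sprintf("SimulationConfig: %s / %s, %d signal fragments, background %g/bp\n",
              object@genotype, object@protein, object@nSignalFragments,
              object@backgroundRate))
  cat("  components:",
      paste(sprintf("%s=%.2f", names(w)[w > 0], w[w > 0]), collapse = ", "),
      "\n")
})

#' Documented genotype/protein simulation presets
#'
#' Returns the default component mixture for each assayed protein in wild
#' type and in a strand-exchange-defective knockout:
#' \itemize{
#'   \item WT / RPA: full-filament resection decay plus return binding
#'     (second midpoint peak at 750 bp), repair-template D-loop signal and a
#'     wrong-polarity component.
#'   \item DMC1KO / RPA: resection decay only; no repair-template signal at
#'     all (inter-homolog intermediates are absent without DMC1).
#'   \item WT / RAD51: distal-only filament binding (DMC1 occupies the
#'     break-proximal part; the proximal weight is 0).
#'   \item DMC1KO / RAD51: the whole filament.
#'   \item WT / DMC1: break-proximal binding plus wrong polarity.
#'   \item DMC1KO / DMC1: an error (the assayed protein is knocked out).
#' }
#'
#' @param genotype `"WT"` or `"DMC1KO"`.
#' @param protein `"RPA"`, `"RAD51"` or `"DMC1"`.
#' @param ... overrides passed on to [SimulationConfig()] (e.g. `seed`,
#'   `nSignalFragments`, `interHomologLifespanMultiplier`).
#' @return a [SimulationConfig-class].
#' @examples
#' cfg <- presetConfig("DMC1KO", "RPA", seed = 3)
#' cfg@weights[["repair_template"]]  # 0: no D-loops without DMC1
#' @export
presetConfig <- function(genotype = c("WT", "DMC1KO"),
                         protein = c("RPA", "RAD51", "DMC1"), ...) {
  genotype <- match.arg(genotype)
  protein <- match.arg(protein)
  key <- paste(genotype, protein, sep = "/")
  weights <- switch(key,
    "WT/RPA" = c(filament_full = 0.45, return_binding = 0.15,
                 repair_template = 0.30, wrong_polarity = 0.10),
    "DMC1KO/RPA" = c(filament_full = 1),
    "WT/RAD51" = c(filament_distal = 1),
    "DMC1KO/RAD51" = c(filament_full = 1),
    "WT/DMC1" = c(filament_proximal = 0.9, wrong_polarity = 0.1),
    "DMC1KO/DMC1" = stop("no DMC1 assay in a Dmc1 knockout", call. = FALSE))
  SimulationConfig(genotype = genotype, protein = protein,
                   weights = weights, ...)
}
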