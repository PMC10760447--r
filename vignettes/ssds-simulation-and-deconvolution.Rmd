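---
title: "Simulating and deconvolving homolog-resolved SSDS maps of meiotic recombination"
author: "ssdskit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and deconvolving homolog-resolved SSDS maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdskit)
```

## The biological model

Meiotic recombination starts with programmed double-strand breaks (DSBs) at
PRDM9-positioned hotspots. Broken ends are resected to 3' single-stranded
overhangs; RPA coats the ssDNA first and is then replaced by the
recombinases DMC1 and RAD51, which search the homologous chromosome and
form a D-loop with it. SSDS (single-stranded DNA sequencing) ChIP recovers
the ssDNA-bound fraction of each of these proteins, strand-specifically:
ssDNA from the left break end maps to the forward strand and ends at the
break; ssDNA from the right end maps to the reverse strand and starts at
it. In an F1 hybrid (B6 x CAST) with dense SNPs, reads can further be
assigned to the homolog they came from, separating the DSB-initiating
chromosome from the repair-template chromosome at hotspots where
essentially all breaks happen on one homolog ("asymmetric" hotspots, by
the PRDM9/H3K4me3 fraction rule f >= 0.9 or f <= 0.1; the thresholds are
inclusive). Strand-exchange-defective mutants (a Dmc1 knockout being the
canonical case) make no inter-homolog joints at all, so any
repair-template signal must vanish in them.

`ssdskit` implements this whole analysis as a closed loop: a forward
simulator with per-fragment truth labels, peak calling, haplotype
assignment and symmetry classification, strand/role-resolved aggregate
profiles, nonnegative deconvolution of per-break footprints, and a
cross-genotype intensity comparison.

## The fragment generator

Each signal fragment is produced by one simulated DSB event:

1. a hotspot is chosen proportionally to its heat;
2. the broken homolog is B6 with probability `fTrue` (the X non-PAR has
   no homolog: breaks there are always on the single, maternal/B6 X and
   repair from the sister chromatid);
3. the break position is drawn about the hotspot center, normal with SD
   `dsbSd` (default 150 bp). This same distribution is the DSB-location
   kernel that deconvolution later inverts;
4. a binding-geometry component is drawn from the preset mixture, a
   resection length L ~ gamma(shape 4, mean 1000 bp) and a fragment
   length ~ N(150, 30) truncated at 50 bp are drawn, and the fragment is
   placed with the SSDS polarity rule above. Fragments overrunning a
   chromosome end are truncated and counted, never silently dropped.

The component vocabulary ties each assay/genotype preset to the expected
in vivo binding patterns: `filament_full` (RPA resection decay, or RAD51 covering the
whole filament when DMC1 is absent), `filament_proximal` (DMC1 near the
break), `filament_distal` (RAD51 near the ssDNA/dsDNA junction in wild
type), `return_binding` (renewed RPA binding of the DSB homolog after
strand invasion), `repair_template` (the RPA-coated displaced strand of
the D-loop, on the other homolog, with opposite-role polarity), and
`wrong_polarity` (signal on the DSB homolog with reversed polarity,
modeling newly synthesized DNA after strand exchange). Knockout presets
carry none of the strand-exchange-dependent components; the class
validity actively forbids them.

Two deliberate geometry choices:

* the `return_binding` offset (750 bp, the midpoint of the reported
  700-800 bp band) parameterizes the *fragment-midpoint* peak position.
  Anchoring the fragment end instead would displace the observable peak
  by half a fragment length, putting it outside the band the feature is
  named for.
* the D-loop (`repair_template`) midpoint offset is +/- N(300, 150) bp,
  placing template signal break-proximally; its share of WT RPA signal
  (0.30) is a free knob with no canonical value, and several properties
  (e.g. template-panel purity under imperfect asymmetry) depend on it
  arithmetically: at f = 0.97, contamination of the template panel by
  minor-homolog DSB fragments is `0.03 (1 - w) / (0.03 (1 - w) + 0.97 w)`
  for template share `w`.

The generator also emits an H3K4me3-like set (`simulateH3k4me3`):
both-homolog binding proportional to PRDM9 binding with B6 probability
exactly `fTrue`, which is the assay the symmetry statistic f is defined
on. Estimating f from a WT RPA library instead would be biased toward 0.5
by the D-loop template signal - which is precisely why the f source is a
separate assay.

## Haplotype assignment and symmetry

No sequence is simulated; genotyping is emulated from truth labels with
an optional per-SNP miscall rate (default 0). A fragment is called B6 or
CAST only if all overlapped SNP alleles agree; any disagreement is
`conflicting` and excluded (conservative), no overlap is `unassigned`.
Background fragments derive from one unknown homolog, drawn fairly per
fragment. The per-hotspot f estimate uses midpoint-in-interval counting,
an exact Clopper-Pearson 95% CI, the inclusive f thresholds, and
a minimum of 10 informative fragments for a defined label (the rule's
source states no minimum; 10 keeps the label noise below the class
widths at the fragment counts used here).

## Peaks and corrected intensity

Peak calling is a sliding-window Poisson test (window 1000 bp, step
window/2) on pooled-strand fragment midpoint counts against `rho x
window`, BH-corrected across all tested windows; significant windows are
merged across gaps <= 500 bp and re-scored. The background rate `rho` is
fragments fully outside a hotspot mask per unmasked bp. Corrected
intensity is `n - rho * width` with midpoint counting (each fragment in
at most one peak); negative values are kept, since clamping would bias
class comparisons downstream.

## Profiles and deconvolution

Aggregate profiles use only autosomal asymmetric hotspots, where the
haplotype call identifies the repair role. Each informative fragment
contributes its midpoint's signed distance from the hotspot center,
mirrored (sign and strand label together, so the polarity law reads
identically in the oriented frame) for orientation "-" hotspots, binned
at 40 bp over [-2400, 2400) and averaged per hotspot. 2400 is used
rather than a round 2.5 kb so the grid is an exact multiple of the bin
and symmetric about the center. Because profiles are center-referenced,
the break-position spread leaks a few percent of mass across zero even
with perfect polarity; wrong-side diagnostics therefore use a tolerance
of about 4 x `dsbSd`.

The observed profile is the per-break footprint convolved with the
break-position kernel, `y = H s`. `deconvolve()` solves `min ||y - H s||^2
+ lambda ||s||^2, s >= 0` with an authored Lawson-Hanson active-set
solver (KKT tolerance 1e-10; ridge via system augmentation). Kernel
conditioning matters: a Gaussian kernel with SD much larger than the bin
width makes H numerically singular and NNLS solutions spiky. The package
therefore (a) exposes a small ridge and uses `lambda = 0.01` in its own
analyses, and (b) evaluates footprint recovery at 240 bp resolution
(six 40 bp bins), below the ~700-800 bp structure of interest but above
the noise-dominated fine scale. Under that protocol, 20/20 seeded
generator round trips at 1e5 fragments exceed cosine similarity 0.95
against the truth-label footprint. Secondary-peak localization uses the
WT-minus-knockout difference footprint: the knockout shares the
resection decay but lacks the DMC1-dependent return-binding bump, so the
difference isolates it - the same contrast logic that identifies the
second RPA peak in real data.

## Cross-genotype comparison

Per-hotspot corrected intensities are library-scaled by total autosomal
hotspot signal (geometric-mean preserving), hotspots are classed as
symmetric / asymmetric (pooled directions) / X non-PAR, and each class is
summarized by the median log2(WT/KO) with a seeded 2000-replicate
bootstrap percentile CI; hotspots nonpositive in either sample are
excluded and counted. A `interHomologLifespanMultiplier > 1` in the WT
preset models the longer lifespan of inter-homolog strand-exchange
intermediates by inflating the effective heat of symmetric autosomal
hotspots; with it, the symmetric class ratio separates from the
asymmetric and X classes with non-overlapping CIs, the in-silico analog
of the published three-way contrast.

## Study sizes and determinism

The packaged analyses run at desk scale, chosen to keep every check
inside a few minutes while leaving comfortable statistical margins:
genomes of 1-2 chromosomes x 2-5 Mb, 40-500 hotspots, 1e5-2e5 fragments
per assay, 20-seed repetition for recovery rates, and a demonstration
pipeline of 2 x 2 Mb, 100 hotspots and 2e5 fragments per genotype. Every
random stage takes an explicit seed; pipeline stage seeds derive from the
global seed by stage-index offset, and a config rerun reproduces the
SHA-256 manifest byte-identically.

## What the simulation does and does not show

The generator reproduces the mechanistic geometry the analyses depend on
(strand polarity, homolog roles, component layout, heat proportionality,
uniform background) but not read-level reality: no sequence, no mapping
bias between haplotypes, no PCR duplicates, no per-hotspot kernel
heterogeneity (a single shared break-position kernel is assumed, and the
kernel is supplied rather than estimated - for real data it must come
from an external break map). Passing tests therefore validate the
analysis pipeline's correctness and its operating characteristics under
the stated model, not the biological fidelity of any particular real
library. Real-data peak counts, overlap fractions and correlations
reported for the deposited datasets depend on those data and prior
hotspot catalogs and are outside what this package can or does check.

## Session info

```{r}
sessionInfo()
```
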