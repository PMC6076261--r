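---
title: "Quantifying autophagy imaging and protease-assay readouts with punctaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying autophagy imaging and protease-assay readouts with punctaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaflux)
```

# Overview

Autophagy drug-discovery campaigns against the cysteine protease ATG4B lean
on a small set of quantitative readouts: per-cell counts of GFP-LC3 puncta
from high-content imaging, the red:yellow punctum ratio of the tandem
mRFP-eGFP-LC3 reporter, Lysotracker intensity, protease-assay enzymology
(IC50, Michaelis-Menten constants, inhibition mode and Ki, binding KD, a
mass-spectrometry cleavage fraction), western-blot densitometry with
bafilomycin-A1 additivity logic, and noncompartmental pharmacokinetics.
`punctaflux` implements these computations as a tested, reusable pipeline,
and pairs them with seeded synthetic-data generators that carry complete
ground truth, so every quantification step can be audited against data
whose answer is known.

This vignette is the package's methods account: the models, their
assumptions, the tunable parameters, and the design choices made where the
underlying assay descriptions leave the algorithm open.

# The synthetic-data generators

Real raw data for these assays (microscopy fields, plate reads, capillary
series) are rarely deposited; the package therefore treats simulation as a
first-class input. One integer seed drives an order-stable stream of
sub-seeds, and identical specs give bit-identical outputs.

## Imaging fields

`genHcsField()` renders a three-channel field — nuclear stain, viability
stain (ethidium-homodimer-like), GFP-LC3 — and `genTandemField()` renders
the red/green/nuclear tandem-reporter equivalent. Geometry is deliberately
idealized: cells and nuclei are discs with Gaussian-blurred edges, placed
at pairwise-separated random centers; puncta are small bright discs placed
strictly inside their cell. Real-cell morphology is out of scope — the
discs are sufficient to exercise every downstream rule (segmentation,
radius-limited cell borders, overlap-based viability, form-factor
filtering, colocalization).

Defaults describe a 20x high-content acquisition of a 400 x 400 px field
with 50 cells: cell radius 14 px, nucleus radius 5 px, punctum radius 2
px, Poisson(4) puncta per cell, background 100 with a linear gradient,
per-cell lognormal brightness (sdlog 0.2), Poisson shot noise plus
additive Gaussian read noise (SD 5). Punctum centers keep a separation of
`2 r + 3` px so the simulated vesicles stay optically resolvable after
edge blurring; at tighter spacing a punctum pair merges into a single
connected component, which is a property of unresolvable data rather than
of a counting method. Dead cells carry a viability-stain disc covering 80%
of the cell disc, far from the 50% decision rule, so live/dead ground
truth is unambiguous; an `ambiguous` mode draws overlaps near 0.5 for
threshold testing.

What passing recovery tests on these fields shows — and does not show:
they demonstrate that the measurement chain (threshold, label, filter,
assign, count) is unbiased and near-lossless when its assumptions hold.
They say nothing about segmentation of irregular or confluent cells,
out-of-focus light, or spectral bleed-through, which the generator does
not emulate.

## Assay tables

`genAssayTable()` draws dose-response (four-parameter logistic),
substrate-by-inhibitor rate grids (Michaelis-Menten with uncompetitive,
competitive or noncompetitive terms), depletion-corrected 1:1 binding,
one-compartment oral pharmacokinetics, and linear progress curves. Each
table contains the noiseless model values (`is_truth` rows) plus `n`
noisy replicates; with zero noise the replicates equal the closed forms
exactly. The default kinetic design (`defaultKineticGrid()`) spans
substrate 10-124.4 uM and inhibitor 0 plus 6-54 uM, the plate layout used
for inhibition-mode work.

# High-content puncta scoring

The pipeline is `segmentNuclei()` (Otsu threshold, hole fill, area
filter, 8-connected labeling, optional watershed split),
`defineCellRegions()` (Voronoi-limited digital disc of configurable
radius around each nucleus centroid; ties to the lower label),
`classifyViability()` (dead iff the viability-stain overlap of the cell
region is at least 0.5 — the threshold is inclusive), `detectPuncta()`
and `summarizeField()`.

Pixel conventions are fixed and oracle-tested: objects are 8-connected,
the background/hole convention is 4-connected, grids are 1-based
`(row, col)`, and the perimeter of a region is the count of 4-neighbor
edges between region and non-region pixels (image border counts as
non-region). Under this convention the form factor `4*pi*A/P^2` of any
digital shape is at most `pi/4 ~ 0.785` (single pixels and filled squares
attain it), and the conventional cutoff 0.4 separates compact puncta from
streaks. Form-factor values are convention-dependent; published cutoffs
only transfer together with their perimeter definition, which is why the
convention is stated explicitly.

"GFP positive" is not a universal definition; the package's declared
default is: subtract a median-filtered background (15 px window, computed
on a coarse grid and bilinearly interpolated), threshold at `k = 4`
robust SDs, require the pixel to clear the threshold in both the raw and
a lightly smoothed (sigma 0.8 px) residual, then apply a 3 x 3 majority
vote. The two-scale rule removes isolated shot-noise pixels; the majority
vote regularizes noise-ragged boundaries, which matters because the
edge-count perimeter inflates sharply with single-pixel raggedness and
would otherwise push genuinely compact puncta below the 0.4 form-factor
cutoff. A fixed-threshold mode (`gfpMode = "fixed"`) bypasses all of this
for hand-built masks and instrument-thresholded images; filter semantics
(area >= 1 keeps single pixels; form-factor and area cutoffs are
inclusive) are identical in both modes.

The field endpoint is the fraction of live cells with at least
`minPuncta` puncta — 5 for the screening endpoint, 1 for the
tissue-style "puncta-positive" reading. The comparator is `>=`; assay
descriptions alternate between "at least 5" and "greater than five", so
the threshold is configuration, not hard-coded. A field with no live
cells reports `NA` with an explicit flag rather than a silent zero.

# Tandem-reporter flux and Lysotracker

Autophagosomes carry both mRFP and eGFP (yellow); in acidic
autolysosomes the GFP quenches, leaving red-only puncta, so a rising
red:yellow ratio reads as flux through the pathway. Each fluorophore
channel is processed independently: `preprocessMask()` applies a Gaussian
filter (sigma 1 px) and an adaptive local-mean threshold
(`mask = smoothed > localMean - offset`, block 11 px). Note the sign
convention of the offset: positive offsets are permissive (a constant
image becomes all-foreground), so useful punctum masks use a negative
offset; the default is `-2 x` robust SD of the smoothed image. The
pipeline then regularizes the mask (majority vote) and keeps components
of at least 6 px — a resolvable punctum disc covers 13+ px at this scale
while surviving noise blobs are smaller.

A red punctum is yellow iff the largest fraction of its area covered by
a single green punctum reaches 0.5 (inclusive, configurable); with no
green punctum it is red-only. The per-cell ratio `nRedOnly / nYellow` is
computed only for cells with at least one yellow punctum; zero-yellow
cells are excluded from the mean but counted and reported, avoiding
silent infinities. The pooled ratio (total red-only over total yellow) is
always computed and is the recommended field-level statistic: at low
red-only fractions a single field's numerator is a few dozen counts, and
pooling across fields (the analogue of scoring at least 100 cells)
stabilizes it. Fewer than 100 assigned cells raises a `few_cells` flag.

`ltrMetric()` implements the dye-intensity readout: mean gray of the
unadjusted dye channel minus the mean over a cell-free background mask
(pixels below the channel's Otsu threshold, eroded by 2 px), divided by
the nuclei count, optionally normalized to a control image.

# Enzymology

All nonlinear fits use Levenberg-Marquardt (`minpack.lm::nlsLM`) with
data-driven starts: quartile-based for the 4PL, Hanes-Woolf linearization
for Michaelis-Menten. Starts are documented because convergence behavior
depends on them; a failed attempt is retried from deterministically
scaled starts (noiseless data can place the start exactly at the optimum,
which trips the singular-gradient check).

* `fitStandardCurve()` / `initialRate()`: OLS fluorescence-to-molar
  conversion and initial-rate extraction over the window where estimated
  product stays below 10% of the starting substrate (minimum 3 points).
* `fitIC50()`: 4PL with free asymptotes (fits falling and rising curves);
  flat data are flagged `no_dose_effect` with no IC50 emitted.
* `fitMichaelisMenten()`, `fitUncompetitiveKi()`: per-condition and
  global grid fits; the global uncompetitive fit also reports the
  apparent-parameter consistency check (`Vmax_app/Vmax` and `KM_app/KM`
  both equal `1/(1 + I/Ki)` for a true uncompetitive inhibitor).
* `diagnoseInhibitionMode()` is trend-based, as inhibition modes are
  argued from apparent-parameter plots: a parameter counts as changing
  when its GLS trend across the inhibitor range is both material
  (relative change >= tau, default 10%) and supported by at least 2.5
  standard errors. The evidence gate exists because apparent `Vmax` is
  weakly identified whenever apparent `KM` exceeds the highest tested
  substrate concentration (as happens for competitive inhibitors on this
  design), and estimation noise alone would otherwise exceed tau. With no
  standard errors supplied the pure tolerance rule applies.
* `fitBindingKd()` fits the depletion-corrected quadratic isotherm, which
  stays valid when the titrated ligand is not in large excess over the
  labeled protein (protein 0.17 uM vs KD in the tens of uM reduces it to
  the familiar hyperbola).
* `msCleavage()` computes the cleavage fraction `A/(A+B)` from the
  product and parent peak heights and its OLS rate over time;
  `percentInhibition()` is `100 (1 - v/v_ctrl)` with negative values
  reported and flagged rather than clipped.

Confidence intervals default to a seeded nonparametric bootstrap
(percentile, 1000 resamples) with an asymptotic Wald alternative; the
original analyses' software internals are not reproduced. The bootstrap
resamples *relative* residuals (multiplicative errors) whenever the
fitted values are bounded away from zero, because plate-reader noise
scales with signal; under additive resampling the Ki intervals
undercover. CIs are widened minimally, when necessary, to contain the
point estimate.

# Densitometry, bafilomycin additivity, pharmacokinetics

`normalizeBand()` is the two-step normalization (lane / loading control,
then relative to the mean vehicle-control lane); it is invariant to
rescaling a whole blot. `bafAdditivity()` formalizes the flux-block
argument: with saturating bafilomycin A1 clamping lysosomal degradation,
a drug acting at or upstream of the lysosome leaves no further LC3B-II
accumulation for bafilomycin to add. The statistic is
`R = mean(drug+Baf - drug) / mean(vehicle+Baf - vehicle)`; `R ~ 0` reads
as flux blocked, `R ~ 1` as not. The call threshold `R <= 0.25` is an
operational default, clearly labeled configuration — the underlying
biology argues qualitatively, not with a numeric criterion. Replicate
inference is delegated to a generic paired t-test, and `R` gets a
case-resampling bootstrap CI.

`pkSummary()` reports Cmax and Tmax from the observed points and
`AUC(0-t)` by the linear trapezoid only — no log-linear tail and no
extrapolation to infinity, which matches desk-scale scope;
`doseProportionality()` compares dose-normalized AUCs between profiles.
Simulated plasma profiles use the one-compartment first-order oral model
with a molar-mass conversion (default 425 g/mol) to report micromolar
concentrations.

# Numerical choices and degenerate inputs

* Thresholds at decision boundaries are inclusive: overlap exactly 0.50
  is dead, form factor exactly at the cutoff is kept, `R` exactly 0.25 is
  a flux block (guarded with a 1e-9 tolerance against floating-point
  dust).
* Component labels are canonical (numbered by first pixel in column-major
  order), so labelings are reproducible across runs.
* Degenerate inputs flag rather than guess: no live cells, no yellow
  puncta, zero nuclei, flat dose-response, nonpositive vehicle increment
  all return `NA` plus a named flag.
* Tie-breaks: Voronoi-contested pixels go to the lower cell label;
  nucleus pixels always belong to their own cell.
* All randomness is seeded; generators restore the caller's RNG state.

# Problem sizes used by the test suite

The shipped tests run the image-oracle suite on 50 randomized images up
to 64 x 64, ground-truth recovery on 20 high-content fields and 30
tandem fields of 50 cells each, 100 simulated grids per inhibition mode,
and 200-seed precision/coverage studies for IC50 and Ki (bootstrap with
200 resamples in the coverage study). These sizes were chosen to give
stable acceptance statistics at interactive runtimes.

# Known limitations

* Disc-based morphology; no PSF or 3D optics, no bleed-through, no
  cell-to-cell heterogeneity beyond a lognormal brightness factor.
* Band quantification from gel images is out of scope; densitometry
  starts from numeric band intensities.
* The flux-block threshold and the GFP-positivity defaults are declared
  substitutes for undisclosed instrument-software internals, not
  reconstructions of them.
* PK is strictly noncompartmental over the sampled window; saturation
  (sub-proportional exposure at high doses) is not modeled.
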