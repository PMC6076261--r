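# punctaflux

Quantification pipeline for the readouts of an autophagy (ATG4B
inhibitor) drug-discovery campaign, for bench scientists and analysts who
need the computations behind the figures to be reusable and testable:

* **High-content GFP-LC3 puncta scoring** — nuclei segmentation,
  radius-limited cell borders, live/dead classification by viability-stain
  overlap (dead iff overlap >= 50%, inclusive), punctum detection with the
  form-factor filter `FF = 4*pi*A/P^2 >= 0.4` (edge-count perimeter
  convention, area >= 1 px), and the fraction of live cells with >= 5
  puncta, optionally normalized to vehicle controls.
* **Tandem mRFP-eGFP-LC3 flux** — Gaussian filter + adaptive threshold +
  connected components per channel; a red punctum is *yellow*
  (autophagosome) if a single green punctum covers >= 50% of its area,
  else *red-only* (autolysosome); per-cell and pooled red:yellow ratios,
  plus a Lysotracker mean-intensity-per-nucleus metric.
* **Enzymology** — standard-curve RFU-to-molar conversion, initial rates
  with a 10%-consumption window, 4PL IC50, Michaelis-Menten `Vmax`/`KM`,
  trend-based inhibition-mode diagnosis, global uncompetitive fit
  `v = Vmax S / (KM + S (1 + I/Ki))` for `Ki`, the mass-spec cleavage
  fraction `A/(A+B)`, percent inhibition, and the depletion-corrected
  1:1 binding `KD`. Seeded bootstrap or Wald confidence intervals.
* **Densitometry & PK** — loading-control + vehicle normalization, the
  bafilomycin-additivity ratio
  `R = mean(drug+Baf - drug) / mean(vehicle+Baf - vehicle)` with a
  flux-block call at `R <= 0.25`, and noncompartmental `Cmax`/`Tmax`/
  trapezoid `AUC(0-t)` with dose-proportionality ratios.
* **Synthetic-data generators** — seeded, ground-truthed simulations of
  every input (microscopy fields with nuclei/viability/GFP or red/green
  channels; assay tables from the closed-form models), so the whole
  pipeline is auditable against known answers.

The methods vignette (`vignettes/punctaflux-methods.Rmd`) documents the
models, conventions (pixel connectivity, perimeter definition, threshold
inclusivity), defaults, and limitations.

## Worked example

Simulate a high-content field, run the full scoring pipeline, then fit a
simulated substrate-by-inhibitor rate grid globally:

```r
library(punctaflux)

sim <- genHcsField(fieldSpec(seed = 7L))   # 50 cells, ground-truthed
res <- analyzeHcsField(sim$field, hcsConfig(cellRadius = 14))
res$summary
#> FieldSummary: 50 cells ( 44 live / 6 dead )
#>   frac live cells with >= 5 puncta: 0.3182

g <- defaultKineticGrid()                  # [S] 10-124.4 uM, [I] 0-54 uM
sp <- assaySpec("michaelis_menten_uncompetitive",
                params = list(Vmax = 1e-8, KM = 50, Ki = 20),
                design = g, n = 4, noiseCV = 0.05, seed = 7)
tab <- assayData(genAssayTable(sp))
tab <- tab[!tab$is_truth, ]
fit <- fitUncompetitiveKi(tab, ciMethod = "bootstrap", nboot = 500,
                          seed = 7)
fit
#> FitResult [uncompetitive_ki]
#>   Vmax     9.98627e-09  [9.47123e-09, 1.05471e-08]
#>   KM       49.3561  [45.4161, 54.2428]
#>   Ki       20.8044  [18.9416, 22.8488]

diagnoseInhibitionMode(fitApparentKinetics(tab))$mode
#> [1] "uncompetitive"
```

The field summary says 6 of 50 simulated cells were classified dead (the
generator planted a 20% dead fraction) and 31.8% of live cells carry at
least five puncta. The kinetic fit recovers the generating parameters
(`Ki` true value 20 uM inside the bootstrap 95% CI), and both apparent
constants fall together (~-65% over the inhibitor range) — the
uncompetitive signature.

A thin command-line launcher wraps the same functions
(`system.file("cli", "punctaflux.R", package = "punctaflux")`) with
subcommands `simulate hcs|tandem|assay`, `hcs`, `flux`, `ltr`,
`enzyme ic50|mm|ki|mode|ms|mst`, `densitometry`, and `pk`; every
subcommand is deterministic for a fixed seed and config.

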