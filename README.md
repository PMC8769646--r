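# phagolapse

Quantitative analysis of **phagosome maturation** in multi-channel
time-lapse fluorescence microscopy, with a built-in synthetic-data
generator that simulates the underlying vesicle kinetics, membrane
topology, and pH-dependent fluorophore photophysics.

The package targets the assays used to study apoptotic-cell clearance in
*C. elegans* embryos, where autophagosomes — double-membrane vesicles
carrying the LC3-family reporters LGG-1/LGG-2 on both membranes — are
recruited to phagosomes and fuse with them.  Because fusion of a
double-membrane vesicle releases its reporter-coated inner membrane into
the phagosomal lumen, while a single-membrane (LAP-like) vesicle leaves all
reporter on the phagosomal surface, the time course of *luminal* reporter
signal discriminates the two topologies.  The pH sensitivity of the
reporters (GFP pKa 6.0, mNeonGreen 5.1, mCherry 4.5, modeled as
single-site titration `f(pH) = floor + (1−floor)/(1+10^(pKa−pH))`)
makes a GFP/mCherry ratio a luminal pH probe.

## Measurements

For every annotated phagosome (center track, two surface polygons, and a
background box) the package computes, per frame `Tn` normalized to the
sealing frame `T0`:

* **Luminal relative intensity** —
  `RInt(Tn) = (Int_center − Int_bg)_Tn / (Int_center − Int_bg)_T0`,
  4×4 px boxes; detects reporter entry into the lumen.
* **Surface relative intensity** — donut unit intensity
  `UI = (Int_outer − Int_inner)/(Area_outer − Area_inner)` minus unit
  background, normalized at T0; detects recruitment to the surface.
* **Acidification index** —
  `A_idx(Tn) = (Int_GFP/Int_mCherry)_Tn / (Int_GFP/Int_mCherry)_T0`,
  3×3 px box, no background subtraction.
* **Nuclear diameter ratio** — FWHM diameter of the engulfed-corpse
  nuclear disc, normalized at T0 (chromatin degradation assay).
* **Event times** — engulfment duration, phagosome lifespan (first
  half-diameter crossing), fusion onset (first sustained luminal signal),
  all with right-censoring ("no fusion").
* **Puncta colocalization** — LoG blob detection, maximum-cardinality
  nearest-neighbour matching, and the single/double-positive percentage
  formulas.

The simulator (`simulate_scene()` + `render_stack()`) provides exact
ground truth — label pools, pH, geometry, punctum states per frame — so
every measurement is validated against latent truth and brute-force
oracles; genotype presets (`wild_type`, `ced1_like`, `rab7_like`,
`atg7_like`, `cup5_like`, `single_membrane_control`) encode the classical
mutant phenotypes.

## Worked example

```r
library(phagolapse)

scene <- simulate_scene(preset_genotype("wild_type"), seed = 1)
stack <- render_stack(scene, optics = optics_noise_free(), seed = 1)
ann   <- annotation_from_scene(scene)

lum <- luminal_relative_intensity(stack, "mCherry::LGG", ann)
fusion_onset(lum)
#> <event_result> fusion_onset: 18 min

phagosome_lifespan(scene_diameter_timecourse(scene))
#> <event_result> lifespan: 48 min

aidx <- acidification_index(stack, "HIS::GFP", "HIS::mCherry", ann)
round(tail(aidx$value, 1), 3)
#> [1] 0.366
```

For this seed the luminal mCherry signal first rises 1.5-fold in a
sustained way at 18 min (the wild-type median over 50 seeds is 16 min,
within the 12–20 min band reported in vivo), the phagosome shrinks to half
its diameter at 48 min (reported band 40–60 min), and the acidification
index falls from 1 to ~0.37 by 60 min as the lumen acidifies from pH 7.2
toward 5.0.  A fusion-defective (`rab7_like`) run instead yields a
censored "no fusion" event out to 90 min with an unchanged lumen, and a
`single_membrane_control` run keeps luminal RInt within [0.94, 1] while the
surface signal still rises several-fold.

The end-to-end pipeline writes stacks (TIFF + JSON metadata sidecar),
ground truth, per-phagosome time-course CSVs, an events CSV, plots, a log,
and the resolved configuration:

```r
run_pipeline(run_config(preset = "wild_type", n_phagosomes = 3, seed = 1),
             out_dir = "runs/wt")
```

or from a shell via the thin CLI in `inst/exec/phagolapse`
(`simulate`, `quantify`, `events`, `coloc`, `run` subcommands).

See the methods vignette (`vignettes/phagolapse-methods.Rmd`) for the
generative model, the calibration of the presets, and every numerical
design choice.

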