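---
title: "Models and measurement methods in phagolapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement methods in phagolapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagolapse)
```

## The biological setting

When a cell in a *C. elegans* embryo dies by apoptosis, a neighbouring cell
engulfs the corpse into a phagosome.  The phagosome then matures: vesicles of
the autophagy pathway (autophagosomes, carrying the LC3-family reporters
LGG-1/LGG-2 on both of their membranes) and lysosomes are recruited to its
surface and fuse with it, the lumen acidifies, and the corpse — including its
condensed nucleus — is degraded until the phagosome has shrunk away.  Live
imaging of this process uses a small set of quantitative readouts:

* **Luminal relative intensity (RInt)** — background-subtracted intensity of
  a fixed 4×4 px box at the phagosome center, normalized to the moment of
  sealing (T0).  A rising luminal mCherry::LGG signal is the fingerprint of
  *double-membrane* vesicle fusion: fusion of a double-membrane vesicle
  releases its reporter-coated inner membrane into the lumen, whereas fusion
  of a single-membrane (LC3-associated-phagocytosis-like) vesicle leaves all
  reporter on the phagosomal membrane.
* **Surface relative intensity** — the "donut" measure: the unit intensity
  of the annulus between two polygons drawn around the rim,
  `UI = (Int_outer − Int_inner) / (Area_outer − Area_inner)`, background-
  corrected per unit area and normalized at T0.  It reports recruitment
  (docking) independently of fusion.
* **Acidification index (A_idx)** — the GFP/mCherry intensity ratio of a
  dual-tagged nuclear histone reporter in a 3×3 px center box, normalized at
  T0.  GFP (pKa 6.0) is quenched as the lumen acidifies while mCherry
  (pKa 4.5) is not, so the index falls from 1 toward the emission-ratio
  floor.  Following the printed definition the index uses **no background
  subtraction**; it is therefore scale-invariant but *not* offset-invariant
  (a background-corrected variant is available behind a flag).
* **Event times** — engulfment duration (pseudopod budding to sealing),
  phagosome lifespan (sealing until the diameter first falls to half its
  initial value), and fusion onset (first sustained luminal signal), with
  right-censoring ("no fusion") when the event is not observed within the
  recording.
* **Puncta colocalization** — percentages of single- and double-labeled
  puncta among detected spots in two channels.

Real recordings of this process are not deposited with desk-scale tooling,
so the package pairs every measurement with a **synthetic-data generator**
whose latent state is known exactly; the generator is first-class, tested
code and arbitrates the correctness of every measurement.

## The generative model

`simulate_scene()` evolves one phagosome per run on the recording grid
(default 2-min frames, 60-min span — the sampling of the time-lapse
protocol; 3-min frames are used for acidification runs, matching the
published curves).

**Vesicle kinetics.** Puncta are born in the cytosol as a homogeneous
Poisson process (`puncta_birth_rate`), dock onto the rim with per-punctum
rate `k_recruit`, and fuse with per-docked-punctum rate `k_fuse`.  Time is
discretized per frame: each transition fires with probability
`1 − exp(−k·Δt)`, events resolved birth → dock → fuse within a frame.  On
fusion of a double-membrane vesicle half of `label_per_vesicle` enters the
luminal pool and half joins the rim pool (both leaflets carry reporter,
symmetrically); a single-membrane vesicle gives its whole label to the rim.
Label bookkeeping is exact: at every frame, label ever born equals label
held by puncta plus the rim and lumen pools — this conservation law is a
test invariant.  A fused punctum remains listed (state `"fused"`, zero
label) for its fusion frame and is dropped afterwards.

**Deterministic trajectories.** Lumen pH relaxes exponentially from
`pH_initial` 7.2 to `pH_final` (default 5.0) with time constant `pH_tau`;
the phagosome radius is constant until `shrink_onset`, then halves every
`shrink_halftime`; the corpse-nucleus disc halves every
`nucleus_decay_halftime` from sealing.  `Inf` switches any of these off.

**Photophysics.** Emission follows a single-site Henderson–Hasselbalch
titration, `f(pH) = floor + (1 − floor)/(1 + 10^(pKa − pH))` — the standard
model for fluorescent-protein pH sensitivity, chosen because it is
analytically checkable (half-emission exactly at the pKa).  mCherry's
reported "pKa < 4.5" is implemented as pKa = 4.5, the conservative worst
case.  Luminal and nuclear label emit at the lumen pH; rim label, docked
and cytosolic puncta emit at a fixed cytosolic pH of 7.2.

**Rendering.** Each label unit contributes
`brightness × emission_fraction` expected photons.  The luminal pool is
spread uniformly over the phagosome disc, the rim pool over a 2-px annulus,
the nuclear pool over the nucleus disc, and puncta are deposited at their
sub-pixel positions (bilinear, flux-conserving).  The expected image is
convolved with an isotropic Gaussian PSF (`psf_sigma` 1.5 px at 0.1 µm/px —
a realistic widefield scale) using a flux-conserving circular-boundary
convolution, then corrupted by Poisson shot noise, Gaussian read noise
(sd 3), and a constant camera offset (20 counts) added *after* the noise
(an electronic offset carries no shot noise), clamped at zero and digitized
to integer camera units.  In noise-free mode nothing is randomized or
rounded, the render is a pure function of the scene, and pixel sums match
analytic expectations to better than 1e-6 — a test invariant.

## Calibration: the study conditions

The generator's defaults are fixed once, to reproduce the headline numbers
of the in vivo assays, and are not tuned per experiment:

| parameter | default | rationale |
|---|---|---|
| `puncta_birth_rate` | 0.5 /min | with the two rates below, ~25 fusions by 60 min: luminal RInt reaches several-fold, near the reported ~9–10-fold |
| `k_recruit` | 0.25 /min | docking within minutes, as observed for surface puncta |
| `k_fuse` | 0.12 /min | median fusion onset lands in the reported 12–20 min band |
| `label_per_vesicle` / `lumen_baseline_label` | 20 / 40 | onset threshold 1.5× corresponds to two fusions; the absolute scale keeps the T0 anchor well above the shot/read-noise floor (a real phagosome center carries substantial diffuse and out-of-focus reporter at sealing) |
| `rim_baseline_label` | 60 | positive surface anchor at T0 |
| `shrink_onset` + `shrink_halftime` | 30 + 18 min | half-diameter (lifespan) at 48 min, inside the reported 40–60 min band |
| `pH_initial → pH_final`, `pH_tau` | 7.2 → 5.0, 50 min | wild-type A_idx ≈ 0.44 at 51 min (reported average 0.443) |
| `nucleus_label` | 150 units | the unsubtracted A_idx tracks the emission ratio only if nuclear signal dominates the camera offset (~3200 photons per 3×3 box vs ~180 offset) |
| `nucleus_decay_halftime` | 60 min | nuclear diameter halves by 60 min in wild type |

Genotype presets map mutant phenotypes onto these parameters: `ced1_like`
(recruitment-defective) sets `k_recruit = 0` — exactly zero, since the
phenotype is a flat surface signal; `rab7_like` (fusion-defective) sets
`k_fuse = 0` with a 90-min recording so "no fusion" censoring is exercised;
`atg7_like` (biogenesis-defective) sets the birth rate to 0.002/min
("hardly any" puncta), pH_final 5.7 (A_idx ≈ 0.69 at 51 min, reported
0.679) and nuclear halftime 100 min (~66% diameter at 60 min, reported
66%); `cup5_like` (acidification-defective) keeps pH flat and nearly stops
nuclear decay (halftime 360 min ⇒ ~89% diameter at 60 min, reported 89%).
Degradation is off in the recruitment/fusion-defective presets, consistent
with their persisting-corpse phenotypes.

**The topology assay runs with degradation off in both arms.**  Shrinkage
concentrates *any* luminal label — including the diffuse baseline — into a
smaller disc, so the center-box intensity of even a fusion-less phagosome
rises geometrically once shrinkage starts.  Comparing double- versus
single-membrane topology therefore uses matched seeds with
`shrink_onset = Inf`, isolating membrane topology as the only difference;
`single_membrane_control` carries this in its preset.  The same reasoning
applies to the `k_fuse` recovery assay, which additionally keeps pH flat so
mCherry quenching does not deflate the measured accumulation curve.

**Cytosolic exclusion zone.**  Newborn puncta are placed outside an annulus
covering the rim, the measurement donut, and the PSF support, so that
un-recruited vesicles never contaminate the surface or background ROIs.
The in vivo measurements face the same hazard and resolve it by drawing
the donut tightly around the rim by hand; the simulator resolves it in the
geometry.

## Numerical and design choices

* **Coordinates** are 1-based `(row, col) = (y, x)` with pixel centers at
  integer positions — the R/EBImage convention.  Even-sided measurement
  boxes (the 4×4 luminal box) center on the upper-left pixel of the central
  2×2 block; this is deterministic and documented rather than interpolated.
* **Polygon rasterization** uses the even-odd crossing rule evaluated at
  pixel centers; *area is the rasterized pixel count*, matching how
  intensity is summed (not the continuous shoelace area).  Both sums are
  verified against independent per-pixel loop oracles.
* **FWHM diameters** threshold at local background plus half the
  peak-above-background, with linear interpolation at the crossings, and
  average the horizontal and vertical chords through the peak.  On discs a
  few pixels across, PSF blur and boundary curvature bias the estimate low
  by up to ~1 px; the T0-normalized diameter *ratio* cancels most of this
  bias, which is why the degradation assay reports ratios.
* **Fusion onset** operationalizes the visual "obvious signal entry" call
  as RInt ≥ 1.5 sustained for 2 consecutive frames (both config-exposed).
  With the default label scale the threshold corresponds to the second
  fusion event, so noise-free wild-type scenes trigger within a frame or
  two of first fusion.  Lifespan uses the first crossing at frame
  resolution, without interpolation, matching the 2-min sampling.
* **Puncta detection** is multi-scale Laplacian-of-Gaussian filtering
  (zero-mean kernels, so flat background gives zero response), local maxima
  over space and scale, and greedy non-maximum suppression.  The default
  response threshold (50) sits far below a one-vesicle punctum (~350) and
  far above the luminal disc-edge response (~15).
* **Puncta matching** seeds with greedy nearest-neighbour matching under
  the distance cap (ties by distance, then lower (y, x)) and refines with
  augmenting paths to guaranteed maximum cardinality: pure greedy can
  strand a matchable pair when one spot sits between two partners, even
  with within-channel separation enforced.  The result equals exhaustive
  optimal bipartite matching, which the tests verify on all instances with
  ≤ 8 spots per channel.
* **The `k_fuse` inverse fit** compares the measured mean luminal curve
  (converted to label units through the known baseline) with the *exact
  discrete-time expectation* of the birth→dock→fuse chain — a three-state
  linear recursion — rather than the continuous-time convolution integral,
  which carries an O(Δt) bias at 2-min frames.
* **Seeding**: one master seed; scene and renderer sub-streams are derived
  deterministically (all below 2³¹), and every simulation restores the
  caller's RNG state.  `(params, seed) → scene` and
  `(scene, optics, seed) → stack` are pure functions; a noise-free pipeline
  run is byte-identical across executions.
* **File formats**: stacks are multi-page TIFF in TCYX page order with a
  JSON sidecar carrying pixel size, frame interval, channel names, and
  storage scale (the installed TIFF writer cannot embed description tags).
  Integer stacks (including all noisy renders, which are digitized camera
  units) round-trip exactly at 16 bit; other data round-trip at 32-bit
  float precision, recorded in the sidecar.  Ground truth travels as a JSON
  sidecar with one object per frame; configurations round-trip through
  YAML or JSON.

## Problem sizes

The validation suite uses 128×128 px single-plane scenes, 31–46 frames,
with 30-seed cohorts for the topology and mutant-matrix checks, 50 seeds
for the wild-type calibration (median onset, lifespan band) and noise
robustness, 100 random images for the oracle-equivalence checks, and
3 × 30 seeds for the rate-recovery study.  These sizes give stable medians
and tight Monte Carlo error for every property tested while remaining
single-CPU friendly.

## What the simulator does and does not emulate

It emulates: the 2-min cadence and 0-min sealing anchor of the recordings;
disc-shaped phagosome with rim, lumen, and an internal shrinking nucleus;
stochastic punctum birth/docking/fusion with membrane-topology-dependent
label routing; pH-dependent quenching of multi-channel reporters; PSF blur,
shot noise, read noise, offset, and digitization; phagosome shrinkage and
nuclear decay; mutant phenotypes as kinetic presets.

It does **not** emulate: 3-D optics or the 12–16-section Z-stacks of the
original recordings (single optical sections stand in; whether the in vivo
intensities were measured on sections or projections is not recoverable,
and only relative quantities are meaningful here); pseudopod membrane
mechanics during engulfment (engulfment duration is carried as annotation);
photobleaching; punctum motility (cytosolic puncta are static between birth
and docking); multi-cell or embryo-scale scenes; phagosome tracking or
segmentation (center tracks and polygons come from ground truth or user
annotations).  Passing tests therefore demonstrate the correctness of the
measurement pipeline on data whose generative assumptions are known, not
the biological fidelity of any particular parameter value.

## A worked example

```{r example, eval = FALSE}
scene <- simulate_scene(preset_genotype("wild_type"), seed = 1)
stack <- render_stack(scene, optics = optics_noise_free(), seed = 1)
ann <- annotation_from_scene(scene)

lum <- luminal_relative_intensity(stack, "mCherry::LGG", ann)
fusion_onset(lum)                     # 18 min for this seed
phagosome_lifespan(scene_diameter_timecourse(scene))  # 48 min

aidx <- acidification_index(stack, "HIS::GFP", "HIS::mCherry", ann)
tail(aidx$value, 1)                   # ~0.37 at 60 min
```

The full pipeline — simulate, render, write, measure, extract events,
plot — runs through `run_pipeline(run_config(...), out_dir)` or the
`phagolapse` command-line script in `inst/exec/`.
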