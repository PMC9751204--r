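# vesiquant

Single-vesicle intensity and colocalization analysis for two-channel TIRF
microscopy image stacks — a scriptable implementation of the
vesicle-population assay used to detect and quantify **fusion**,
**fission**, and **lipid exchange** between surface-tethered lipid
vesicles labeled with two different fluorescent dyes.

Sub-resolution vesicles appear as diffraction-limited spots whose
brightness tracks membrane area. The package detects those spots, measures
background-normalized intensities, matches vesicles across the two
wavelength channels, and summarizes the population so that remodeling
events can be read off three observables:

| event | colocalization | N (count) | ⟨I⟩ per vesicle |
|---|---|---|---|
| fusion | ↑ | ↓ | ≥ control |
| lipid exchange | ↑ | unchanged | ↓ |
| fission | unchanged | ↑ | ↓ |

## Method core

Per channel grid *I(r, c)* of camera counts:

* background *BG* per column by a rolling ball of radius *r*:
  1-D grayscale opening with the semicircular element
  sqrt(r² − (k·dx)²), then 3×3 median, subtraction, Gaussian filter;
* pixel-specific threshold `I_th,pos = SFR · 2(I_median − I_min)` from
  per-column median/minimum statistics of the corrected image;
* spots = 8-connected components above threshold, each enlarged by a 5×5
  window; spot size σ = enlarged pixel count;
* `I_int = Σ I_pixel` over the enlarged mask; background model
  `I_BG(σ) = a0 + a1·σ` fitted to 100 vesicle-free pseudo-spots of
  10–100 px;
* normalized intensities `I_tot = (I_int − I_BG(σ)) / I_BG(σ)` and
  `I_peak = (I_max − I_BG(1)) / I_BG(1)`;
* colocalization either by centroid position (disc of radius ρ,
  one-to-one greedy matching) or by transferred-mask intensity
  (`I_int − I_BG(σ) ≥ SFR·I_BG(σ)` on the other channel's grid), with
  integer-pixel drift correction from the cross-correlation peak of the
  two channels;
* population metrics: Weibull fits of the intensity distributions (mode
  λ((k−1)/k)^(1/k)), ΔN, Δ⟨I_int⟩, total signal N×⟨I_int⟩,
  lipid exchange % = 100·⟨I_tot⟩_masked / ⟨I_tot⟩_detected, and a
  pooled-variance two-sample t-test for group comparisons.

A synthetic-scene generator (`generate_scene()`) renders two-channel
frames with known ground truth — Weibull-distributed emitter fluxes,
integrated-Gaussian PSF, Gaussian illumination field, Poisson noise,
integer channel offset — so the entire pipeline is validated end to end
without microscope data. See `vignettes/vesiquant-methods.Rmd` for the
model, parameter rationale, and the limits of what the simulator
establishes.

## Worked example

Simulate a mixed sample in which 50% of each channel's vesicles carry both
dyes (dual-label fraction 1/3 of all vesicles), write it as a dual-view
TIFF, and analyze it:

```r
library(vesiquant)
p  <- scene_params(frac_colocalized = 1/3, frac_blue_only = 1/3, seed = 42)
sc <- generate_scene(p)
write_scene(sc, "scene42.tif", "truth42.csv")
rep <- analyze_run(run_config(input = "scene42.tif", seed = 42, label = "mix50"))
print(rep)
```

```
<vq_run_report> mix50: 1 frame(s), 0 error(s)
<vq_popsummary> channel blue: N = 138.0 spots/image (138 spots, 1 images)
  <I_int> = 3.2e+03 +/- 1.12e+03, <I_tot> = 6.82 +/- 1.92
  Weibull(I_tot): k = 3.97, lambda = 7.54, mode = 7
<vq_popsummary> channel red: N = 134.0 spots/image (134 spots, 1 images)
  <I_int> = 3.5e+03 +/- 1.57e+03, <I_tot> = 7.41 +/- 2.55
  Weibull(I_tot): k = 3.16, lambda = 8.29, mode = 7.35
  position colocalization: 54.4%
  intensity colocalization: 57.0%
```

Reading the output: 138 and 134 spots were detected out of 139 emitters
per channel placed by the simulator; the (2, 1) px inter-channel offset
was recovered automatically and both colocalization methods report
fractions near the 50% per-channel ground truth (this seed's binomial
draw is 78/139 = 56% dual-labeled, so the measured 54–57% sits right on
it — see the vignette for the error budget of each method). `I_tot` is the
spot intensity in units of the expected background of an equally sized
empty region.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/vesiquant.R simulate --config scene.json --out scene.tif \
    --truth truth.csv --seed 5
Rscript inst/cli/vesiquant.R analyze --config run.json --drift auto \
    --coloc-method both [--preview]
```

Per-frame spot tables and pair lists are written as CSV, the run report
and log as JSON, and a detection/colocalization overlay (colocalized pairs
ringed in white) as PNG.

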