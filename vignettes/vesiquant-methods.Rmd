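---
title: "vesiquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vesiquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Small unilamellar vesicles (~50 nm) are far below the diffraction limit, so
in a fluorescence microscope each vesicle is a point-spread-function-shaped
spot whose brightness, not size, carries the information. When two vesicle
populations carrying different dyes (a "blue" AF488-type and a "red"
Cy5-type label) are mixed, incubated with a membrane-active agent, diluted
to single-vesicle surface density and imaged in two wavelength channels,
three kinds of remodeling events leave distinct population signatures:

* **fusion** — vesicles colocalize across channels, the count N drops, and
  per-vesicle intensity stays or rises;
* **lipid exchange** — vesicles colocalize, N is unchanged, per-vesicle
  intensity drops in each channel;
* **fission** — no change in colocalization, N rises, per-vesicle intensity
  drops.

vesiquant implements the full quantification chain for such two-channel
(dual-view splitter) image stacks: spot detection, background-normalized
intensity measurement, cross-channel colocalization with drift correction,
and the population metrics (ΔN, Δ⟨I_int⟩, N×⟨I_int⟩, colocalization %,
lipid-exchange %) that feed the signature table above
(`classify_event()`).

## Detection chain

Per channel grid (a matrix of camera counts, 0-based coordinates in all
exported tables):

1. **Low-pass filter** (Gaussian, `lowpass_sigma = 1` px).
2. **Rolling-ball background**: for every image *column*, a 1-D grayscale
   opening with a semicircular structuring element of radius
   `ball_radius = 25` px (height sqrt(r² − (k·dx)²) at offset k, sampled at
   `dx = 1` px). An opening is exactly the envelope of all positions of a
   ball rolled beneath the intensity profile: it tracks the slow Gaussian
   illumination gradient of the excitation laser along the column but
   cannot enter a diffraction-limited peak. The column-wise baselines are
   assembled and smoothed with a 3×3 median filter before subtraction
   (clipped at zero), followed by a final Gaussian filter
   (`post_gauss_sigma = 1` px).
3. **Pixel-specific threshold**: the fluctuation level of a pixel is
   2·(median − minimum) of its column of the corrected image (two row
   vectors of column statistics broadcast down the columns), and the
   detection threshold is SFR × fluctuation. The per-column statistic makes
   the threshold follow any residual unevenness across the field. We read
   the row-vector statistics as *column-wise* median/min because the
   background pass operates along the same axis and because that is the
   orientation in which the illumination profile survives; this indexing
   is stated explicitly for anyone comparing against other
   implementations.
4. **Spots**: 8-connected components of the above-threshold mask with at
   least `min_core_px = 2` pixels; centroid = intensity-weighted mean of
   core pixels. Border-touching spots are kept but flagged, since their
   clipped area biases the normalized intensity.
5. **5×5 enlargement**: every core is dilated with a 5×5 square (2 px in
   all directions) so that sub-threshold spot edges contribute to the
   integral; the enlarged pixel count is the spot size σ.
6. **Intensities**: I_int = Σ intensities over the enlarged mask,
   I_max = core maximum, both on the corrected grid the threshold was
   applied to.
7. **Background model**: 100 pseudo-spots of 10–100 px are placed in
   vesicle-free area (outside all enlarged masks plus a 2-px guard band)
   and integrated; ordinary least squares gives I_BG(σ) = a0 + a1·σ. A
   negative fitted intercept is unphysical (a zero-size region collects no
   background) and within sampling noise of zero, so the line is then
   refitted through the origin; this keeps the extrapolation to σ = 1
   (needed for I_peak) positive and stable.
8. **Normalization**: I_tot = (I_int − I_BG(σ))/I_BG(σ) and
   I_peak = (I_max − I_BG(1))/I_BG(1).

### Which grid is integrated

Whether the original interactive program integrates the raw or the
background-subtracted image is not decidable from its description; we
integrate the corrected grid, which keeps the normalization consistent
with the background model fitted on the same grid. The consequence, worth
knowing when comparing absolute numbers: on nearly noise-free data the
corrected grid's background is only the clipped noise pedestal, so I_tot
values are much larger than when the raw background is retained in the
denominator. All relative quantities (ΔN, ΔI, colocalized fractions,
lipid-exchange percentages — which are ratios of I_tot means measured the
same way) are unaffected by this choice.

A corollary: a "noise-free" scene is degenerate under this design — with
the background perfectly removed, both the fluctuation threshold and
I_BG(σ) collapse to zero. Linearity of I_tot against true emitter flux is
therefore validated on low-noise (not zero-noise), flat-illumination
scenes, where the linear fit reaches R² > 0.99.

### The SFR operating point

The SFR is the method's single sensitivity knob, reviewed interactively on
the first image of a batch in the original workflow and then frozen. On
the simulator's shot-noise-limited defaults, SFR = 2 admits smoothed noise
clusters (they sit exactly at twice the fluctuation level), while SFR 3–4
is a wide plateau with 96% recall and 1.4% false detections, insensitive
to the exact value; the package default is `sfr = 3`. For data with more
structured background the appropriate SFR will differ — that is the
parameter a user is expected to review (`analyze --preview`).

## Colocalization

* **Position-detected**: after aligning the red channel, a blue and a red
  spot whose centroids lie within `coloc_radius = 2` px (a disc — one
  isotropic parameter) are candidates; candidates are matched one-to-one
  greedily by ascending distance with ties broken by blue id. Greedy
  matching is deterministic and auditable; on generic data it attains the
  exhaustive maximum-cardinality matching (verified against brute force on
  small instances).
* **Intensity-detected**: each spot's enlarged mask is transferred onto the
  other channel's grid and integrated; the vesicle counts as colocalized
  when the transferred integral exceeds its expected background by
  SFR × I_BG(σ), i.e. transferred I_tot ≥ SFR (`coloc_sfr = 2`). The test
  runs symmetrically (blue masks on red, red masks on blue) and fractions
  are reported per channel.
* **Drift**: the integer inter-channel offset (chromatic + alignment) is
  the argmax of the normalized cross-correlation of the two corrected
  grids over shifts in [−10, 10]², ties broken by the smaller shift. The
  correlation peak only exists when the channels share colocalized
  vesicles; when the measured colocalization comes out below 10% the
  automatic estimate is discarded and the frame re-analyzed uncorrected —
  for genuinely uncolocalized samples a fixed offset from a reference
  sample (`drift = "fixed:drow,dcol"`) is the supported route.
  Cross-correlating binary masks instead of grids is available
  (`estimate_drift(use = "masks")`) and behaves near-identically.

The two methods fail differently: position matching is strict and misses
small/defocused partners (measured-vs-true slope ~0.9 on simulated
series), intensity transfer is more sensitive but picks up "false"
partners from any red signal leaking into a blue mask (~an order of
magnitude more false colocalization on 0% samples, a few percent at ~200
vesicles per 1024×512 channel). Hence the operating rule: position
detection for low-colocalization samples, intensity detection when
colocalization is substantial.

## Population metrics

`summarize_population()` reports N (mean spots/image), means ± SD of
I_int/I_tot/I_peak, and two-parameter Weibull fits. Small-vesicle
fluorescence scales roughly linearly with membrane area, which makes the
peaked, right-skewed Weibull a good intensity model; the fit is by profile
maximum likelihood with location fixed at 0 (the histogram-vs-MLE choice
is not decidable from the original description; MLE is standard and its
parameter recovery is testable — bias ~0.3% at n = 10⁴). The "population
maximum" is the fitted mode λ((k−1)/k)^(1/k) for k > 1.

Lipid exchange is quantified as 100 × ⟨I_tot⟩(transferred masks) /
⟨I_tot⟩(detected vesicles) per channel; group comparisons use the
pooled-variance two-sample t-test (two groups that are both constant give
p = 1 when equal, 0 otherwise, by convention). `change_metrics()` computes
ΔN, ΔI and the total-signal change from test and control summaries, and
`classify_event()` applies the signature table with explicit "unchanged"
thresholds (defaults 15% for ΔN and ΔI, 5 points for colocalization) —
the original classifies by inspection, so cut-offs must be user-visible
configuration. Vesicles falling below the detection limit are *reported*
through the total-signal change, not corrected for.

## The synthetic world

`generate_scene()` states the emulated experiment once; its defaults are
the package's validation world and are deliberately not tunable per test:

| parameter | default | rationale |
|---|---|---|
| image shape | 1024×512 /channel | a 2048×2048 sCMOS frame, 2×2 binned, split left/right |
| n_vesicles | 200 | the surface density at ~25 nM lipid (just below 200/image) |
| flux/vesicle | Weibull(k = 3, λ = 4000) counts | ~36% CV, the area spread of sonicated ~50 nm vesicles |
| PSF sigma | 0.8 px | diffraction-limited optics at 217 nm/px after binning |
| background | 100 counts/px, Poisson | shot-noise-limited camera regime |
| illumination | Gaussian, width 512 px | excitation beam wider than the field; ~2× fall-off at corners |
| min separation | 6 px | single-vesicle dilution; overlaps are rare but not absent |
| channel offset | (2, 1) px integer | dual-view chromatic/alignment drift; sub-pixel shift out of scope |

The nominal `scene_snr()` (median emitter peak / background noise sd) of
these defaults is ~78; all validation bands are stated for SNR ≥ 10.
Dual-label ("both") vesicles draw their two channel fluxes independently.
When emulating a mixing series with theoretical *per-channel*
colocalization T, the dual-label fraction of all vesicles is T/(2−T)
(balanced single-label populations).

What the simulator does *not* emulate — and what a green test therefore
does not establish: structured background (surface junk, autofluorescent
clumps, residual bulk fluorescence), sub-pixel chromatic shifts and
rotation between channels, camera fixed-pattern noise and read noise,
photobleaching, defocus across the field, and vesicle diffusion during
exposure. The false-colocalization rates of real data are dominated by
exactly these nuisances, so the simulated rates (position « intensity,
both a few percent) reproduce the *ordering and magnitude class* of real
measurements, not their exact values.

## Numerical choices and degenerate inputs

* Rolling-ball columns are opened with the profile treated as +∞ outside
  the image (the standard boundary rule); a constant image therefore
  returns itself as background exactly.
* PSF rendering uses the integrated (pixel-binned) Gaussian on a support
  truncated at ±4σ (< 0.01% flux loss); emitter centers are rejected
  within a margin of the border so that the offset red copy stays inside.
* Rejection sampling of centers aborts with an explicit density message
  after 200·n failed draws.
* Spots whose transferred mask leaves the image entirely yield NA
  transferred intensity and are excluded from fractions.
* `detect_spots` weights centroids by intensity but falls back to the
  unweighted mean if a core integrates to zero.
* Component splitting makes "spot count non-increasing in SFR" false in
  edge cases: the above-threshold mask is nested, but one merged doublet
  can split into two valid components at a higher SFR. The package keeps
  the faithful assertion in its acceptance suite and documents the
  counterexample rather than hiding it.
* The Weibull shape root is bracketed on [0.01, 1000] with overflow-safe
  rescaling of x^k.
* TIFF support is a built-in minimal baseline codec (uncompressed
  grayscale 8/16-bit, multi-page, both byte orders on read, 16-bit
  little-endian on write) because no TIFF-reading R package is assumed at
  run time; interoperability is tested against an independent Python TIFF
  implementation.

## Known limitations

Intensity is never converted to absolute vesicle size (that needs a
single-fluorophore or size-standard calibration); censored (sub-detection)
populations are not refitted; channel alignment is integer-pixel
translation only; time-lapse tracking and FRET-based docking/fusion
discrimination are out of scope.
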