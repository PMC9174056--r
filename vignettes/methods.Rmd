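---
title: "Ratiometric tfLC3 vesicle classification and PANTHOS lesion analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric tfLC3 vesicle classification and PANTHOS lesion analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panthoscope)
```

## The measurement problem

Neurons expressing the tandem mRFP-eGFP-LC3 (tfLC3) reporter carry two
fluorophores on every LC3-positive autophagic vesicle. mRFP emission is
pH-resistant; eGFP emission collapses as the vesicle lumen acidifies, with
its effective midpoint near pH 6. The green/red ratio of a vesicle is
therefore a luminal-pH read-out: a neutral autophagosome (AP) is yellow, a
properly acidified autolysosome (AL) is red, and a cathepsin-positive
autolysosome that has failed to acidify (pa-AL) remains yellow. Adding an
immunofluorescence channel for a lysosomal marker (CTSD/LAMP, rendered
"pseudo-blue") separates the yellow classes: AL becomes purple
(red + blue), pa-AL becomes white (red + green + blue), and a lysosome
without LC3 cargo (LY) is blue only.

`panthoscope` implements this logic as a quantitative pipeline - puncta
detection, hue-angle/saturation conversion, the four-class decision table,
per-neuron statistics, and detection of PANTHOS lesions (degenerating
neurons ringed by autophagic-vacuole-filled membrane blebs with a central
nuclear remnant and perinuclear amyloid) - together with a synthetic
confocal-field generator that emulates the probe's photophysics so every
stage can be validated against known ground truth.

## The photophysics model

eGFP emission fraction follows a Henderson-Hasselbalch (logistic) titration

$$f(\mathrm{pH}) = \frac{1}{1 + 10^{\,h\,(\mathrm{pH}_{1/2} - \mathrm{pH})}}$$

with default midpoint $\mathrm{pH}_{1/2} = 6.0$ and Hill coefficient
$h = 1$. The source literature states only that eGFP is quenched below
pH 6.0; placing the titration midpoint there, with unit cooperativity, is
this package's modelling choice (both are `FluorophoreModel` parameters).
mRFP is modelled as constant emission. A rendered vesicle has green
intensity `lc3_load * f(pH)` and red intensity `lc3_load`, so its
green/red ratio is exactly $f$, strictly increasing in pH.

```{r quench}
egfpQuenchFactor(c(4.8, 6.0, 7.0))
```

## Hue angle and saturation

Each detected punctum is summarized by background-subtracted mean channel
intensities $(R, G, B)$ = (mRFP, eGFP, marker). The hue angle is the
spreadsheet formula used in the original workflow,

$$\mathrm{Hue}^\circ = \operatorname{atan2}\!\big(\sqrt{3}\,(G - B),\; 2R - G - B\big)\cdot\frac{180}{\pi} \bmod 360,$$

where the two-argument arctangent of the spreadsheet convention takes
$(x, y) = (2R - G - B, \sqrt3 (G - B))$. R's `atan2(y, x)` therefore
receives the arguments in swapped order; the primary-color anchors
(red 0, yellow 60, green 120, blue 240) are unit-tested to pin
this convention. Saturation is $(\max - \min)/(\max + \min)\cdot 100$ on
channel intensities normalized to $[0, 1]$ by their 99.9th percentile,
valid while lightness $(\max+\min)/2 < 1$ (reported as `lightness_ok`).

Two deliberate choices depart from a literal three-channel reading:

* **Classification hue uses the tfLC3 pair** $(R, G, 0)$. The decision
  table treats the marker channel as a separate boolean branch (purple =
  red hue + marker, white = yellow hue + marker). Feeding the marker
  intensity into the hue would rotate purple vesicles toward magenta and
  white vesicles off the yellow sector, contradicting the table the colors
  stand for. The exported `hueAngle()` remains the full three-argument
  formula.
* **The minimum-saturation gate uses the same pair.** A "white" pa-AL is
  achromatic in the three-channel triple *by definition*, so the
  full-triple saturation cannot serve as the unclassified gate without
  discarding the very class of interest. With $B = 0$ the gate excludes
  only puncta with no tfLC3 chroma at all; low-level noise puncta are
  instead rejected by the LC3/marker positivity tests.

## The decision table

With `lc3` = punctum exceeds background + 3 MAD in mRFP or eGFP, and
`marker` = same rule on the marker channel:

| lc3 | hue sector          | marker | class        |
|-----|---------------------|--------|--------------|
| yes | red [315, 40)       | any    | AL           |
| yes | yellow [40, 90)     | yes    | pa-AL        |
| yes | yellow [40, 90)     | no     | AP           |
| no  | -                   | yes    | LY           |
| any | other / sat < s_min | -      | unclassified |

Sector boundaries are not published with the original workflow; the
defaults above place the yellow-to-orange-to-red transition inside the red
sector and are exposed in `classificationConfig()`. In two-channel mode
(no marker channel) yellow puncta cannot be split into AP versus pa-AL and
are reported unclassified ("yellow, indeterminate"); requesting
marker-dependent analysis on a two-channel image is an error.

## Puncta detection

Detection is multi-scale Laplacian-of-Gaussian blob detection on the sum of
the detection channels (mRFP + eGFP + marker), followed by cross-scale
non-maximum suppression, a local half-maximum threshold around each seed,
and nearest-seed splitting of contested pixels (the watershed-style step;
ties resolve deterministically by (y, x) order). Puncta outside the
0.2-3 um diameter range are discarded; the lesion module widens the
ceiling to 4 um because PANTHOS pa-ALs exceed the normal vesicle scale.
Background for intensity measurement is the median of an annulus 2-6 px
outside the punctum, excluding pixels claimed by any punctum - local, so
uneven illumination does not bias the ratio. On noise-free rendered fields
the detector finds every vesicle with centroids within one pixel and areas
within the one-pixel-ring discretization bound of $\pi r^2$.

## The synthetic world

The generator's presets *are* the stated experimental conditions; their
parameters are the published summary statistics, not tuning knobs:

* per-neuron class counts: Poisson with means 2.1/6.6 (control) and
  9.0/4.4 (5-month AD model) pa-AL/AL per neuronal cross-section, 17.2
  pa-AL at 12 months; mean sizes 0.48/0.74 and 1.3/1.75 um^2 (log-normal,
  25% CV). "Size" is interpreted as cross-sectional area. AP and LY means
  (2.0 and 4.0) are not printed in the source and are realism choices.
* class pH: AP ~ N(7.0, 0.2) on [6.5, 7.5], pa-AL ~ N(6.6, 0.3) on
  [6.4, 7.5], AL/LY ~ N(4.8, 0.3) on [3.5, 5.8]. A single blanket
  truncation to [3.5, 7.5] would let ~14% of pa-AL draws fall below the
  hue-sector boundary (pH 6.27 maps to hue 40 at the default quench
  parameters), which contradicts the definition of pa-AL - a
  *poorly-acidified* compartment above the quench point - and would make
  100% ground-truth agreement impossible by construction. The per-class
  bounds keep the stated world self-consistent; the chloroquine preset
  deliberately breaks it (ALs shifted above pH 6.4) to model
  de-acidification, and there ground-truth ALs are *expected* to read as
  pa-AL.
* colocalization: the amyloid-antibody preset (`fig3b`) needs two printed
  facts at once - 88.6% of antibody-positive puncta are pa-AL, and 40% of
  neurons contain at least one positive punctum. Poisson thinning gives
  per-vesicle positivity $9.0\,p_{paAL} + 4.4\,p_{AL} = -\ln 0.6$ with the
  pa-AL share 0.886, so $p_{paAL} = 0.0503$, $p_{AL} = 0.0132$. The PLA
  preset fixes the 92.9% pa-AL share; the overall PLA rate is not printed
  and is set to 2 expected positive puncta per neuron.
* PANTHOS cohorts: one stage-iii rosette per 72 um field - 6-8 radially
  arranged blebs (radius 3-4.2 um, necks 2-3.5 um) filled with enlarged
  pa-ALs, a central LC3-free core around the nucleus, a perinuclear
  amyloid corona, and co-label flags drawn at the published rates (DAPI
  detectable 91.4%/67.8%, Thio-S 58.1%/95.2%, GFAP 32.8%/70.7%, IbaI
  35.8%/87.4% for the early/late cohorts). Rosettes are capped at 8 blebs
  so adjacent blebs remain morphologically separable in a 2D section; the
  real lesions carry dozens across the full 3D cell, which a single
  optical section never shows. With probability 0.0905 a field receives an
  isolated extra-lesional plaque of the same integrated intensity as a
  corona, which simultaneously yields the published 91.7%
  plaque-with-lesion fraction and the 91.7% of total amyloid signal
  inside lesions.
* optics: pixel size 0.1 um (0.15 um for the lesion presets, whose
  features are an order of magnitude larger - this keeps 200-lesion
  cohorts within a desktop time budget), Gaussian PSF sigma 0.15-0.2 um,
  Poisson shot noise at 400 photons full scale, Gaussian read noise at 2%
  of full scale. Acquisition bit depth and background of the original
  microscope are not published; defaults are configurable and not claimed
  faithful.

One root seed drives everything; cohorts derive one child seed per field,
so outputs are bit-reproducible (`simulate` twice with the same seed gives
byte-identical TIFFs).

What a green closed-loop test establishes: that the pipeline recovers the
parameters of *this* stated world - non-overlapping disk vesicles, flat
backgrounds, isotropic PSF, exactly the stated class-pH separation. It
does not establish robustness to the things real sections add: overlapping
and out-of-focus vesicles, autofluorescence, chromatic shifts, sectioning
through rosettes off the equatorial plane, antibody penetration gradients.

## PANTHOS detection and staging

A candidate lesion is a connected region of high smoothed LC3 (mRFP)
signal (threshold: background + 15% of the robust dynamic range), closed,
hole-filled, larger than 250 um^2 and containing at least 20 pa-AL calls.
The area criterion is deliberately below the published soma-and-a-half
scale so that stage-i lesions (an expanded but unblebbed perikaryon) are
still candidates; the pa-AL burden carries the specificity, and healthy
fields produce zero calls. Blebs are counted on the radial-extent profile
of the lesion boundary: 5-degree angular bins whose outer mask radius
exceeds the 15th-percentile baseline by 2.2 um, grouped into circular
runs - a disk yields none, focal bulging one or two, a rosette one run
per bleb. Staging: >= 6 blebs plus a dark core (mean core LC3 below half
the lesion mean) is stage iii; >= 1 bleb is stage ii; otherwise stage i.
Counts are within one bleb of ground truth in >= 90% of simulated
rosettes; touching blebs merging under the morphological closing are the
known failure mode.

DAPI status of a lesion core (1.5 nucleus radii around the centroid):
"absent" below 1 um^2 of DAPI-positive area - an area criterion rather
than the raw maximum, which a single hot pixel of shot noise would
trigger - "condensed" below half the expected nucleus area, otherwise
"normal". Amyloid signal fraction integrates background-subtracted
intensity above the noise floor (3 MAD) inside the dilated lesion-mask
union over the field total; thresholding at the noise floor keeps the
half-normal sum of pure noise pixels from swamping the denominator.
Plaques are Otsu-segmented (guarded by a 6-MAD floor for fields with no
real bimodality) with hole filling and a 20 um^2 minimum; plaque-lesion
correspondence requires mask overlap of at least half the smaller mask.
"Marker within the confines" means >= 5 um^2 of marker-positive area
inside the lesion mask. "Total 3D6 signal" is read as integrated
intensity, not thresholded area.

## Statistics

Group summaries are mean +/- s.e.m. with the sample (n-1) standard
deviation; comparisons use the pooled-variance two-tailed unpaired
Student's t-test (the stated method; not Welch), with documented
degenerate conventions (equal constant groups: t = 0, p = 1). Per-neuron
colocalization fractions are computed over marker-positive puncta pooled
within each neuron and then averaged across neurons, matching the
per-neuron unit of analysis; the pooled cohort-level fraction is also
reported. No multiple-testing correction is applied, and neurons (not
mice) are the replication unit - both choices mirror the source analysis.

## Numerical and engineering choices

* No TIFF or image-processing package exists in the supported R stack, so
  the package carries a minimal uncompressed little-endian TIFF
  reader/writer (32-bit float images, 16-bit labels, channel metadata as a
  JSON ImageDescription; verified against Python's `tifffile`) and its own
  separable-convolution / connected-component / morphology primitives in
  C++.
* Detection and lesion parameters are config objects
  (`detectionParams()`, `classificationConfig()`, `panthosParams()`);
  every threshold named above is overridable.
* Watershed ties and component labels are ordered by (y, x), so all
  outputs are deterministic given the seed; analysis contains no
  randomness at all.
* Degenerate inputs: blank images give empty punctum lists (not errors);
  zero marker-positive puncta, zero lesions, or zero amyloid signal give
  flagged `NA` fractions; an all-zero intensity triple has no hue and is
  an error at the formula level, an unclassified punctum at the pipeline
  level.

## Known limitations

Single optical sections only (no z-stacks, matching the per-cross-section
units); no EM simulation, photobleaching, or chromatic aberration; no
neuron segmentation from cytoplasmic stains (ground-truth or user label
masks assign puncta to neurons); bleb counts saturate when blebs touch;
hue-sector boundaries and the saturation floor are declared defaults, not
values recovered from the original commercial workflow.
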