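---
title: "Quantifying capillary ultrastructure after subarachnoid hemorrhage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying capillary ultrastructure after subarachnoid hemorrhage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmorph)
library(dplyr)
```

## The problem

Subarachnoid hemorrhage (SAH) injures the neurovascular unit: capillaries
collapse, the perivascular neuropil degrades, pericytes retract, and
astrocyte endfeet detach from the basal lamina (BL). Electron microscopy
captures these changes, but turning micrographs into statistics requires a
long chain of conventions — which profiles to sample, how each parameter is
defined, how regions of interest are aggregated, and how three experimental
groups (SHAM, SAH, SAH + minocycline) are compared. `capmorph` implements
that chain as tested code, together with the companion molecular readouts
(3-D colocalization of immunofluorescence, relative qPCR expression,
immunoblot densitometry, zymogram activity) and the SAH grading used for
animal inclusion.

Raw micrographs are not part of the package's scope: annotations are. Every
morphometric operation consumes manually traced contours and polylines in
micrometre coordinates, exactly as a blinded experimenter would produce
them; only the electron-lucent "hole" measurement touches pixel
intensities. Because the original images are not available at all, the
package ships a synthetic phantom generator whose ground truth is known by
construction, so the entire measurement chain is verifiable end to end.

## Morphometric definitions

For a closed contour with area $A$ and perimeter $P$:

* **circularity** $= 4\pi A / P^2$, 1 for a circle, approaching 0 for an
  infinitely elongated outline;
* **roundness** $= 4A / (\pi M^2)$ where $M$ is the major axis of the
  moment-matched fitted ellipse — the ellipse with the same area-normalized
  second central moments as the filled region. For an exact ellipse with
  semi-axes $a > b$ this equals $b/a$. The polygon moments are computed
  from closed-form contour integrals (no rasterization), so a unit square
  gives exactly $3/\pi$;
* **endothelium area** = capillary (abluminal) area − lumen area, so the
  lumen and endothelium **volume fractions** sum to exactly 1 on every
  profile. Group means of the two fractions are averaged independently, so
  aggregated tables need not preserve the identity;
* **lumen/capillary size** = area / circumference (for a circle of radius
  $r$, $r/2$) — a calibre measure robust to outline irregularity.

**Basal lamina thickness** uses grid overlay sampling (GOIA): a square grid
of pitch 0.5 µm is laid over the profile, and at every gridline crossing of
the inner BL contour the local thickness is the distance to the outer
contour along the inner contour's outward normal. Crossings within 0.25 µm
(arc distance, configurable) of a pericyte adhesion arc are excluded,
because the lamina splits and thins where it envelops a pericyte; the
estimate is the mean of at least three admissible crossings, and coincident
contours return 0 by continuity. The 0.25 µm default is our choice: the
field's convention says only "adjacent".

**Tight-junction tortuosity** divides the traced junction length by the
diagonal of the axis-aligned rectangle bounding the complete trace; a
straight junction gives 1. The bounding box is axis-aligned, so the value
is frame-dependent — rotating a trace changes it. This matches how the
measurement is done on micrographs (in the image frame) and is asserted in
the tests rather than hidden.

**Pinocytic vesicle density** pools 3–5 counting fields of endothelial
cytoplasm into one reference area: $\sum \text{counts} / \sum
\text{areas}$, not a mean of per-field densities.

**Pericyte and astrocyte metrics**: process areas on a profile are summed;
coverage divides the summed adhesion arc length by the BL circumference.
We take the outer BL contour's perimeter as that circumference — the
adhesion arcs are traced on the parenchymal face — and expose the choice,
since the convention leaves it ambiguous.

**Electron-lucent ("hole") area** thresholds the perivascular band (2 µm
outward from the abluminal contour, configurable). The default threshold is
Otsu's method on the band pixels, guarded by a bimodality test: if the
separation between the two Otsu classes is less than four below-class
standard deviations, the band is declared hole-free. Without the guard,
Otsu *always* finds a threshold inside the noise of a hole-free band and
reports spurious bright area; with it, intact SHAM neuropil correctly
yields 0. Connected components are labelled with `EBImage`, and every
above-threshold component touching the band contributes its full area. A
fixed grey-level threshold can be supplied to bypass both.

**Sampling inclusion**: a profile enters analysis only if the lumen is
lined by ≤ 2 endothelial cells, the vessel is cut in cross-section, the
lumen is free of blood cells and plasma, and no endothelial or pericyte
nucleus is visible.

## The phantom generator

The generator's purpose is a known-truth testbed, not photorealism.

* **Contours** are Fourier-perturbed ellipses (harmonics 2–5, amplitudes
  shrinking as $1/\sqrt{k}$) rescaled uniformly so the enclosed area equals
  the drawn value *exactly*; the lumen is a concentric scaled copy, so the
  drawn lumen fraction is exact as well.
* **Parameter draws** come from truncated normal distributions at the
  physical bounds (areas, lengths, densities ≥ 0; fractions inside (0,1);
  tortuosity ≥ 1). The pre-truncation location is solved so the
  *post-truncation mean equals the specified group mean*; naive truncation
  would, for example, bias mean tortuosity upward by ~0.02 for a group at
  1.25 ± 0.16.
* **Basal lamina**: the outer contour is an outward vertex-normal offset of
  the inner one with a bisector correction, so the perpendicular face
  distance equals the drawn thickness to well under a nanometre at 192
  vertices.
* **Tight junctions** are zig-zag templates along the diagonal of an
  axis-aligned box with sine-tapered perpendicular offsets; the amplitude
  is solved by root finding so the tortuosity is hit exactly (representable
  range up to ≈ 3).
* **Adhesion arcs** are placed as disjoint sub-arcs of the outer BL contour
  with randomized gaps; their summed arc length equals the drawn adhesion
  exactly. Draws that cannot fit on the circumference are re-drawn a
  bounded number of times (then the whole profile is re-drawn from a
  perturbed substream; a persistent failure errors). This induces a slight
  negative bias in mean adhesion for the smallest capillaries, well inside
  the recovery tolerances.
* **Holes** are painted as quasi-circular pixel sets inside the
  perivascular band: the painted pixel count is the drawn area rounded to
  the pixel grid, so the thresholding path recovers the painted truth to
  half a pixel area. SHAM groups (hole mean 0) paint nothing, and their
  images contain only background noise.
* **Vesicle fields** draw 3–5 field areas around 1 µm² and Poisson counts
  at the drawn density; the realized pooled density is recorded alongside
  the drawn one, since Poisson noise is part of the emulated measurement.
* **Determinism**: every profile has its own random substream derived from
  the config seed and the animal/profile indices, so datasets are
  reproducible profile-by-profile and invariant to generation order.

What the phantoms do **not** emulate: real TEM texture, segmentation error
(annotations are exact by construction), correlated parameters within an
animal (profiles are i.i.d. within a group — there is no animal-level
random effect), nuclei or non-cross-section profiles (all phantoms pass
inclusion), and lumen/abluminal shape divergence (the lumen is a scaled
copy, so shape descriptors of the two contours coincide). Passing
round-trip tests therefore demonstrates the *measurement chain* is correct
on clean annotations, not that the pipeline is robust to tracing error.

## Colocalization

Two-channel stacks are reduced to threshold-based statistics in the Costes
style. The channel relation is fit by orthogonal regression on
*standardized* intensities (the standardized major axis, slope
$\pm\,\sigma_b/\sigma_a$): both channels carry noise, so neither is
privileged, and standardizing makes the thresholds equivariant under
per-channel intensity scaling — multiplying one channel by $k$ scales its
threshold by $k$ and leaves the correlation and percent-material results
unchanged, which the tests assert. Candidate thresholds for channel A
descend the intensity range (integer grey levels for integer data, 256
quantile steps otherwise) with $T_b = \text{slope} \cdot T_a +
\text{intercept}$; the first candidate whose below-both-thresholds voxel
population has Pearson $r \le 0$ wins. Two boundary conventions matter:

* if the whole stack is already non-positively correlated, the highest
  admissible threshold is the maximum intensity — nothing colocalizes;
* if $r$ never reaches zero (perfectly correlated channels), the scan
  bottoms out at the minimum intensity with an `exhausted` flag and
  essentially everything colocalizes.

Colocalized voxels are those above both thresholds. Percent material is
each channel's intensity share in those voxels; the Pearson coefficient is
reported both over colocalized voxels (the classification statistic;
`correlated` means $r \ge 0.5$, boundary inclusive) and over the whole
stack. Voxels zero in both channels are excluded from the regression.

The volume simulator has two styles. The *gaussian* style mixes smoothed,
standardized fields so the expected whole-stack correlation equals the
requested $\rho$ exactly (negative $\rho$ uses the negated shared field);
requesting more correlation than the noise budget allows errors. The *blob*
style builds channels from compactly supported spot fields sharing a
requested fraction of their mass — the generating truth for percent
material — over an independent noise floor that lets the threshold scan
terminate; with a disjointness request (fraction 0) the second channel's
spots avoid the first channel's support, so non-overlap is known by
construction. Mass share and whole-stack correlation cannot be set fully
independently under threshold-based counting (a brighter shared component
inevitably correlates the sub-threshold population too), so when both are
requested the generator fixes the mass share and steers the variance share
toward $\rho$, and both become approximate.

## Molecular quantification

Relative expression uses the comparative CT method with amplification
efficiency fixed at 2: $\Delta CT = CT_\text{gene} - CT_\text{reference}$
per sample, $\Delta\Delta CT$ subtracts the control group's arithmetic mean
$\Delta CT$ for the same gene, and the fold change is $2^{-\Delta\Delta
CT}$. Centering on the arithmetic mean of $\Delta CT$ makes the geometric
mean of control folds exactly 1 — the package documents (and tests) this
rather than forcing the arithmetic mean to 1.

Immunoblot densitometry adjusts each band by the mean of the membrane
background measured above and beneath the lane (floored at zero),
normalizes by the loading-control band, and expresses folds against the
mean normalized control level *on the same membrane*, which cancels
per-membrane gain exactly. Zymogram activity integrates the depth of the
lane trace below the local background across the band window (clear bands
are intensity minima), optionally divided by a parallel-gel loading value;
whether that normalization is applied is left to the caller.

## Grading and statistics

The SAH grade sums six basal-brain segment scores of 0–3 (range 0–18);
animals with grade ≥ 8 are included (boundary inclusive). Morphometric
records are averaged per animal — the animal, not the profile, is the
experimental unit — with missing values excluded parameter-wise. Each
parameter is then tested with a classical one-way ANOVA on animal means
plus pairwise Welch t-tests, adjusted with Benjamini–Hochberg FDR within
each parameter's three-comparison family by default (`fdr_scope =
"pooled"` adjusts across parameters instead; both scopes are defensible
and the convention is genuinely underdetermined, so the choice is
exposed). Star flags encode *which* comparison is significant (`*` group 2
vs 1, `**` group 3 vs 1, `***` group 3 vs 2), not significance tiers — a
legend convention that is easy to misread.

## Numerical choices and degenerate inputs

* Areas use the shoelace formula on polygon vertices; coordinates are
  micrometres with y increasing downward. Digitized circles can push
  circularity marginally above 1 through perimeter bias; values are clamped
  at 1 after asserting ≤ 1.02.
* GOIA with coincident BL contours returns 0 (continuity); fewer than three
  admissible crossings errors with the profile named.
* Empty pericyte/astrocyte annotation lists yield zeros, not errors; absent
  optional annotations (BL, TJ, vesicle fields, image) yield `NA` in the
  record, never zeros.
* An empty colocalized voxel set yields zero percentages, `NA` correlation,
  `correlated = FALSE`.
* The Costes scan requires at least 20 below-threshold voxels before
  evaluating a candidate.
* Truncated-normal sampling is by rejection (exact), with a degenerate
  `sd = 0` returning the clamped mean.

## Problem sizes

The shipped tests and the acceptance script use phantom datasets of 100
profiles per group for parameter-recovery checks (intensity images at
0.08 µm/px, ~200² px), 40-profile SAH datasets for the hole-recovery path,
64×64×16 to 64³ voxel volumes for colocalization, and 50 replicates of a
3-group × 4-animal × 10-profile design for the power check of the lumen
volume fraction. These sizes put every recovery well inside its sampling
tolerance while keeping a full run in minutes on one core; all of them
scale with ordinary arguments.

## A worked example

```{r example, eval = FALSE}
res <- run_pipeline(n_animals = 4, profiles_per_animal = 10, seed = 7,
                    output_dir = "sah_run")
res$report          # parameter x group means/SDs with star flags
autoplot(res$stats, parameters = c("lumen_volume_fraction", "hole_area"))
```

## Known limitations

* No animal-level random effect in the generator means the power check
  reflects profile-sampling noise only; real designs have between-animal
  variance that lowers power.
* The ANOVA is classical (equal-variance); pairwise tests are Welch. A
  heteroscedastic omnibus test was deliberately left out to keep the
  omnibus/posthoc pair conventional, and the FDR family scope is a
  documented choice, not a discovery.
* Spot/object-based colocalization is out of scope: the published parameter
  sets for spot detection are insufficient to reimplement it faithfully, so
  only threshold-based statistics are provided.
* Vesicle *detection* is out of scope — counts are annotation inputs, as
  they are in practice.
```
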