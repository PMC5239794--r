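---
title: "Constant-curvature contours: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constant-curvature contours: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvestats)
```

`curvestats` implements a twin analysis of contours defined by constant
curvature: a psychophysical branch (stimulus synthesis and Gaussian tuning
fits for two-interval forced-choice contour detection) and an
image-statistics branch (log-Gabor edge extraction, constant-curvature
contour mapping, and end-element orientation statistics). This vignette
records the models, the parameters that matter, the numerical choices
behind them, and what the synthetic validation does and does not show.

## Conventions

Positions are `(x, y)` in pixels with `y` increasing down the rows; angles
are degrees from the positive x axis toward positive y. Edge and element
orientations are axial quantities on `[0, 180)`; signed differences between
orientations are wrapped to `(-90, 90]`. Stimulus space uses degrees of
visual angle at a fixed raster scale of 64 px/deg, so an 8 x 8 deg field is
a 512 x 512 px image and the 8 px carrier period corresponds to 8
cycles/deg. All randomness flows through explicit integer seeds; identical
seeds give bit-identical stimuli, synthetic images, and response tables.

## Stimulus synthesis

Each element is a Gabor micro-pattern, the product of a circular Gaussian
envelope (`sigma` = 4 px) and an oriented cosine carrier (`lambda` = 8 px,
phase 0). The carrier phase is even-symmetric and identical for all
elements: phase per element is a free choice here, and a single fixed phase
keeps every element's contrast polarity identical, which is the simplest
assumption consistent with a field of identical micro-patterns.

A contour is built from a 4-element core turning by the curvature angle
`alpha` per element. Placement is cocircular: the displacement from one
element to the next bisects their orientations, so consecutive elements are
tangent to a common circle and the pairwise geometry satisfies the
continuity relation used later by the mapper. End elements (for 6-element
contours) sit at a separation `end_separation_deg` from the terminal core
elements in direction `theta_e` relative to the terminal orientation, and
are oriented along their own direction. Positive `theta_e` shares the
rotational sense of positive `alpha`, so "positive = continuing the
curvature" holds at both ends by mirror symmetry. S-shaped contours flip
the sign of the step once, between the two middle core elements — the only
interior flip point a 4-element core admits.

Density control restricts element centroids to a 16 x 16 grid of
0.5 x 0.5 deg cells, one centroid per cell. The placement search applies
uniform random rotations about the path centroid and uniform translations
until all centroids land in distinct cells (up to 10,000 attempts, then an
error; callers retry with a new seed). Patches may extend beyond their
cells — only the centroid is constrained. Empty cells are filled with
uniformly oriented, uniformly positioned noise elements; orientations are
drawn on `[0, 180)` since Gabors are 180-degree periodic. Fields always
hold 256 elements; when a widely separated end element must share a cell,
one fewer noise element is added so the total is conserved. Compositing is
additive in contrast about the mid-gray background, clipped to the
displayable range with a clip count recorded.

## The Gaussian tuning model

Detection performance per condition is `n_correct / n_trials`, and the
tuning of performance over end direction `X` is fit by

$$Y = A \exp\left(-\tfrac{1}{2}\,(X - M)^2 / SD^2\right)$$

by Levenberg–Marquardt least squares (`minpack.lm`). The denominator is
`SD^2`, the standard dimensionally consistent form. Initialization is
data-driven (`M` at the argmax, `A` at the maximum, `SD` at half the
sampled range) with five jittered restarts; the lowest-SSE converged fit is
kept, which makes the fit invariant to row order and robust to the shallow
likelihood surface of broad tuning curves. Fits are *flagged* rather than
rejected when they are uninformative: `A` within 0.05 of chance, `SD`
exceeding the sampled range, or `M` far outside it. No lower bound at
chance is imposed on `A`; the flag (`A < 0.55` for 2IFC) marks fits where
the unconstrained estimate is not meaningfully above guessing.

The logit transform (with proportions clamped to `[1/(2n), 1 - 1/(2n)]`)
is provided for variance stabilization of proportions; the tuning fit
itself operates on raw proportions, which is how the model above is
defined. Repeated-measures ANOVA and post-hoc machinery for human group
data are out of scope; the module stops at per-observer fits and group
means.

The simulated observer answers correctly with probability
`max(chance, Y(condition))`. The chance floor matters: for strongly curved
contours the default surface dips to chance at the extreme anticlockwise
end directions, and for the 40-deg surface (`A` = 0.566, `SD` = 92 deg)
the floored curve is essentially flat over the whole sampled range —
detection at chance — so its peak location is unidentifiable by design.
Recovery tests therefore pool medians across the full condition grid,
where the unidentifiable cell is absorbed by the median, and additionally
check the identifiable angles individually.

## Edge extraction

Images are converted to grayscale (Rec. 601 weights), optionally passed
through a user-supplied luminance linearization hook (for cameras with
known exposure), center-cropped, and windowed by a 480-px circular
aperture. Outside pixels are set to the mean interior luminance so the
aperture border introduces no contrast edge of its own.

The radial log-Gabor amplitude is
$H(r) = \exp(-5.77\,(\ln(r/f_c)/B_0)^2)$ with $f_c = 0.1$ cycles/px and
$B_0 = 1.5$, applied in the frequency domain with zero DC response. With
natural logarithms and decay coefficient 5.77 the separation of the two
half-amplitude radii is
$2 B_0 \sqrt{\ln 2 / 5.77} / \ln 2 = 1.50$ octaves, which
`log_gabor_bandwidth_octaves()` confirms by root finding; this is the
reading of the filter constants under which the stated 1.5-octave
bandwidth actually emerges.

Zero crossings of the band-pass image (sign changes against a 4-neighbour,
attributed to the pixel nearer zero, within the 216-px analysis radius)
are candidate edges, at pixel resolution. A magnitude floor of `1e-10`
ignores sign flips in numerically flat regions — a constant image's
band-pass response is pure floating-point residue and must yield nothing.

Orientation analysis uses a polar-separable log-Gabor bank: the radial
term above times an angular Gaussian of 40-deg full width at half
amplitude, single-sided in the spectrum so the inverse transform gives an
even/odd quadrature pair. Orientation energy is the squared modulus.
Eighteen orientations at 10-deg steps cover the circle, since orientation
energy is 180-degree periodic. Candidates whose peak energy falls below
10% of the strongest candidate response are discarded; the threshold
reference (image-wide maximum) is a configurable choice
(`threshold_frac`), as per-pixel versus global normalization is genuinely
ambiguous. The final orientation interpolates the log-energy profile
parabolically over the peak bin and its two circular neighbours — standard
sub-bin peak estimation, accurate to well under a degree for clean
gratings.

A band-pass filter's response to a single edge rings: secondary crossing
lines appear roughly half a carrier wavelength (5 px at $f_c = 0.1$) to
either side of the true locus, at energies that can exceed the 10%
threshold. The thinning pass therefore suppresses, within a radius of
`0.6 / f_c` = 6 px, any candidate weaker than a neighbour of similar
orientation (within 5 deg), greedily from the strongest candidate, with
row-major tie-breaks for determinism. Duplicate responses to one edge
collapse to the locally strongest pixel while distinct nearby edges of
different orientation survive. The radius is the one deliberate departure
from plain 8-neighbour adjacency: with adjacency alone the ringing
duplicates survive and, downstream, corrupt the end-element statistics by
pairing mapped contours with their own flanking artifacts.

## Contour mapping

For an ordered edge pair, `d` is the center distance, `phi` the direction
of the second element measured from the first element's orientation, and
`theta` the orientation difference, both wrapped to `(-90, 90]`. The pair
is continuous when `|theta - 2 phi| <= 5` deg — the exterior-angle
(cocircularity) relation. Under this parameterization, swapping the pair
preserves `d`, negates `theta`, and maps `phi` to `phi - theta` (axially);
`phi` negates exactly when the pair is continuous. Continuity itself is
symmetric.

`find_contours()` is a greedy, unguided search for chains of exactly four
edges satisfying: pairwise continuity; equal consecutive spacings within
one fifth; a constant signed orientation step within 5 deg; and forward
motion (consecutive displacements within 90 deg, ruling out chains that
double back — implicit in growing "in the same direction"). Four elements
is the cap because longer constant-curvature chains close into circles at
high curvature. Candidate spacings are scanned globally coarse to fine:
the outer loop runs integer spacings 42 down to 1 px, seeding edges in
row-major order within each spacing, and accepted contours mark their
members out of all further seeding and growth (configurable via
`mark_members`). The global ordering matters: scanning all spacings per
seed lets the small-spacing duplicate structure along a smooth edge
consume the members of a genuine large-spacing contour before it is ever
tried. When several candidates extend a chain, the one minimizing
`|theta - 2 phi|` wins, ties broken by smaller distance. Member order is
canonicalized (row-major head first) so the sign of the reported step is
well defined; reflecting an edge field then negates every step.

End elements are edges one spacing (within one fifth) beyond a contour
terminus, continuous with it, and not doubling back over the contour
(direction within ±90 deg of the outward continuation). Their orientation
is reported relative to the curvature direction — positive continues the
curvature — using the chain's travel step toward that end; for straight
contours the raw signed difference is kept, the curvature direction being
undefined. Mapped spacings are binned to the five length bins
1–8, 9–17, 18–24, 25–33, 34–42 px (the printed bin edges, used verbatim
even though they are not all 8 px wide), and steps to curvature classes at
multiples of 10 deg.

## Curvature statistics

End-orientation histograms use 10-deg bins centered on multiples of
10 deg — the orientation sampling grid — so a distribution peaked at a
sampled orientation falls mid-bin rather than on an edge. Frequencies are
normalized by the total number of contours of the curvature class, making
proportions comparable across classes; the per-length-bin split is
preserved. Per-class distributions are fit with the same Gaussian model as
the psychophysics (flat or near-empty distributions are flagged, not
errors), and the fitted peaks across classes are fit by exponential growth
`M = S exp(K X)`, initialized from the log-linear regression; if the
optimizer rejects an exact zero-residual start, the start itself is
reported. Linear trends (amplitude and width versus length) use ordinary
least squares.

## The synthetic corpus: what it emulates, and what it does not

`render_planted_image()` renders chains of edge elements — odd-symmetric
(dark-to-light) Gaussian-windowed segments, elongated 3.5 : 1.4 px along
the edge — over a uniform or 1/f background, with optional random
distractor elements. The edge (rather than line) polarity is deliberate:
the zero-crossing detector localizes odd structure at its center, so
planted elements are recovered within a pixel, whereas a bar's crossings
sit on its flanks. The elongation keeps each element's orientation well
defined to the 40-deg-bandwidth oriented filters; with compact isotropic
elements, orientation estimates of neighbouring elements contaminate each
other at the corpus spacings.

The default corpus — the package's fixed validation conditions — uses 50
images of 480 x 480 px, four chains per image at spacings
{20, 24, 28} px, curvature classes 0–40 deg with weights 5:4:3:2:1
allocated exactly (largest-remainder rounding) so planted counts decrease
monotonically with curvature, random headings and curvature signs, and
continuation elements planted one spacing beyond each chain end. In the
realistic default the continuation offset is Gaussian around the curvature
step (SD 12 deg, inside the 6.5–24 deg range of per-class spreads such
corpora exhibit); the end-to-end recovery tests instead plant offsets
exactly at the step, the condition under which per-class distribution
peaks have a known ground truth.

What passing the synthetic recovery shows: the full chain —
filtering, thresholding, thinning, mapping, end extraction, binning,
fitting — is internally consistent and recovers planted structure to
within a few degrees under clean conditions. What it does not show:
behavior on natural images, which contain extended smooth contours (not
discrete elements), occlusions, broadband clutter, and luminance
nonlinearity. Three artifacts of the method visible even synthetically are
worth knowing. First, duplicate chains: the band-pass response to a chain
of elements is nearly continuous, so the mapper finds additional valid
contours along bridging responses between elements — these share the
parent's curvature and mostly amplify its statistics. Second, a
sign-rectification bias at low curvature: near-straight chains have noisy
step signs, and normalizing end orientations by that sign rectifies part
of the noise, biasing the class-0 peak upward by several degrees under the
jittered default (visible in the README example). Third, high-curvature
sparsity: class-40 chains are rare by construction and their wrapped
orientation geometry makes overshoot likely, so class-40 fits should be
read with the same caution as broad, poorly fit distributions in real
corpora.

## Problem sizes and runtime choices

The validation suite uses the sizes at which the properties are stable and
informative: 500 random ≤50-edge fields for the mapper–oracle comparison;
30 single-chain noise-free images (5 steps x 3 headings x 2 spacings) for
strict planted recovery; 20 images across ten continuation offsets for
end-orientation recovery; 200 simulated observers at 200 trials/condition
for psychometric recovery; and the 50-image corpus above for the
end-to-end check. A full image pass (18-filter quadrature bank on
480 x 480 px plus mapping) takes on the order of a second, which sets the
scale of everything image-bound.

## Known limitations

* The mapper is unguided; overlapping or intersecting structures can be
  stitched into spurious contours that satisfy all four criteria. Marking
  removes members after acceptance (first-come wins in scan order).
* Edge positions are pixel-resolution; no subpixel localization is
  attempted, matching the pixel-based distance bins.
* Orientation estimates degrade where elements of different orientation
  overlap within a filter wavelength.
* The luminance linearization hook is a pass-through interface; no camera
  model ships with the package.
* Exp-2 stimuli with end separations up to 2 deg can fail the strict
  one-centroid-per-cell search for unlucky geometries; the search errors
  after its attempt budget and callers retry with a new seed.
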