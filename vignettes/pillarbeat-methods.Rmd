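---
title: "Methods: micropillar tracking, beam mechanics, and beat statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micropillar tracking, beam mechanics, and beat statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillarbeat)
```

## The measurement model

A cardiomyocyte attached to the top of a slender elastomeric micropillar
bends it laterally as it contracts. For small deflections of a cylindrical
cantilever of diameter $D$ and length $L$ made of a material with Young's
modulus $E$, the tip behaves as a linear spring,

$$k = \frac{3\pi E D^4}{64 L^3} = \frac{3EI}{L^3},\qquad
I = \frac{\pi D^4}{64},$$

so the contraction force follows from the tip deflection $d$ as $F = k\,d$,
where $d = X_i - X_\mathrm{ref}$ is the displacement of the pillar top in
frame $i$ from its relaxed reference position. The model assumes:

* **small deflections** — tip excursions of a few μm on a 48 μm pillar stay
  well inside the linear Euler–Bernoulli regime, so force–displacement is
  linear through the origin; no large-deflection corrections are applied;
* **tip loading** — the cell grips the pillar top; shear contributions are
  neglected at aspect ratio $L/D = 3$;
* **a rigid base** — substrate warping, a known artefact of thin-film
  cantilever chips, does not arise for pillars on a thick slab and is not
  modelled.

Units are chosen to match how these quantities are usually printed:
geometry in μm, modulus in MPa, $k$ in N/m, deflection in μm, force in μN
($\mu m \times N/m = \mu N$ with no extra factor). All SI conversions are
internal. For the reference geometry (D = 16 μm, L = 48 μm, E = 0.5 MPa)
the closed form gives $k = 0.0436$ N/m, i.e. 0.04 N/m at one significant
figure; we treat the closed form as authoritative and regard the
one-significant-figure value as its rounding. A calibrated stiffness
(e.g. from AFM) can be supplied via `pillar.spring_constant_n_per_m`, in
which case it takes precedence over the formula. PDMS moduli outside
0.5–4 MPa only warn, so stiffer elastomers remain usable.

## Coordinate and angle convention

Every module shares one convention, documented once and tested: image
x = column index increasing rightward, y = row index increasing downward,
origin at the centre of the top-left pixel; angles are measured
counterclockwise from +x in the *physical* (y-up) frame and mapped to
$[0^\circ, 360^\circ)$. An image-frame displacement of $(0, -1)$ px — one
pixel up on screen — therefore has direction 90°.

## The synthetic-data generator

`render_stack()` emulates an inverted-microscope recording of a square
pillar lattice: each pillar top is drawn as a bright disk whose edge is a
Gaussian-softened step (the error-function profile of a hard disk convolved
with a Gaussian, accurate for top radius ≫ blur σ), on a dark background,
with additive Gaussian noise. Defaults mirror the physical array the
package targets: 23 μm pitch, 16 μm pillar diameter (top radius 16 px at
0.5 μm/px), 25 fps. The recording length, beat rate, and pixel size are
not properties of the array, so they are configuration, not physics: we
default to 10 s, 1 Hz, and 0.5 μm/px as realistic values for a neonatal
rat ventricular myocyte recording on a 20–40× objective.

Motion follows a cardiac twitch: a raised-cosine rise over 0.2 s to the
peak amplitude (3 μm by default), an exponential-like relaxation over
0.4 s forced to exactly zero at its end, then quiescence until the next
period. The peak value and period are contractual; the rise/decay shapes
are implementation choices. Each pillar moves along a single axis drawn
from the direction field: in `aligned` mode the groove axis plus optional
Gaussian jitter, in `isotropic` mode an independent uniform angle.
Contraction and relaxation displacements therefore point in opposite
directions along one axis, which is what produces the characteristic
bimodal (e.g. 90°/270°) pattern of groove-aligned beating.

What the simulator deliberately does **not** emulate: Poisson photon
statistics (noise is additive Gaussian, and tracker performance is
specified at an SNR, defined as signal level / noise σ), out-of-plane
motion, photobleaching, cell bodies, and the groove texture on the pillar
top (grooves steer the cells, not the tracked image feature). Passing the
recovery tests therefore demonstrates correctness of the geometry,
tracking, calibration and statistics chain at a realistic SNR — not
robustness to focus drift, debris, or irregular arrhythmic beating, which
real recordings can exhibit.

Rendering is bit-deterministic: the seed is mandatory, the caller's RNG
state is saved and restored, and frames are quantized to the 16-bit grid
at render time so a written TIFF round-trips bit-exactly.

## Detection

The reference frame defaults to the frame closest (mean absolute
difference) to the temporal median image — a "most relaxed" proxy, since
contraction excursions are brief. A second pass recomputes the median over
the quietest quarter of frames so that relaxation tails cannot pull the
choice slightly off rest; the selection can always be overridden by index.

Detection itself is a difference-of-Gaussians band-pass tuned to the
expected top radius (σ of r/2 and 1.5 r), strict 8-neighbour local maxima
above a relative response threshold (default 0.3 of the maximum), greedy
non-maximum suppression at the minimum separation, and sub-pixel
refinement by intensity-weighted centroid in a radius-sized window of a
lightly smoothed frame (σ = r/4). The centroid was chosen over Gaussian
fitting because pillar tops are flat-topped disks, not Gaussian spots; the
light smoothing suppresses pixel noise without biasing a symmetric blob.
The refined centre may drift at most one window from its start, so manual
seeds on featureless background stay put and are flagged low-score rather
than wandering to the nearest bright object. Degenerate (constant) frames
are an error; zero detections produce an empty set with a warning, not a
crash. `fit_lattice()` provides a geometric QC check: fourfold circular
mean of nearest-neighbour bond angles for the orientation, then a joint
least-squares fit of origin and pitch over integer lattice indices, with
per-centre residuals; collinear centre sets are rejected as degenerate.

## Tracking

Each pillar's template is cut once from the reference frame — pillar
appearance is static, so templates are never updated (updating invites
drift). Every frame is matched by normalized cross-correlation over an
integer shift grid (half-width `window_px`, default 5 px) centred on the
previous frame's position, and the correlation peak is localized to
sub-pixel precision by separable parabolic interpolation of the peak and
its neighbours, with the offset clamped to ±0.5 px. Carrying the search
window along with the previous frame's integer offset keeps the grid small
while following motion of many pixels per beat.

Frames whose peak correlation falls below the quality threshold (default
0.5), or whose search window would leave the image, are flagged `lost` and
filled by linear interpolation — never silently dropped, because silent
gaps corrupt peak detection downstream; the flag column lets beat
statistics exclude them.

Although the deflection definition $d = X_i - X_\mathrm{ref}$ is
one-dimensional, the tracker reports both components: direction analysis
requires the vector, and the magnitude reduces to the scalar definition.

**Reference position.** "Relaxed position between contractions" and
"original position" are different operationalizations, so both exist:

* `percentile` (default): project the trajectory on its principal motion
  axis, orient the axis so contraction excursions are positive (positive
  skew), and average the frames at or below the 10th percentile of the
  projection — the relaxed extreme. With a twitch duty cycle well below
  90% this estimates the true rest position even though the pillar spends
  much of each period in motion.
* `fixed`: a chosen frame's position (the original-position notion).
* `rolling`: a per-frame 10th-percentile baseline along the motion axis in
  a rolling window (default 75 frames = 3 s at 25 fps, i.e. about three
  beats) plus a rolling median across it, tolerant of slow stage drift
  that a single fixed reference cannot follow.

The method used is recorded in the series' metadata.

## Beat segmentation and direction statistics

Beats are peaks of the deflection magnitude $d(t)$ with height **and
topographic prominence** at least `min_amplitude_um` (default 0.5 μm) —
prominence rather than raw height so a drifting baseline does not mask or
fabricate beats — separated by at least `min_separation_s` (default
0.3 s, comfortably under any physiological beat period at ≤ 3 Hz); of two
closer peaks the taller wins. Beat boundaries sit at the nearest
sub-threshold crossings on either side of the peak. A series with no
qualifying peaks is reported quiescent. Beat frequency is the reciprocal
of the *median* inter-peak interval (robust to one missed or spurious
beat), with the plain count/duration rate reported alongside; fewer than
two beats leave it undefined.

Each beat's direction is the angle of the deflection vector at its peak
frame. Summaries report both the directional resultant
$R = |\langle e^{i\theta}\rangle|$ with its circular mean and the axial
order parameter $R_2 = |\langle e^{i2\theta}\rangle|$ with dominant axis
$\tfrac12\arg\langle e^{i2\theta}\rangle$. Alignment to a groove is an
axial property: a pillar beating back and forth along 90°/270° has $R
\approx 0$ but $R_2 = 1$ with axis 90°, so reporting a directional mean
alone would misleadingly suggest no order. Beat vectors are per-beat peak
vectors (per-frame vectors would overweight long beats); the angular
histogram defaults to 36 bins of 10°, the usual polar-plot resolution.

## Group statistics

Per-experiment summaries are compared with Student's t-test
(pooled-variance by default, matching the classical naming; Welch and
paired variants behind flags), reported with mean ± SEM (SEM with the
$n-1$ standard deviation; undefined at $n = 1$ rather than silently 0),
the percent difference of means, the exact p-value, and a significance
tier (* p < 0.05, ** p < 0.01, NS). Zero pooled variance is handled
explicitly: equal means give $p = 1$; unequal means raise an infinite-t
flag. Drug responses are normalized per experiment as
$100\,(\mathrm{pre}-\mathrm{post})/\mathrm{pre}$ (positive = decrease),
then summarized; the percentage is scale-invariant by construction. The
percent decrease is reported with the SEM *of the percentages* — quoting a
μN-scale SEM against a percentage mixes units, so we do not do it. No
multiple-testing correction is applied; the intended use is a handful of
planned comparisons.

## Numerical choices and degenerate inputs

* Sub-pixel NCC peaks use a parabolic fit only at interior grid points;
  border maxima keep the integer position for that axis.
* A constant trajectory's reference is that constant (the principal-axis
  machinery is bypassed below a variance floor).
* The twitch decay uses shape constant 5 and is renormalized so the
  waveform is exactly 0 at the end of relaxation, keeping "starts at rest"
  exact rather than within $e^{-5}$.
* Greedy non-maximum suppression breaks ties by response strength, then
  ordering is row-major (rows grouped by half the minimum separation).
* Rendered geometry is validated: tops closer than two rendered radii are
  refused rather than drawn overlapping.
* Errors are classed conditions (`pillarbeat_invalid_parameter`,
  `pillarbeat_degenerate_input`, `pillarbeat_insufficient_data`, …) so
  callers can distinguish bad parameters from bad data.

## Problem sizes

The test suite exercises mostly a 3×3 lattice over 4 s (100 frames,
160×160 px) and the full 5×5, 10 s, 250-frame reference scene — noise-free
and at SNR 10 over three seeds — for the end-to-end recovery checks; the
t-test calibration uses 10,000 simulated null comparisons at $n = 5$.
These sizes were chosen so the whole chain, from rendering to statistics,
runs comfortably on a laptop while leaving no stage untested at the
reference scale.

## Known limitations

* Tracking assumes quasi-rigid, in-plane motion of a static-appearance
  template; defocus, stage z-drift or morphology changes degrade the
  correlation quality (and are surfaced through the quality column, not
  corrected).
* The beat segmenter targets regular twitches; heavily fused or
  arrhythmic events merge under the separation rule rather than being
  classified.
* The simulator's Gaussian noise understates the signal-dependence of
  shot noise at low light.
* Only multi-page TIFF input is supported; other containers should be
  converted upstream.
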