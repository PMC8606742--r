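---
title: "Geometric moment arms, joint kinematics and ROM envelopes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric moment arms, joint kinematics and ROM envelopes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momentarms)
```

This vignette is the package's account of its science: the models it
implements, the assumptions baked into its defaults, the numerical choices,
and what the synthetic-rig tests do and do not establish about real data.

## The measurement problem

Marker-based biplanar fluoroscopy of a manipulated limb yields, per video
frame, a rigid-body transform for each bone and 3D positions for markers
implanted in muscle bellies. Two families of quantities are derived from
this. First, *joint kinematics*: the pose of a distal anatomical frame
relative to its proximal partner, decomposed into three Euler rotations
(abduction-adduction about x, long-axis rotation about y,
flexion-extension about z) and three translations. Second, *muscle moment
arms* (MMAs): the leverage, in mm, of a muscle's line of action about each
joint axis, which multiplied by muscle force gives joint torque.

## The geometric MMA method

A joint axis is a line through the joint centre with unit direction
$\hat{x}$; the muscle line passes through its proximal marker $p$ with
unit direction $\hat{F}$ (proximal → distal). `common_perpendicular()`
returns the shortest segment $\vec{r}$ joining the two skew lines; it is
perpendicular to both. Its length alone is not the scalar moment arm: any
component of the pull parallel to the axis generates no moment about it,
so the magnitude is scaled by the in-plane fraction of $\hat{F}$ and
signed by the right-hand rule,

$$ r_\theta \;=\; \operatorname{sign}\!\big((\vec r \times \hat F)\cdot\hat x\big)\,
   \lVert \vec r\rVert\, \big\lVert \hat F - (\hat F\cdot\hat x)\hat x \big\rVert
   \;=\; \big((p - a)\times \hat F\big)\cdot \hat x , $$

the torque per unit force about the axis. The closed form on the right is
used as an independent oracle in the tests; the implementation goes
through the explicit skew-line construction so the vector moment arm and
its foot points remain available for inspection. Consequences worth
knowing:

* $r_\theta$ depends only on the muscle's *line*, not on which two points
  along it define the line or how far apart they are.
* $|r_\theta| \le \lVert\vec r\rVert$, with equality exactly when the
  muscle is perpendicular to the axis; a muscle parallel to the axis, or
  crossing it, has $r_\theta = 0$.
* Applying one rigid transform to the joint frame and the muscle leaves
  every $r_\theta$ unchanged.

**Sign contract.** The force direction is defined proximal marker →
distal marker; swapping the markers flips every sign. With that
orientation $r_\theta$ equals $+\,\mathrm{d}L/\mathrm{d}\theta$ for a
straight muscle, whereas the tendon-travel estimator
(`tendon_travel_mma()`) follows the field's muscle-action convention
$-\,\mathrm{d}L/\mathrm{d}\theta$ (a muscle that shortens with positive
motion gets a positive moment arm). The two estimators therefore agree
exactly when the geometric muscle line is oriented in the direction the
force pulls on the distal segment, i.e. insertion → origin. The
equivalence tests and the `compare` subcommand use that orientation; both
conventions are deliberate and documented rather than silently
reconciled.

Tendon travel uses central differences with a default half-step of 0.01°,
which puts the $O(h^2)$ truncation error near $10^{-7}$ mm — far below
the 0.1 mm reporting precision of the data this method serves — while
staying far above the $10^{-6}$-degree floor where floating-point
cancellation dominates.

## Kinematics

Bone transforms are fitted from ≥3 non-collinear markers per bone by
orthogonal Procrustes (SVD with the determinant constrained to +1, so a
reflection is never returned even on degenerate noisy frames). Collinear
marker sets are rejected outright: a collinear triad cannot constrain
rotation about its own axis, the classic failure when slender bones force
markers into a line.

Euler decomposition defaults to intrinsic rotations applied x, then y,
then z — the rotate order of the animation packages typically used to
export such data. The order is an assumption, not a measurement; it is
configurable per joint (`euler_order`) and stored with every pose so a
mismatch is visible rather than silent. Within ~10⁻⁶ degree of the ±90°
gimbal singularity the first and third rotations are coupled; the
decomposition then sets the third angle to zero (a deterministic
tie-break), flags the pose, and still recomposes to the original rotation
exactly.

Joint axes for MMA evaluation follow the *proximal* bone's animated frame
by default, since anatomical axis frames are fixed on bones; the distal
frame can be selected instead (`axes_from = "distal"`). For a hinge the
shared axis gives identical answers either way; for off-axis components
the choice matters and is recorded.

Kinematic series are filtered with a 4th-order Butterworth low-pass run
forward and backward (zero phase), with odd reflection padding and each
pass initialised at the steady state of its first sample so DC gain is
exactly 1. Cut-offs of 3–8 Hz at 60 Hz sampling are the intended regime
for passively manipulated limbs; `lowpass_response()` exposes the exact
(bilinear-warped) amplitude response the tests check against.

## ROM summaries and envelopes

`pooled_range()` pools per-specimen extremes as min-of-minima /
max-of-maxima; the packaged `echidna_forelimb_ranges()` table is the
worked example, and pooling it reproduces the published "total possible"
column. One published row is internally inconsistent at the 1° level
(its total was evidently computed from unrounded data before the
endpoints were rounded for print), so tests compare totals at the printed
1° precision of the endpoints.

`cosine_correct()` implements $x' = x\cos(y)$ on the axis of greatest
variation (x, abduction-adduction) modulated by long-axis rotation (y).
The published description names only the corrected axis; the modulating
axis is this package's explicit assumption, and both are parameters. The
correction is odd in the corrected coordinate and never increases its
magnitude.

`alpha_hull()` computes a 3D Delaunay tetrahedralisation (an in-package
incremental Bowyer–Watson construction, written here because no installed
R package offers 3D Delaunay) and keeps tetrahedra whose circumsphere
radius is ≤ alpha. The *radius* dialect is the default because it makes
the canonical threshold of 20 commensurate with degree-scaled axes; a
*reciprocal* dialect is available, and the dialect is recorded in every
output. Volume is the sum of retained tetrahedron volumes, in cubic
degrees; it is non-decreasing in alpha and reaches the convex hull volume
as alpha → ∞. Numerical notes: exactly cospherical subsets (e.g. the
corners of a cuboid cloud) would stall the incremental construction, so
points are perturbed by a deterministic ~10⁻⁸-relative jitter during
construction only — volumes are measured on the unperturbed coordinates;
coplanar clouds are rejected with an explanatory error; a cavity is
restricted to its face-connected component so sliver-circumsphere
round-off cannot corrupt the mesh. Envelopes are computed on rotational
coordinates only; translations are summarised separately, mirroring how
such data are tabulated.

## Torque layer

Maximal isometric force is PCSA × 0.3 N/mm². Torque about an axis is
$\tau_\theta = r_\theta F_{max}\,[a\,f_{act}(\tilde\ell) +
f_{pas}(\tilde\ell)]\cos(\text{pennation})$. The generalised curves are
deliberately simple parametric stand-ins for the usual tabulated forms —
a Gaussian active force-length curve (peak 1 at $\tilde\ell = 1$, width
0.45 normalised lengths), an exponential passive curve engaging above
$\tilde\ell = 1$, a linear-region tendon — because species-specific
curves are typically unavailable; all are pluggable, including from
tabulated CSVs (`tabulated_curve()`). Fibre length uses the rigid-tendon
assumption: (musculotendon length − tendon slack length)/cos(pennation),
normalised by optimal fibre length — the simplest defensible model when
tendon compliance is unknown. A force-velocity curve is stored for
completeness but unused: the analysis is isometric torque-angle, not
dynamics. Multi-head muscles are averaged within a muscle before summing
across muscles (`summed_series()`), so a muscle modelled as several lines
of action is not over-counted; `peak_rank_order()` ranks motions by peak
absolute summed value with alphabetical tie-breaks, and
`compare_rank_orders()` reports rank changes, such as a large-PCSA muscle
promoting flexion past adduction between an MMA ranking and a torque
ranking.

## The synthetic rig: what it emulates and what it does not

`synthetic_rig()` + `simulate_trial()` generate what the trackers would
see: two bones (proximal fixed), a revolute / ball / free joint with known
centre and axes, straight-line muscles, marker triads rigidly following
their bones, at 60 frames/s, with optional iid isotropic Gaussian noise
per marker coordinate. Noise of 0.05–0.3 mm spans plausible tracking
error for ~1 mm markers; the study conditions used in the recovery checks
are 0.1 mm over 600 frames. The seed is recorded in trial metadata and
trials are bit-reproducible under it.

The rig gives exact ground truth (transforms, poses, moment arms, and a
law-of-cosines closed form for the planar hinge), which is what makes
end-to-end pipeline checks meaningful: noise-free recovery to ≲10⁻⁶ mm,
noisy recovery unbiased within sampling error. What the rig does *not*
emulate — and hence what passing tests cannot show about real data —
includes curved or wrapping muscle paths (the geometric method itself
assumes a straight line between markers), marker migration within the
muscle, soft-tissue constraint on joint motion, tracking error that is
correlated across frames or anisotropic along the X-ray axes, and
time-varying joint centres. Agreement between the geometric and
tendon-travel estimators on the rig validates the *mathematics*, not the
anatomical fidelity of a straight-line muscle.

## Problem sizes and other choices

The heavier checks run at sizes chosen to keep the whole suite
desk-interactive while leaving the statistics meaningful: 100 random
hinge rigs × 36 poses for method equivalence, 600 frames for noisy
recovery, ~1000–1500-point clouds for envelope volumes (at those
densities the mean inter-point spacing is ~4°, which is why the canonical
alpha of 20° sits comfortably above it and recovers concave volumes to a
few percent). Reports round to 0.1° / 0.1 mm — the precision of the
tables this package reproduces — while CSV and JSON outputs keep full
precision.

Known limitations: no via-points or wrap surfaces; no activation or
contraction dynamics; envelope extraction assumes enough poses to sample
the reachable set (a sparse cloud under-fills its true envelope at any
alpha); and Euler-angle ROM summaries inherit the usual coordinate
distortions that the cosine correction only partially removes.
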