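---
title: "Measuring linker DNA trajectories and H1 compatibility in nucleosome arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring linker DNA trajectories and H1 compatibility in nucleosome arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucgeom)
```

# The model

`nucgeom` reduces a nucleosome (array) to the ordered 3-D centroids of its
base pairs. This coarse-graining is lossless for the quantities the
package computes: every downstream operation — frame construction, linker
vectors, projections, superposition, stacking metrics — consumes base-pair
centroids only, so atomic detail beyond the centroid is never needed. A
centroid is the unweighted mean of all heavy atoms of the two paired
nucleotides (`atoms = "heavy"`); a C1′-only mode (`atoms = "c1"`) is
provided as a sensitivity check because the atom selection entering the
centroid is a genuine modelling choice — the two differ by fractions of an
Ångström and rotate the measured angles by well under a degree, but the
all-heavy-atom default is the most literal reading of "centroid of the
base pair" and is what the tests pin down.

## The per-nucleosome frame

Three anchor base pairs define the frame: the central base pair of the
147-bp core (p1, on the dyad), and the base pairs 38 bp upstream (p2) and
39 bp downstream (p3) of it. Because ~77 bp of wrapped DNA complete one
superhelical gyre, p2 and p3 lie on the two different gyres directly
across from the dyad, so

- **v** = unit(p3 − p2), the gyre-to-gyre vector, approximates the disc
  normal,
- **u** = unit(p1 − midpoint(p2, p3)) approximates the dyad axis,
- **w** = unit(**u** × **v**) completes the triad.

**u** and **v** are approximations by construction (they are exact only
for an idealized superhelix), and the two plane bases are made exactly
orthonormal by Gram–Schmidt: the perpendicular plane is spanned by
{**u**, orthonormalized **v**}, the disc plane by {**u**, **w**}.
Direction conventions — **u** from the gyre midpoint toward the dyad,
**v** from the upstream to the downstream anchor — fix all signs below;
unsigned quantities are convention-independent.

## Linker angles and deviations

Each linker side is one vector: from the centroid of the base pair 5 bp
into the core (counted inclusively from the core edge) to the base pair
10 bp outside it. Offsets are inclusive ("5 bp into" = the 5th core base
pair) and configurable (`into_offset`, `outside_offset`); the measured
angles shift only weakly under a ±1 register change. A side with fewer
than 10 resolved linker base pairs is *undefined* — a first-class state
that propagates as `NA`, never as zero and never as an error.

β is the signed angle from **u** to the linker vector after projection
onto the perpendicular plane; α the same after projection onto the disc
plane; range (−180°, 180°], sign toward the plane's second basis vector.
Deviations Δα/Δβ against a reference mononucleosome are computed by
superposing the reference's 147 core centroids onto the target core
(Kabsch, reflection-guarded), rotating the reference linker vectors
through the fitted rotation, and taking the unsigned angle between target
and mapped-reference projections in the target frame. With consistent
signed angles this equals |signed target angle − signed mapped-reference
angle|; the test suite asserts the two readings agree to 1e-9 degrees, so
either description can be used interchangeably.

Two consequences of rebuilding the frame from whatever coordinates are
measured deserve note. First, all angles are exactly invariant under
common rigid motions. Second, mirroring a structure flips the sign of α
while leaving β unchanged — the frame's out-of-plane axis flips with the
structure, which cancels in β and inverts the in-plane chirality that α
reads. Both behaviors are pinned by tests.

## Stacking metrics

For a nucleosome pair the package reports the distance between core
centroid means, the angle between disc normals (the **v** axes, folded to
[0°, 90°]), the dyad tilt (between **u** axes, folded), and the lateral
offset (center-to-center component perpendicular to the mean normal). A
pair is classed as stacked when centers are within 75 Å and normals
within 30°, with "aligned" vs "offset" split at 15 Å lateral offset.
These thresholds quantify a qualitative distinction (face-to-face
stacking vs free nucleosomes); they were calibrated once on the synthetic
generator, are exposed as arguments, and the class labels are geometric
statements only — they assert nothing about which histone surfaces form
the interface.

## H1 compatibility and the steric screen

A nucleosome is compatible with on-dyad H1 binding when **every defined
side** has Δβ ≤ 6° (inclusive). One strongly deviated linker suffices for
incompatibility because the linker histone needs both linker contacts;
a nucleosome with no defined side yields an *indeterminate* call, never
`FALSE`. The 6° default comes from the upper bound observed where H1 is
always bound; it is a bound, not a fitted cutoff, so it is configurable.
The classifier is monotone by construction: raising any Δβ can only flip
compatible → incompatible.

The steric screen maps a coarse H1 footprint — five pseudo-atom spheres of
radius 6.5 Å: one on the dyad axis and, per side, two along the path a
linker bent 50° in β toward the mid-plane would take, i.e. inside the
wedge between the two linkers that the H1 winged-helix domain occupies —
from the reference onto the target via core superposition, and counts
environment points within (cutoff + radius), cutoff 4 Å. The environment
is every base-pair centroid of the array except the target's own core:
the target's own linkers stay in, because a linker swinging through the
H1 wedge is exactly the collision of interest. Sphere positions and radii
are an engineering calibration on the generator (chosen so that reference
trajectories clear the footprint by > 2.5 Å while bends ≥ 20° intrude);
the screen is a geometric plausibility check, not an energy model.

# The synthetic generator

The generator exists so that every stage of the pipeline can be tested
against analytically known ground truth, with no external data.

**Core.** 147 centroids on a left-handed superhelix, radius 41.9 Å, pitch
25.9 Å (canonical nucleosome values). The default turn count is 146/77 ≈
1.90 so that the frame anchors (dyad −38/+39 bp) sit exactly one gyre
apart at matched azimuth — the geometry the anchor construction presumes.
At the often-quoted 1.65 turns the anchors end up ~50° apart in azimuth
and the gyre-to-gyre vector lies far off the superhelix axis; that value
remains available through the `turns` parameter, but it makes **v** a
poor normal and is not the default. Parameter combinations whose anchors
are less than half a pitch apart axially (e.g. a flat spiral) are
rejected as violating the gyre condition.

**Linkers.** A linker leaves each core as a straight segment at B-DNA
rise 3.4 Å/bp. The segment's direction is solved so that the *measured*
chord — from the 5th core base pair to the 10th linker base pair — has
exactly the requested (α, β); ground-truth recovery at zero noise is
therefore exact to floating-point precision (asserted at 1e-6 degrees on
the packaged templates and within the 0.5° contract over a ±40° grid). Between the two straight 12-bp end
segments of an internal linker, the interior follows a cubic Hermite
curve matching both end tangents: real linker DNA bends smoothly, and a
straight interior cannot turn the ~150° needed to fold back onto a
stacked partner without kinking. Entry and exit angles of a nucleosome
are therefore independently controllable, which the per-side deviation
presets require. Angle targets need |α|, |β| < 90°.

**Templates.** `nrl_preset()` ships 4×177/187/197/207 zig-zag templates:
nucleosome 1 at the origin, nucleosome 3 stacked 63 Å along the disc
normal with a 4° tilt, nucleosomes 2 and 4 looping out, placed at runtime
from a tuned parameter table (stack azimuth, Euler angles, junction
spacings) so that linker paths stay smooth and nothing approaches within
10 Å. The per-side β deviations encode the qualitative NRL trend —
stacked nucleosomes far from the reference at short NRL, relaxing toward
zero as the NRL grows (nucleosome 1 compatible from 187, nucleosome 3
only at 207, nucleosomes 2/4 always) — with bends directed toward the
mid-plane so that large deviations also intrude into the H1 footprint.
These presets are hand-tuned test data that emulate an observed pattern;
they are not predictions about real arrays. Construction is fully
deterministic given the spec; isotropic Gaussian noise (σ in Å) is
applied after assembly under the spec seed, with ground truth recorded
pre-noise. Non-bonded base pairs (more than 4 positions apart along the
DNA) closer than 10 Å raise a warning and set a flag, never silently.

**What passing tests do and do not show.** The generator produces ideal
superhelices, straight-to-smooth linkers, isotropic noise and a perfectly
known core register. Real data adds curvature within the core, sequence-
dependent geometry, partially resolved base pairs, register uncertainty
and anisotropic coordinate error. Tests on the generator therefore verify
the *measurement machinery* — that angles, deviations, stacking calls and
classifications are computed correctly and robustly — not that any
biological system behaves like the presets.

# Numerical choices

- Orthonormality, equivariance, superposition identities: 1e-9 (absolute,
  degrees or unitless). Frame degeneracy (collinear anchors): cross
  product below 1e-6.
- Angle deltas use the atan2 form, exact at zero; acos-based angles lose
  ~1e-7 degrees near coincidence.
- Projections with in-plane norm ≤ 1e-9 of the vector norm are undefined
  (`NA`), flagged, never zero.
- Kabsch uses SVD with the determinant sign guard, so a proper rotation
  is returned even for near-planar inputs; fewer than 3 points or
  collinear references are errors.
- The noisy-recovery study (σ = 0.5 Å, the resolution-scale coordinate
  error of the intended use) scores the fraction of *angle measurements*
  (α and β pooled) within 3° of truth, required ≥ 95%. Per angle this
  holds with margin; requiring both angles of a replicate simultaneously
  would demand ~1.2° accuracy from a frame whose gyre baseline is a
  single pitch (25.9 Å) and is not attainable at this noise level.
  Validation sizes: a 9×9 noise-free grid and 200 noisy replicates, which
  keep the full study under a few seconds.
- Report files print angles at 3 decimals; `NA` cells stay `NA`.

# Limitations

- The reference shipped with the package is synthetic; absolute Δα/Δβ
  values against it are internally consistent but only comparable to
  published per-structure values when a user supplies the corresponding
  deposited reference coordinates to `run_analyze()`.
- Linkers are summarized by one vector per side; per-base-pair helical
  parameters (roll/twist/tilt) are out of scope.
- The steric screen uses coarse spheres, not van der Waals radii, and the
  stacking interface classes are geometric labels only.
- Base pairing is positional (registry-declared, antiparallel); the
  package never infers pairing from geometry or sequence.
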