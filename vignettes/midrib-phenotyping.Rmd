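---
title: "Correcting and phenotyping 3D-digitized leaf midribs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting and phenotyping 3D-digitized leaf midribs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(midribr)
```

## The measurement problem

A contact 3D digitizer records an ordered sequence of key points along a
maize stalk (about five node points, bottom to top) and along the midrib of
the ear leaf (base to tip, more points where the leaf bends). Two error
processes degrade these data. First, the whole recorded plant is tilted and
offset because stalk-node points are probed on alternating sides of a
several-centimetre-thick stalk. Second, individual midrib points deviate
from the true curve: a small background error at the scale of the device
accuracy (about 0.25 cm), and occasional gross fluctuation errors when the
probe slips. The midrib itself, in its natural state, is a smooth space
curve — so deviations reveal themselves as spikes in curvature.

`midribr` estimates the underlying smooth midrib curve from one noisy
sample and derives fifteen shape traits plus an architectural type from it.
The estimator is exposed in the classic R modelling idiom: `fit_midrib()`
returns a `midrib_fit` object with `print()`, `summary()`, `coef()` (the
trait vector), `predict()` (points on the fitted curve), `residuals()`
(raw-point displacements), `simulate()` (re-digitization from the fit) and
`plot()` methods.

## The correction chain

`fit_midrib()` runs five stages.

1. **Broken-midrib QC.** The discrete (Menger) curvature of every interior
   raw key-point triple is computed; if any exceeds `broken_thre` (default
   0.2 1/cm, strict inequality) the sample is marked invalid — a midrib that
   sharp at the raw sampling scale is snapped or mis-probed, not shaped.
   This runs on raw points, before any interpolation, so that inserted
   points cannot dilute the test.
2. **Positive-direction correction.** A total least-squares line (principal
   axis of the centred points) is fitted to the stalk nodes; ordinary
   single-axis regression is ill-posed for near-vertical stalks, which is
   why the fit is total. The whole sample — stalk and midrib together — is
   rotated about the stalk centroid so this axis becomes +Z. The axis sign
   is taken upward (positive z component), so a stalk file recorded
   top-to-bottom yields the same frame.
3. **Equidistant interpolation.** Each raw segment of chord length
   \(D_m\) receives \(N = \lceil D_m / D_b \rceil - 1\) linearly
   interpolated points at uniform fractions (`D_b` = 4 cm), capping the key
   spacing at `D_b`. Original and inserted points are flagged.
4. **Cubic B-spline densification.** Every key segment is evaluated at
   \(t = g/(c+1)\), \(g = 1..c\) (`c` = 30) with the uniform cubic basis
   \[F_0 = (1-t)^3/6,\quad F_1 = (3t^3-6t^2+4)/6,\quad
     F_2 = (-3t^3+3t^2+3t+1)/6,\quad F_3 = t^3/6,\]
   using the control window \((P_{m-1}, P_m, P_{m+1}, P_{m+2})\). The dense
   curve interleaves the key points with the evaluated nodes —
   \(n + (n-1)c\) nodes for \(n\) keys — and carries per-node analytic
   curvature \(\kappa = |r' \times r''|\,/\,|r'|^3\) and cumulative arc
   length.
5. **Curvature-constrained iterative correction.** Dense nodes with
   \(\kappa >\) `kappa_thre` (0.004 1/cm) are flagged and mapped to their
   owning key point. For each flagged interior key point a correction plane
   is built through the midpoint of its two neighbours with normal along
   their chord, and the point is moved to the crossing of the smoothed
   curve with that plane nearest to its current position (orthogonal
   projection onto the plane if the curve does not cross). The pass repeats
   until nothing is flagged, nothing moves, or `max_iter` (20) passes have
   run. The base and tip are never modified.

### Numerical choices in the correction step

Three choices in stage 5 deserve justification because the obvious
alternatives degrade clean geometry.

**Crossing against the smoothed nodes only.** The dense curve contains the
key points themselves; a key point generically lies *on* its own
correction plane (the plane is the perpendicular bisector of its
neighbours), so a crossing search over the full dense polyline would
always return the key point itself and the correction would be a no-op.
The crossing is therefore computed against the spline-evaluated nodes
alone.

**The natural-sag deadband.** Snapping a key point onto the spline is, on
average, the smoothing mask \((1/6, 4/6, 1/6)\) — a contraction. A clean
key point on an arc of curvature \(\kappa\) and spacing \(h\) sits about
\(\kappa h^2/6\) off the uniform B-spline even with zero noise, and with
`kappa_thre` = 0.004 1/cm every naturally curved midrib (typical
\(\kappa\) 0.01–0.08 1/cm) is flagged at every node, every pass. Without a
guard, each pass would pull every curved midrib toward its chord and
twenty passes visibly flatten the leaf. A flagged point is therefore moved
only when its displacement *perpendicular to the local chord* exceeds
\(1.5\,\kappa_{\mathrm{arm}} h^2/6\) (floor 0.02 cm), where
\(\kappa_{\mathrm{arm}}\) is the Menger curvature over a ±4-key arm —
wide enough that single-point noise averages out of the reference. The
tangential component of a displacement is ignored by the trigger because
it is reparameterization, not error. On a noiseless circular arc the
correction then has a fixed point (zero passes); a kinked or slipped point
still exceeds its deadband and is corrected.

**Boundary windows by reflection.** End segments use phantom controls
\(P_0 = 2P_1 - P_2\) (and mirrored at the tip) rather than replicated
endpoints. Replication makes the spline start at \((5P_1 + P_2)/6\) — a
sixth of a segment away from the measured base — and inflates curvature in
the end pieces, which the iteration then "corrects" by dragging near-end
points inward. Reflection makes the spline interpolate base and tip
exactly (a natural end condition).

Interpolated points are corrected like any other flagged node but are never
re-derived from the current chords: re-running the interpolation each pass
was tried and rejected, because refreshing the chord points re-creates the
chord's inward sag relative to the already-corrected keys and the iteration
contracts curved regions collectively. The frozen interpolated points act
as anchors. One exception: when a measured point receives a gross
correction (≥ 1 cm — the probe-slip scale), its chord's interpolated
children follow with the interpolation-weighted share of the displacement,
so a slipped chord does not anchor the curve to the slip.

## Direction-plane normalization and the fifteen traits

Before trait extraction the curve is put in a canonical frame: base at the
origin, growth axis +Z (from stage 2), and the midrib's main plane rotated
into XOZ — a total least-squares line is fitted to the XY projections of
all dense nodes and rotated onto the X axis, sign chosen so the tip has
\(x \ge 0\). Leaves with horizontal extent under `min_horizontal` (1 cm)
keep the identity rotation and are flagged; every horizontal-plane trait is
zero for them by construction.

With \(S\) the dense arc length, \(s(i)\) the arc position of node \(i\),
and \(i^\*\) the first node of maximal height:

| Trait | Definition | Unit |
|---|---|---|
| TipTop | 1 if \(z(i^\*) - z(\mathrm{tip}) >\) `epsilon_z` (0.1 cm) | 0/1 |
| LeafLength | \(S\) | cm |
| LeafAngle | angle between +Z and the chord from the base to the node at arc length \(\min(s_{\mathrm{angle}}, 0.1S)\), `s_angle` = 5 cm | deg |
| HorizontalLength | \(\max_i \sqrt{x_i^2+y_i^2}\) | cm |
| OutwardGrowthMeasure | HorizontalLength / \(S\) | – |
| UpwardGrowthMeasure | VerticalHeight / \(S\) | – |
| VerticalHeight | \(z(i^\*)\) | cm |
| CurvaturePos | \(s(\arg\max \kappa)/S\) (first index on ties) | – |
| CurvatureRatio | base-to-tip chord / \(S\) (1 = straight) | – |
| DeviationAngle | absolute azimuth of the basal chord relative to the fitted main plane | deg |
| DeviationTip | \((S - s(i^\*))/S\) — the drooping arc fraction | – |
| MaxCurvature | \(\max_i \kappa_i\) | 1/cm |
| MaxWindingRate | max azimuthal turn per arc length over key-point chords | deg/cm |
| WindingRatePos | arc position of that maximum / \(S\) | – |
| ProjectionArea | shoelace area of the \((x,z)\) node polygon closed tip→base | cm² |

The 5 cm basal chord for LeafAngle and DeviationAngle mimics how a
field angle ruler is held against the leaf base; a first-segment tangent
would be far too noise-sensitive. The winding rate is evaluated on
key-point chords (the digitizing scale) and only where both adjacent
segments have at least 1 mm of horizontal magnitude: on dense
sub-centimetre segments, near-planar curves produce azimuth flips divided
by ~0.1 cm arc steps and the rate explodes; even at the chord scale this
remains the least stable pair of traits. ProjectionArea uses the
main-plane (XOZ) projection — the ground-plane projection of an open curve
has no meaningful area. All arg-max ties break to the smallest index, and
ratio traits are clamped to \([0, 1]\).

## Classification

The deflection flag is independent of the base type:
`DeviationAngle > 10°` (strict). The base type is the first match in a
fixed priority order — drooping (tip more than `epsilon_z` below the
base), creeping (`VerticalHeight < 12` cm), vertical
(`LeafAngle < 25°` and straightness ≥ 0.95), tip-curved (tip droops below
the highest point while the base-to-highest sub-curve is ≥ 0.95 straight),
bending (`MaxCurvature > 0.05` 1/cm or straightness < 0.75), and stretch
as the catch-all. Drooping and creeping fire first because they are the
most specific geometric facts; a drooping leaf also has large curvature
and must not be consumed by the bending rule. Only the 10° deflection
cutoff is fixed by convention; the remaining thresholds are
`midrib_control()` parameters with the defaults above, and
`archetype_specs()` provides seven constructed curves — one per type —
that pin the intended semantics in the test suite.

## The synthetic digitizer

`midrib_spec()` defines a ground-truth midrib by arc-length integration of
an inclination profile \(\varphi(s) = \theta_0 + \kappa_0 s + \kappa_1
s^2/2\) and a horizontal azimuth drift \(\alpha(s) = \psi s\). This
minimal family — linear curvature profile plus constant drift — spans all
seven architectural types. Ground-truth traits are computed by the *same*
trait code on the dense (0.1 cm) noise-free curve, so parameter-recovery
benchmarks test the correction chain, not trait-definition agreement.

`digitize_plant()` emulates acquisition: five stalk nodes on a vertical
axis with per-node vertical (0.5 cm) and horizontal (0.2 cm) offsets, a
whole-plant tilt drawn up to 5°, and midrib key points sampled at 5–9 cm
arc intervals, denser (the bottom of the range) where the true curvature is
in its upper quartile. The sampling interval never drops below 5 cm: below
that spacing, centimetre-scale probe jitter alone drives the raw Menger
curvature past the broken-midrib threshold, so a denser protocol would be
self-defeating for a noisy operator (for spacing \(d \ge 5\) cm the Menger
curvature of a displaced triple cannot exceed \(1/d \le 0.2\)).

Interior key points receive a two-component error: background device noise
plus occasional probe slips (probability 0.1, sd 3 cm), with the background
sd derived so the marginal per-coordinate sd equals `sigma` (default
1 cm → background 0.33 cm). A single iid Gaussian of the same magnitude
produces raw data far *cleaner* in rank order (trait \(R^2\) vs truth near
1) than real digitizer campaigns show, while the slip mixture reproduces
the characteristic raw-data signature — most points good, a few grossly
off — that curvature-based correction is designed for. The base and tip
are anatomical landmarks (collar, apex) and get device-scale noise only
(0.25 cm): an operator places the probe deliberately there, and the
smoother pins them, so modelling them as sloppy would make parts of the
leaf-angle error irreducible by construction.

Population draws (`generate_population()`) sample specs uniformly from
ranges calibrated once so the noise-free trait distribution matches
published maize ear-leaf population statistics (mean leaf angle ≈ 39°,
upward growth ≈ 0.47, vertical height ≈ 30 cm): length U(40, 95) cm,
base angle U(5, 70)°, \(\kappa_0\) U(0, 0.018) 1/cm, \(\kappa_1\)
U(0, 4e-4) 1/cm², \(\psi\) U(−0.5, 0.5) deg/cm. Everything is seeded and
byte-reproducible.

What the generator does **not** emulate: leaf blades (only the midrib
line), multi-leaf canopies, S-shaped curvature profiles (sign changes in
\(\kappa\)), spatially correlated probe drift, and digitizer calibration
drift within a session. Passing recovery benchmarks therefore show that
the correction chain removes the modelled error classes — they do not
certify performance on error structures outside this family.

## Validation harness and problem sizes

`run_recovery_benchmark()` generates a seeded population, processes every
sample twice — traits from the raw key-point polyline and from the full
smoothing chain — and compares both against ground truth with per-trait
RMSE, \(R^2\), and the RMSE reduction \(1 - \mathrm{RMSE}_s /
\mathrm{RMSE}_r\). The packaged benchmark uses 150 plants at the default
noise model, the scale at which population summaries stabilize while a
full run stays comfortably in interactive time; `scripts/acceptance.R`
re-runs it from scratch at a caller-supplied seed.

Two accuracy limits of the defaults are worth knowing. First, a leaf angle
measured on a 5 cm basal chord has an error floor of several degrees under
centimetre-scale interior jitter — the chord target sits inside the first
raw segment, whose direction no smoother can recover beyond what the
neighbouring keys constrain — so the benchmark's leaf-angle recovery
improves far less than leaf length or vertical height; at device-scale
noise (σ ≈ 0.25 cm) the floor drops proportionally. Second, the dense
curve interleaves key points with spline nodes, so arc-length-derived
traits carry a small positive bias (≈ 0.9% on a noiseless 40 cm
quarter-circle fixture, the package's closed-form regression test).

## Known limitations

* The smoother pins base and tip; errors in those two points propagate
  untouched into every trait referencing them.
* Curvature below the key-point sampling scale is unidentifiable; the
  dense-curve curvature is the *spline's* curvature, and its maximum can
  sit slightly above the geometric value where key spacing is uneven.
* The seven-type classifier uses fixed thresholds on four traits; border
  cases (e.g. vertical height within millimetres of the creeping cutoff)
  flip type under noise. The deflection flag is the only threshold with an
  external convention behind it.
* Winding-rate traits are reported but intrinsically unstable; treat them
  as qualitative.
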