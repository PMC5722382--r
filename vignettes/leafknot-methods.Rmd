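---
title: "Capturing self-intersecting leaf outlines: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capturing self-intersecting leaf outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafknot)
```

## The problem and the model

Automatic leaf contouring assumes the blade is a single thresholdable
region. Leaves with touching lobes (TL) or overlapping lobes (OL)
violate this: part of the margin is hidden under another lobe or seals
off a sinus, so the silhouette boundary is not the leaf outline. Under
transillumination, however, optical density encodes tissue thickness —
background bright, blade mid-gray, overlaps (double thickness) darkest —
and every component of the true outline becomes recoverable from one
image.

`leafknot` models the outline as a closed polygonal ring that may cross
itself (at the two cross points flanking each overlap) and touch itself
(at each touch point). The pipeline is: two-level segmentation, region
tracing, junction localization, pairwise concatenation, and elliptic
Fourier description. This vignette records the scientific and numerical
choices behind each stage; the README shows the user-facing workflow.

## Segmentation

Two thresholds are computed on the 256-bin histogram.

**Maximum entropy (T1).** The Kapur–Sahoo–Wong criterion maximizes the
sum of the dark-class and bright-class Shannon entropies, each
normalized to its own probability mass; evaluation is exhaustive over
all 255 candidates and ties resolve to the smallest threshold, so the
result is deterministic. On a trimodal transilluminated histogram the
optimum isolates the small dark overlap class: splitting off a narrow
mode costs little class entropy while the bright side keeps its full
two-mode mixture term. On a leaf without overlaps (bimodal histogram)
the same criterion lands near the blade/background split instead —
there is no third class to isolate.

**Intermeans (T2).** The classic bimodal fixed point
`t ← ⌊(μ(≤t) + μ(>t))/2⌋`. The iteration starts at the midpoint of the
*occupied* intensity range, not at bin 127: with a tiny dark overlap
class, a start below the blade mode converges onto the overlap/blade
split (the dark-class mean never leaves the overlap mode), which is not
the whole-leaf threshold the method is meant to produce. From the
occupied-range midpoint the fixed point is the blade/background split.
Cycle detection guards the loop; convergence is typically 3–6
iterations.

**Mask polarity and composite.** T1 selects the dark class and is
inverted; T2 keeps everything at or below it. Their XOR makes the blade
black and background, overlap outlines and closed sinuses white — each a
separately traceable region. Because automatic thresholds shift with
image composition and illumination, `threshold_panel()` rebuilds the
composite for every combination of t1 and t2 scaled by 0.95/1.00/1.05
(rounded, clamped to [0, 254]) — nine candidates for visual selection,
the center one bit-identical to the unperturbed composite.

**No-overlap detection.** Leaves with only touching lobes need a single
bimodal threshold; the XOR composite is degenerate there because both
thresholds estimate the same split. The pipeline uses the dual route
only when the dark class is both small (≤ 20% of pixels) and well below
the bimodal threshold (t2 − t1 ≥ 16 gray levels); otherwise it traces
the T2 mask directly, whose black holes are exactly the enclosed
sinuses. Both signals separate cleanly on realistic histograms — on the
generator's no-overlap presets the maximum-entropy threshold actually
lands *above* the intermeans one.

**Binary close.** A morphological closing (disk, default radius 2 px,
`radius = 0` disables) removes dark venation traces from the inverted
T1 mask before composition. Closing is extensive on the mask foreground:
it can only erase thin *dark* features, never bright ones — which is why
it removes 1-px venation while leaving the ≥ 8-px-wide overlap regions
intact (their right-angle corners are rounded by up to the brush
radius, which the junction rules tolerate).

## Tracing

Connected regions of the composite are labeled with the standard
duality — white 8-connected, black 4-connected — and every region that
does not touch the image border and has at least `min_area` (default
16 px², venation specks) pixels is traced. Both polarities are traced:
the blade is a black region, overlap outlines and sinuses are white
ones; the border-touching background is skipped. Boundaries come from a
Moore-neighbor walk over the region's own pixels, starting at the
topmost-then-leftmost pixel with a West backtrack; the walk is a
deterministic state machine and terminates exactly when it re-enters
its first state (pixel + backtrack), which is robust on 1-px
appendages where the naive "start seen again" rule fails. Vertices are
0-based pixel centers, x = column, y = row (y down); with these axes a
positive shoelace area is a clockwise screen tour. The largest-area
contour is the blade; any other region whose pixels are ≥ 50%
dark-class is an overlap outline, the rest are sinuses.

## Junctions

For each contour pair, all locally minimal vertex-pair distances within
`d_adj` (default 2.0 px — the composite places adjacent outlines 1–2 px
apart, across one-pixel walls) produce one junction each; minima closer
than `min_sep` (10) ring vertices to an accepted one are suppressed, so
long parallel stretches yield a single junction. The junction point is
the midpoint of the closest vertex pair. Kind follows region class:
any pair involving an overlap outline is a cross point, all others are
touch points. The junction graph must connect all contours; a
disconnected graph is reported with the unreachable contours named.
`junctions_from_points()` accepts user-supplied kinds/locations instead,
mirroring an interactive workflow.

## Concatenation

At a junction, with `a_c`/`b_c` the junction-nearest vertices and
`a1, a2, b1, b2` their ring predecessors and successors, segment
p joins a1–b2 and q joins a2–b1. Slopes and midpoint-form intercepts
are computed literally; Z is the line intersection; p and q intersect
iff Z lies in the range **common to both segments**. Two numerical
notes:

* The pooled bounding box of all four endpoints (reported in the
  `R` field) is necessary but not sufficient — Z can fall inside it on
  the *extension* of the shorter segment. Since intersection is an
  if-and-only-if condition, the decision uses the overlap of the two
  segments' coordinate spans, which is exactly segment intersection for
  non-degenerate configurations (verified against a cross-product
  oracle on 10⁴ random pairs, 100% agreement off collinear cases).
* Pixel contours routinely produce vertical chords, where the slope
  algebra is undefined (|Δx| < 10⁻⁹): an exact cross-product predicate
  substitutes there. Slopes within 10⁻⁹ of each other are parallel and
  never intersect.

Cross points require p, q to intersect, touch points the opposite;
failing that, contour B is reversed (reversal keeps the starting
vertex) and the test repeats — fixing *which* contour reverses makes
the procedure deterministic. The splice produces
`[a_c, b_c, b_c+1 … b_c−1, b_c, a_c, a_c+1 … a_c−1]`:
n_A + n_B + 2 vertices, both junction vertices duplicated. Junctions
are processed in ascending (x, y); at each step the two live contours
are found by union-find, the larger-|area| one plays A (the blade
absorbs its satellites and is never reversed), and `a_c`, `b_c` are
re-derived from the junction point on the current rings rather than
index-translated — simpler, and robust to the duplicated vertices
earlier splices introduce. Each splice reduces the live count by
exactly one.

The p/q condition has a useful reading: the spliced ring passes twice
through the `a_c`–`b_c` corridor, once as strand a1 → … → b2 and once
as b1 → … → a2, and p, q are precisely the chords of those strands'
endpoints — so "p and q intersect" *is* the condition that the two
strands cross transversally. A cross point therefore contributes
exactly one transversal self-intersection (two per overlapping lobe,
the "slalom" through its pair of cross points) and a touch point none.
`self_crossings_near()` measures this on the finished ring, counting
both proper edge crossings and corridor transversality by branch-angle
interleaving. Filling the final ring with the nonzero winding rule
(`fill_contour()`) recovers the leaf silhouette: overlap regions are
toured with doubled winding, enclosed sinuses with zero.

## Elliptic Fourier analysis

`efa_forward()` computes Kuhl–Giardina closed-contour coefficients
under cumulative chord-length parameterization; consecutive duplicate
vertices (spliced junctions produce them) are collapsed first because
zero-length chords are undefined. Self-intersecting rings are processed
identically — the parameterization follows the vertex chain, which is
what makes touch and overlap features part of the harmonic description.
No size/rotation/phase normalization is applied by default; the
coefficients are raw, and any normalization belongs to the downstream
ordination, where it should be an explicit, recorded choice.

One property worth stating precisely: under chord-length
parameterization only a *circle* is exactly one harmonic. An eccentric
ellipse's arc length is not its affine parameter, so harmonics leak
into the odd orders: a 2:1 ellipse yields first-harmonic semi-axes
(1.828, 1.073) rather than (2, 1), with ≈ 7% relative third-harmonic
amplitude and 99.4% of harmonic energy in harmonic 1 (99.95% for a
1.2:1 ellipse). The implementation was verified to four decimals
against an independent oracle (dense uniform arc-length resampling and
direct trigonometric projection); the unit tests freeze those oracle
values. Reconstruction error is monotone in the harmonic count, and 100
harmonics reproduce every preset's final ring — self-intersections
included — with RMSE below half a pixel.

## The synthetic generator

`make_leaf()` renders a transilluminated leaf with analytic ground
truth. The blade is polar-harmonic,
`R(θ) = R_max (1 − d/2 + (d/2) cos n(θ − θ₀))` with n = 4 lobes on the
diagonals, sinus depth d = 0.538 and R_max = 130 px on a 320 × 320
canvas. Closed-sinus features are *constructed*, not emergent: each
touch or overlap feature lives in an axis-aligned window on one of the
four sinus axes, where every wall, enclosed bay, overlap lens and
junction pinch is laid out in exact integer pixels. This is a deliberate
trade against visual realism: emergent intersecting-circle geometry puts
junction pinches at the mercy of rasterization (diagonally touching
white regions merge under 8-connectivity; a binary close erases thin
lens corners), whereas the template construction makes region classes,
junction kinds/locations and contour counts true *by construction* —
the generator can promise its ground truth instead of measuring it.
Two template details matter: all junction contacts are straight
parallel chain stretches (a junction at a one-pixel hairpin tip gives
the p/q test meaningless neighbor geometry), and the inner cross-point
pinch approaches the overlap lens from the bright side, which a binary
close cannot erase.

Gray levels default to background 230, blade 140, overlap 60 —
transillumination ordering, separated by ~13 σ of the default noise.
Noise is Gaussian (σ = 3 by default), truncated at ±3 σ and clamped to
[0, 255]; truncation guarantees the rendered class geometry equals the
constructed label map exactly, so ground truth survives any noise seed.
What the generator does *not* emulate: continuous intensity gradients at
edges (scanner PSF), illumination fields, petioles, natural margin
roughness, and realistically curved overlap lenses. Passing tests
therefore demonstrate the pipeline's topological and geometric
correctness under clean class separation, not robustness to poorly
illuminated or low-contrast scans — on real material the threshold
panel exists precisely because the automatic split can need a ±5%
nudge.

Presets: `simple` (open sinuses only, 1 contour), `tl` (two
touch-closed sinuses, 3 contours), `ol` (two overlap-closed sinuses,
5 contours), `both` (touching and overlapping together, 7 contours:
blade, 2 overlap outlines,
2 OL-closed and 2 TL-closed sinuses — the canonical worked example).
Features require the 4-lobe axis-aligned blade and a ≥ 300 px canvas;
anything else is rejected as infeasible rather than rendered wrong.

## Editing and I/O

`cut_contour()` splits a ring along a segment crossing it exactly twice,
inserting the exact sub-pixel intersection points and closing each part
with the chord — petiole removal, border-break repair (keep the larger
part) and separation of overlapped herbarium leaves are all this one
operation. Any other crossing count is an error reporting the count; on
a self-intersecting ring a transect can legitimately cross six times,
so cuts are placed across a single feature. XY files are plain text,
one vertex per line, tab-separated, no header (the ImageJ raw import
format); integers are written bare and fractional coordinates with
three decimals, so save/load round-trips are exact at written
precision. A comma dialect is available.

## Problem sizes and runtime

The test suite and acceptance script run the full pipeline on 320 × 320
images (contour rings of ~50–1900 vertices), 10⁴ random segment pairs
for the geometry oracle, and 100–270 harmonics for the Fourier checks;
the whole suite completes in well under a minute on one CPU. These
sizes were chosen to exercise every code path at pixel-exact ground
truth, not to benchmark: the algorithms are linear in boundary length
except junction search, which is quadratic in vertex counts per
contour pair and dominated by the blade ring (~10⁶ distance
evaluations here).

## Known limitations

* Junction detection assumes two contours per junction; three contours
  meeting at one point are not handled.
* One nesting level: regions inside overlap outlines are not expected.
* The no-overlap/dual-threshold decision is heuristic (dark-class mass
  and threshold separation); exotic histograms could misroute, in which
  case thresholds can be forced via `pipeline_config(t1 =, t2 =)`.
* Chord-length EFA slightly distorts eccentric shapes relative to their
  affine parameterization (see above); harmonic comparisons between
  methods must hold the parameterization fixed.
* JPEG input is rejected outright: lossy block artifacts corrupt the
  narrow dark overlap class that T1 depends on.
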