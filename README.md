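# leafknot

Leaf shape is a standard taxonomic character, and for most leaves the
outline is easy to obtain: threshold the image and trace the single
blade region. That breaks down for species — grapevine, fig, some maples
and chrysanthemums — whose lobes grow until they **touch** (TL) or
**overlap** (OL) each other. The true margin then runs through regions
that are hidden under another lobe or enclose a sinus completely, and no
single-region tracer can recover it. `leafknot` captures these complex
outlines automatically from transilluminated grayscale images, producing
one closed — possibly self-intersecting — contour that follows the real
leaf margin through every touch and cross point, ready for elliptic
Fourier shape analysis.

## Method

Transillumination turns tissue thickness into optical density: the
background is bright, the blade mid-gray, and wherever one lobe lies
over another the doubled thickness is darker still. The pipeline
exploits this with two thresholds on the 256-bin histogram:

* **T1** — maximum-entropy threshold (Kapur–Sahoo–Wong): the t
  maximizing `H_dark(t) + H_bright(t)`, the sum of the Shannon entropies
  of the two classes. It isolates the small dark overlap regions. The
  inverted dark-class mask is the T1 mask; thin venation traces are
  removed from it with a binary close (disk radius 2 px by default).
* **T2** — iterative intermeans (bimodal/isodata) threshold:
  `t ← ⌊(μ(≤t) + μ(>t))/2⌋` to a fixed point, started from the midpoint
  of the occupied intensity range. It separates the whole leaf from the
  background.

`T1_inverted XOR T2` yields a composite mask in which the blade is black
and the background, overlap outlines and enclosed sinuses are distinct
white areas. Every interior region (white 8-connected, black
4-connected, border-touching background excluded) is traced with a
Moore-neighbor boundary walk — seven contours for the canonical worked
example: blade A, two overlap outlines B and G, two OL-closed sinuses C
and F, two TL-closed sinuses D and E. A ±5% perturbation panel (3 × 3
composites) is available when the automatic thresholds need visual
checking. Leaves without overlaps need only T2; the pipeline detects
this and traces the single-threshold mask directly.

Adjacent contours are linked at **junctions**: locally minimal
vertex-pair distances below an adjacency limit (2 px). A junction is a
*cross point* when one contour is an overlap outline (the final outline
crosses itself there — twice per overlapping lobe, a "slalom" through
the pair of cross points) and a *touch point* otherwise (the outline
touches itself without crossing). Contours are then concatenated
pairwise. At a junction with nearest vertices `a_c`, `b_c` and their
ring neighbors `a1, a2, b1, b2`, the test segments are

    p = a1 – b2        q = a2 – b1

with slopes and midpoint-form intercepts as
`p_slope = (a1y − b2y)/(a1x − b2x)`,
`p_intercept = (a1y + b2y)/2 − p_slope (a1x + b2x)/2` (and the q
analogues); the candidate intersection is
`Z = ((p_intercept − q_intercept)/(q_slope − p_slope), p_intercept +
p_slope·Zx)`, and p, q intersect iff Z falls in the range common to both
segments. Cross points require p and q to intersect, touch points
require them not to; when the condition fails, the second contour's
orientation is inverted. The splice then opens A at `a_c`, tours B
completely from `b_c`, and closes back through `a_c` — one contour fewer
after every splice, ending in a single closed ring whose nonzero-winding
fill reproduces the leaf silhouette.

The final ring (self-intersections included — that is the point) is
described by Kuhl–Giardina elliptic Fourier coefficients under
chord-length parameterization, with truncated and stepwise inverse
reconstruction. Cut/repair utilities split rings along a line (petiole
removal, border-break repair, separating overlapped herbarium leaves),
and contours are exchanged as raw tab-separated XY coordinate files, the
format ImageJ imports directly.

A synthetic transilluminated-leaf generator with analytic ground truth
(region classes, junction kinds and locations, expected contour counts)
drives the test suite; presets `simple`, `tl`, `ol` and `both` cover
the four canonical leaf classes.

## Worked example

```r
library(leafknot)
lf  <- make_leaf(leaf_preset("both", seed = 7))  # leaf with 2 OL + 2 TL sinuses
res <- run_pipeline(lf$image)
print(res$set)
```

```
<contour_set: 7 contours on 320 x 320 canvas>
<leaf_contour C1: 1130 vertices, class BLADE, signed area 47177.0 px^2>
<leaf_contour C2: 148 vertices, class SINUS, signed area 1369.0 px^2>
<leaf_contour C3: 172 vertices, class SINUS, signed area 1408.0 px^2>
<leaf_contour C4: 50 vertices, class OL_OUTLINE, signed area 138.0 px^2>
<leaf_contour C5: 172 vertices, class SINUS, signed area 1408.0 px^2>
<leaf_contour C6: 50 vertices, class OL_OUTLINE, signed area 138.0 px^2>
<leaf_contour C7: 148 vertices, class SINUS, signed area 1369.0 px^2>
```

Seven regions: the blade, two overlap outlines and four enclosed
sinuses. Their junctions and the merge result:

```r
res$report$junctions[, c("kind", "x", "y", "a", "b", "distance")]
##    kind     x     y  a  b distance
## 1 CROSS  34.5 140.5 C1 C4 1.414214
## 2 CROSS  56.0 136.0 C3 C4 2.000000
## 3 TOUCH 160.0  56.5 C1 C2 1.000000
## 4 TOUCH 160.0 263.5 C1 C7 1.000000
## 5 CROSS 264.0 184.0 C5 C6 2.000000
## 6 CROSS 285.5 179.5 C1 C6 1.414214
print(res$contour)
## <leaf_contour C1+...+C7: 1882 vertices, class BLADE, signed area 41899.0 px^2>
print(res$efa)
## <efa_coefficients: 20 harmonics, perimeter 1949.8 px, center (160.0, 160.0)>
```

Each overlap outline carries two cross points (one against the blade,
one against the sinus it closes); each touch-closed sinus one touch
point. Six splices merge seven contours into one 1882-vertex ring
(`1130 + 148 + 172 + 50 + 172 + 50 + 148 + 2·6`): every splice
duplicates its two junction vertices.

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/leafknot.R synth --preset both --seed 7 --out leaf.png
Rscript inst/cli/leafknot.R run leaf.png --out out/       # leaf.xy, efa.csv, report.json
Rscript inst/cli/leafknot.R efa out/leaf.xy --n 20 --out coeffs.csv
```

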