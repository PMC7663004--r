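---
title: "Counting overlapping agave plants by iterative erosion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting overlapping agave plants by iterative erosion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agavecount)
```

## The problem

Blue agave is sown in rows roughly 3–4 m apart with 1.0–1.2 m between
plants, but a mature crown is 1–2 m wide or more — wider than the in-row
spacing — so in a nadir UAV view neighbouring plants overlap into
connected clumps. A plant-class segmentation of the orthomosaic (the
input this package expects: plant pixels in color on a black background,
at ~3 cm/px) therefore cannot be counted by plain connected-component
labeling: a clump of five crowns is one component.

`agavecount` separates and counts these clumps with flat binary
morphology only. Morphology needs no training data — a real constraint
for agave, where no labeled image corpus exists — and its two parameters
(a diameter threshold and the structuring-element shapes) have direct
physical readings.

## The pipeline and its assumptions

**Preprocessing** (`preprocess()`). The segmented RGB layer is collapsed
with the BT.601 luma weights $I = 0.299R + 0.587G + 0.114B$ and
binarized with the strict rule $I(r) > 0$: the upstream segmentation
paints background pure black, so any nonzero luminance is plant class.
The gray image stays in floating point; rounding before the threshold
could only lose dim nonzero pixels and buys nothing. Two repairs follow:

* *clean* — every 8-connected component with area below `min_area`
  (default 2, i.e. exactly the isolated single pixels) is removed. The
  area semantics is a deliberate choice: segmentation speckle at this
  resolution is single stray pixels, and anything larger may be a weed
  or a seedling that later stages should see.
* *fill* — every background region not 4-connected to the image border
  becomes foreground. Filling whole enclosed regions (not just
  single-pixel holes) is required because illumination artifacts punch
  multi-pixel holes in crowns, and an unfilled hole makes the later
  erosion fragment a plant from the inside out.

Foreground connectivity is 8, background connectivity 4 throughout — the
standard dual pairing, so an 8-connected ring always encloses its
interior.

**Object separation** (`separate_objects()`). Opening then closing with
the same 3×3 square element. Opening first is essential: it cuts necks up
to 2 px thick where crowns touch; the closing then restores the 1-px
boundary layer the opening shaved off plant bodies, and cannot re-create
a cut neck. Applying closing first would weld near-touching crowns
before the opening ever sees them.

**Counting** (`count_agaves()`). The iterative procedure:

1. label the connected components of the working image;
2. harvest every component with equivalent diameter
   $d = \sqrt{4A/\pi} < Th$ into the accumulating image $IS$, recording
   centroid, area and the capture iteration;
3. erode the remainder $IG$ with a diamond element of radius 2;
4. repeat from 1 until $IG$ is empty;
5. the count is the number of harvested fragments.

The physical picture: each erosion peels ~2 px off every clump boundary,
so the bridge between two crowns (thinnest where they interpenetrate
least) breaks before the crown cores shrink below threshold; cores then
drop below $Th$ one by one and are harvested as individual plants.

## Parameters

| parameter | default | units | reading |
|---|---|---|---|
| `th_px` | 13 | px | equivalent-diameter threshold; 39 cm on the ground at 3 cm/px — below this, a component is a single plant pattern |
| `erosion_se` | diamond:2 | – | city-block ball of radius 2 (13 px); its 90°-symmetric shape keeps counts rotation-invariant |
| `opening_se` | square:3 | – | neck cutter/repairer for the separation stage |
| `connectivity` | 8 | – | component adjacency |
| `strict_less` | TRUE | – | harvest on $d < Th$; `FALSE` gives $\le$ for sensitivity analysis |
| `max_iterations` | 200 | – | safety cap only; the termination bound below makes it unreachable for real images |

The threshold comparison is strict (`<`) because the operating rule is
that components with diameter *less than* 13 px are single-plant
candidates; the `<=` variant is provided purely to probe sensitivity at
the boundary.

**Diamond of size 2** is read as the city-block ball of radius 2
(13 pixels), the convention of mainstream morphology toolboxes,
including the one the original field workflow was built in.

## Numerical and boundary choices

* **Border policy.** Outside-image pixels are background for *every*
  operator. Plants touching the frame therefore erode from the border
  like interior plants, and closing a mask that touches the frame erodes
  its border ring — the price of treating all image content uniformly
  rather than inventing data beyond the frame. (Toolboxes differ here;
  some pad erosion with foreground. The package's tests pin this policy
  down explicitly.)
* **Coordinates** are 1-based `(row, col)` matrix indices, the R idiom,
  with pixel centers at integer coordinates; every CSV written by the
  package states this in a header comment.
* **Capture-before-erode.** Within each pass, harvesting precedes
  erosion, so a component that is already sub-threshold at iteration 1
  is captured intact. A component at or above threshold loses less than
  5 px of equivalent diameter per diamond-2 erosion if it is convex, so
  with $Th = 13$ no convex component can be annihilated uncounted.
* **Termination.** Each erosion shrinks every remaining component's
  bounding box by 2 in both directions, so the loop ends within
  $\lceil\max(H, W)/2\rceil$ passes; `max_iterations` is a safety net
  against adversarial inputs, not a tuning knob.
* **Fragment vs union counting.** Fragments harvested at different
  iterations can, rarely, touch in the binary union $IS$. The package
  counts *fragments* (each capture keeps its identity, stored in a label
  raster); `count_mode = "union"` gives the stricter
  components-of-the-union count, and `summary()` reports both so a
  divergence is visible. On all synthetic validation fields the two
  agree.
* **Determinism.** The counting pipeline consumes no randomness, and
  component labels are assigned in raster-scan order of each component's
  first pixel, so repeated runs are byte-identical.

## Matching detections to ground truth

The survey counts that motivated the metrics were scored visually by an
expert; a reproducible stand-in is needed. `match_detections()` uses
greedy one-to-one nearest-first matching within a radius, default 17 px
(≈ 0.5 m at 3 cm/px, half the in-row plant spacing): a detection is
credited only if it lies closer to a plant than to that plant's
neighbour. Greedy matching is order-free (pairs sorted by distance) and,
on the instance sizes that occur per clump, attains the same TP as
exhaustive optimal matching (property-tested against a brute-force
oracle).

`pooled_summary()` pools confusion counts over regions before computing
metrics (micro-averaging, $\Sigma TP/\Sigma GT$), which weighs every
plant equally; the macro-average of per-region accuracies — a different
number whenever regions differ in size — is attached alongside, clearly
labeled, rather than silently substituted.

## What the synthetic generator emulates — and what it does not

`generate_field()` produces the *segmented layer*, not the orthophoto:
circular plants in a flat green on black, on a jittered row lattice with
the plantation geometry above (defaults: rows every 117 px ≈ 3.5 m,
plants every 37 px ≈ 1.1 m, crown radii 16–33 px ≈ 1–2 m diameters).
Degradations mirror the failure modes the real workflow documents:

* *overlap* — with probability `overlap_prob` a plant is shifted toward
  its row neighbour until the disks interpenetrate by a few pixels; with
  the default radii, large neighbouring crowns also overlap by geometry
  alone, as in the field;
* *weeds* — Poisson-scattered disks of radius 1–4 px; the small ones are
  removed by clean/opening, the larger ones survive as false positives,
  the dominant FP source in real fields;
* *holes* — 1–3 small interior holes per affected plant (repaired by
  preprocessing, which is why fill exists);
* *dropout* — an angular sector (25–100%) of a crown erased, mimicking
  illumination loss; a fully erased plant stays in the ground truth and
  becomes a guaranteed false negative.

Every stochastic choice consumes a seeded base-R generator in a fixed
documented order, so fields are bit-reproducible across platforms.

The three presets sketch the surveyed fields' characters: `field1` wide
size heterogeneity and heavy overlap but little weed; `field2` moderate
overlap with weeds and illumination dropouts; `field3` homogeneous plant
sizes with the most weed. Unstated generator knobs (jitter 2 px, the
preset probabilities, the 585×900 px canvas holding ~115 plants) were
fixed once as realistic for ~3 cm/px plantations and are not fitted to
anything.

What the generator does **not** emulate: rosette leaf structure (crowns
are disks, so real erosion behaviour on spiky silhouettes is untested),
soil texture and segmentation noise beyond speckle, row curvature, and
spatially correlated illumination fields (dropout is per-plant
independent). Passing on synthetic fields therefore demonstrates the
counting mechanics — separation of overlaps, robustness to speckle,
holes and dropouts — not the upstream segmentation quality that
dominates real-survey error.

## Validation design

The test suite checks, at small fixed problem sizes chosen so the whole
suite stays comfortably interactive:

* exact agreement of all four morphology operators with a brute-force
  double-loop oracle on random 32×32 masks, plus the algebraic laws
  (duality away from the border, anti-/extensivity, idempotence of
  opening/closing, monotonicity);
* labeling against a BFS flood-fill oracle (both connectivities) and
  against EBImage's 4-connected `bwlabel` partition;
* the counting loop against an independent re-implementation built only
  from the oracle primitives, translation/90°-rotation invariance, the
  two-disk separation sweep (count goes 1 → 2 monotonically), and the
  termination bound;
* exact count recovery (error 0) on disjoint-disk fields across seeds —
  these use radii 10–16 px so that disks *cannot* touch at the 37 px
  spacing, isolating the no-overlap regime;
* metric identities and the nine-region survey table, reproduced to its
  printed 4 decimals from the raw TP/FN/FP/GT counts (two recall cells
  in that table are arithmetically inconsistent with
  $TP/(TP+FN)$ — transcription errors — and are excluded);
* end-to-end producer's accuracy on the presets, which stays within
  [0.80, 1.0] over seeds (means ~0.92–0.99), bracketing the 0.83–0.98
  range reported for the real fields.

## Known limitations

* A plant smaller than the threshold that overlaps a large neighbour so
  deeply that it erodes away before the neck breaks is silently merged —
  the same failure the field survey attributes to overlap.
* Non-convex fragments left by sector dropout can split under erosion
  and yield duplicate detections (counted as FPs by the matcher).
* The threshold is calibrated in pixels; imagery at a different ground
  sampling distance needs `th_px` rescaled (`threshold_ground_cm()`
  makes the conversion explicit).
* Fields whose segmentation is not black-background ("0 is background")
  must be re-encoded before `binarize()` applies.
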