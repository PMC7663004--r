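# agavecount

Counting blue agave plants (*Agave tequilana* Weber) in UAV-derived,
pre-segmented crop-layer images with binary mathematical morphology.

The number of agave plants in a plantation is a key input for estimating
tequila production, and in Mexico it is still mostly counted by hand.
Given an orthomosaic of a field at roughly 3 cm/px ground sampling
distance and a plant-class segmentation of it (e.g. a k-means crop layer:
plant pixels in color, background black), `agavecount` turns that layer
into a per-plant count plus per-plant centroids — including in the hard
case where neighbouring plants overlap, because 1–2 m plant crowns are
wider than the 1.0–1.2 m in-row spacing.

## The method

For a segmented layer with channels R, G, B:

1. **Preprocessing.** Gray conversion `I = 0.299 R + 0.587 G + 0.114 B`,
   binarization `I(r) > 0`, removal of isolated specks, and filling of
   enclosed holes, giving the clean binary image `Ic`.
2. **Object separation.** Opening then closing with a 3×3 square
   structuring element `B`: `Io = (Ic ⊖ B) ⊕ B`, `Icl = (Io ⊕ B) ⊖ B`.
   The order matters: opening first cuts the thin necks where crowns
   touch, closing then repairs plant bodies without re-joining them.
3. **Iterative erosion counting.** Repeat: label the connected
   components; every component whose *equivalent diameter*
   `d = sqrt(4·area/π)` is below the threshold `Th` is harvested into the
   accumulating image `IS`; the remainder `IG` is eroded with a diamond
   structuring element of radius 2 (`IG = IG ⊖ B`), which pinches
   overlapped clumps apart; stop when `IG` is empty. The plant count is
   the number of harvested fragments.

The default `Th = 13` px corresponds to 39 cm on the ground at 3 cm/px.
Detection quality against expert ground truth is summarised with
confusion-matrix metrics: producer's accuracy `Pacc = TP/GT`, user's
accuracy `Uacc = TP/(TP+FP)`, `recall = TP/(TP+FN)` and the average
accuracy `Acc = (Pacc + Uacc)/2`, with greedy one-to-one centroid
matching within a 17 px radius standing in for visual expert matching.

Because no survey imagery is publicly available, the package also ships a
seedable synthetic field generator (`generate_field()`) that emulates the
segmented layers: jittered row lattices (row spacing 3.5 m, plant spacing
1.1 m, crown diameters 1–2 m at 3 cm/px), along-row overlap, weed
speckle, interior holes and illumination dropouts, with exact ground
truth — so the whole pipeline is testable end to end.

## Worked example

```r
library(agavecount)

# a synthetic field in the style of the second surveyed field:
# moderate overlap, weeds, illumination dropouts
f <- generate_field(field_presets("field2", seed = 7))
f
#> synthetic field: 585x900 px, 115 plant(s), 26 weed(s), seed 7

res <- run_pipeline(f)       # preprocess -> separate -> count -> evaluate
res$count
#> agave count: 128 plant(s) in 15 iteration(s) (585x900 image)
res$metrics
#> TP 109  FN 6  FP 19  GT 115
#> Pacc 0.9478  Uacc 0.8516  recall 0.9478  Acc 0.8997
```

Of the 115 plants, 109 were found (6 missed: fully dropped out of the
layer or fused with a neighbour), and 19 of the 128 detections are
spurious — almost all of them weed blobs large enough to survive the
cleaning, exactly the failure mode real weeds cause. Per-region counts
pool across regions with `pooled_summary()` (micro-averaging,
`Σtp/Σgt`); the nine-region survey counts shipped with the package give

```r
fc <- agave_field_counts()
pooled_summary(lapply(seq_len(nrow(fc)), function(i)
  confusion_counts(tp = fc$tp[i], fp = fc$fp[i], fn = fc$fn[i])))
#> TP 1851  FN 216  FP 116  GT 2067
#> Pacc 0.8955  Uacc 0.9410  recall 0.8955  Acc 0.9183
#> macro-averaged Acc over regions: 0.9225
```

A thin command line covering the same operations (`count`, `evaluate`,
`synth`, `metrics`, `run`) lives at
`system.file("cli", "agavecount.R", package = "agavecount")`.

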