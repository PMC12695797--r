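# orchardvision

Detection and metric 3D localization of apples in orchard imagery, built for
robotic-harvesting research. Deep detectors need large annotated datasets and
GPUs and still return only 2D boxes; `orchardvision` implements the
alternative: an unsupervised, clustering-based pipeline that segments fruit
by hue, recognizes it by fused colour/texture/shape evidence, and
triangulates each fruit to millimetre coordinates from a rectified stereo
pair — cheap enough for real-time use on a CPU.

## The method

**Segmentation.** RGB frames are denoised (Gaussian + median), converted to
HSI, and clustered on the hue plane H = atan2(√3(G−B), 2R−G−B) with an
enhanced K-Means: initial centers are chosen adaptively by a density score

&nbsp;&nbsp;&nbsp;&nbsp;C_k = argmax_i P(i) · Σ_{j∈N(i)} 1 / (‖H(i)−H(j)‖ + ε),

which places them inside large hue-homogeneous regions (fruit, foliage,
shadow), and assignment uses the weighted Euclidean distance
D(x,y) = √(Σ_m w_m (F_m(x)−F_m(y))²). The fruit cluster is cleaned by
morphological opening/closing, touching fruit are separated by a
distance-transform watershed with adaptive refinement, and boundaries come
from erosion-and-subtract.

**Recognition.** Each candidate region is scored by the fusion

&nbsp;&nbsp;&nbsp;&nbsp;T = α₁·H + α₂·GLCM + α₃·Shape,

combining circular hue closeness to the variety reference, a gray-level
co-occurrence texture statistic, and circularity 4πA/P²; regions with
T ≥ 0.6 become detections with hue-weighted sub-pixel centroids and
least-squares (Kåsa) circle fits.

**3D localization.** SAD block matching along rectified rows with left-right
consistency and sub-pixel refinement yields disparity d; triangulation gives
Z = fB/d and X = (c−c₀)Z/f, Y = (r−r₀)Z/f. The localization error is
E = √(ΔX²+ΔY²+ΔZ²).

**Evaluation.** Recognition accuracy RA = 100·TP/(TP+FN), mean coordinate
deviation (MCD, % of the image diagonal), correct recognition rate (CRR, %
of true fruit reaching IoU ≥ 0.5), precision/recall/F1, single-class AP,
per-distance depth error, and angle-stability standard deviation.

Because the original orchard imagery is not public, the package ships a
synthetic stereo scene generator (`scene_spec()`, `render_scene()`) that
emulates the stated survey conditions — red or green apples on green
foliage, fruit overlap up to a controlled occlusion budget, day/night
brightness, ±20% brightness jitter, ±15° orientation jitter, Gaussian pixel
noise, depths of 800–1700 mm — with exact per-apple ground truth, so every
stage is testable end to end.

## Worked example

```r
library(orchardvision)

spec  <- scene_spec(n_apples = 10, apple_color = "red", seed = 3)
scene <- render_scene(spec)
res   <- detect_scene(scene$left, scene$right,
                      config = pipeline_config(), rig = scene$rig)
round(res$detections[, c("row", "col", "radius", "score", "Z_mm")], 2)
#>       row    col radius score    Z_mm
#> 1  268.36 673.67  27.40  0.96 1126.83
#> 2  233.50 643.07  26.72  0.96 1450.13
#> 3   69.60 709.33  24.42  0.94 1120.49
#> ...
#> 9   25.75 694.66  22.20  0.92 1633.33
#> 10  39.20 668.74  15.69  0.87  881.00

m <- match_detections(res$detections, scene$truth)
recognition_accuracy(m)
#> [1] 100
```

Each row is one fruit: sub-pixel image centroid (`row`, `col`), fitted
radius in pixels, fusion score in [0,1], and triangulated depth in mm.
All ten apples are recovered, including two overlapping pairs; comparing
`Z_mm` with `scene$truth$depth_mm` shows sub-1% depth agreement (e.g.
1633.3 mm recovered against a true 1619.9 mm at the far end of the range).

A thin command-line front end over the same functions lives at
`inst/cli/orchardvision.R` (`synth`, `detect`, `evaluate`,
`depth-validate` subcommands).

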