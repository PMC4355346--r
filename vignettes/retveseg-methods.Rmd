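---
title: "Methods: retinal vessel segmentation by diffusion and directional morphology"
author: "retveseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal vessel segmentation by diffusion and directional morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retveseg)
```

## The problem and the model

A colour fundus photograph shows the retinal vessel tree as dark,
elongated, locally straight structures on a brighter background, with the
optic disc (OD) as the brightest compact region and a circular field of
view (FOV) surrounded by a dark camera frame. Because every vessel
converges on the OD, its bright rim is the main source of false vessel
detections; the pipeline therefore locates and removes the OD before it
extracts vessels. All images are 8-bit-per-plane RGB; the green plane
carries the strongest vessel/background contrast, the red plane the
clearest OD.

The pipeline is a deterministic composition of five stages
(`segmentVessels()` runs them all and keeps every intermediate):

1. **FOV mask** (`buildFovMask`). Green-plane pixels above 10 grey levels
   form the raw mask; a 1-px-disc opening removes speckle, 4-connected
   border clearing removes frame-connected clutter, and internal holes
   are filled. The stage also yields the mask's 15-px dilation (used to
   clean raw OD candidates) and its 10-px erosion (used to cut the bright
   outer circle from the vessel mask).
2. **OD segmentation** (`diffuse` + `segmentOD`). The red plane is
   smoothed by eight-neighbour Perona–Malik diffusion,
   $I \leftarrow I + \psi \sum_{d} C(\nabla_d I)\,\nabla_d I$ with
   diffusivity $C(g) = 1/(1 + (g/k_a)^2)$, so the OD boundary survives
   while texture flattens. Iterative mean-split (isodata) thresholding of
   the diffused plane, intersection with the dilated FOV, and
   largest-component selection give the OD mask, centroid and area.
3. **OD elimination** (`eliminateOD`). OD pixels are replaced by zero
   (default) or by the mean background intensity in the green plane.
4. **Vessel enhancement** (`orientationResponses`, `maximumResponse`).
   The working image is the inverted green plane restricted to the FOV
   (openings preserve *bright* structures, vessels are dark). Twelve line
   structuring elements — 10 px long, at 15°…180° in 15° steps — each
   produce a greyscale opening; the pixelwise maximum over the twelve
   responses preserves every vessel along its best-aligned direction.
5. **Vessel extraction** (`extractVessels`). The maximum response is
   isodata-thresholded into a binary image $G$; the disc top-hat
   $G - \mathrm{open}(G, \mathrm{disc}(15))$ keeps structures thinner
   than the disc and removes bulk regions; the result is intersected with
   the eroded FOV, components with fewer than 50 pixels are removed, and
   OD pixels are excluded.

Evaluation (`confusionCounts`, `segMetrics`, `datasetReport`) is
pixel-wise with vessel as the positive class:
$Se = TP/(TP+FN)$, $Sp = TN/(TN+FP)$, $Acc = (TP+TN)/\mathrm{all}$,
counted inside the FOV by default (the dark surround would otherwise
inflate $Sp$ and $Acc$ with trivially correct negatives; full-frame
counting is available by omitting the FOV argument). Dataset averages
are unweighted per-image (macro) means.

## Tunable parameters

All parameters live in a layered YAML configuration
(`defaultConfig()` < file < overrides; `loadConfig()` rejects unknown
keys and out-of-range values by name). YAML was chosen as the
configuration format: flat, typed, comment-friendly, with a mature
parser.

| key | default | unit | role |
|---|---|---|---|
| `diffusion.psi` | 1/8 | — | explicit update rate; ≤ 1/8 guarantees the discrete maximum principle with eight neighbours |
| `diffusion.kappa` | 30 | grey levels | edge scale $k_a$: gradients below it diffuse, above it persist; 30 separates vessel/OD edges (≥ 45 grey levels) from noise (σ ≈ 3) on 8-bit images |
| `diffusion.iterations` | 15 | steps | enough to flatten background texture without rounding the OD rim |
| `threshold.t0` | 15 | grey levels | isodata start value; out-of-range starts fall back to the range midpoint (below) |
| `threshold.tol` | 0.5 | grey levels | convergence tolerance on successive thresholds |
| `threshold.fov_only` | TRUE | — | class means over FOV pixels only (below) |
| `mask.green_threshold` | 10 | grey levels | raw FOV cut; `"auto"` runs the isodata procedure instead |
| `mask.open_radius` / `dilate_radius` / `erode_radius` | 1 / 15 / 10 | px | FOV cleanup, OD-candidate cleaning, outer-circle trim |
| `od.channel` / `od.fill` | red / zero | — | diffusion input plane; OD replacement value |
| `vessel.line_length` | 10 | px | oriented template length |
| `postprocess.s_size` | 15 | px | top-hat disc radius: keeps structures thinner than 15 px |
| `postprocess.min_component` | 50 | px | minimum surviving component size |
| `postprocess.connectivity` | 8 | — | 8-connectivity; vessels are thin diagonal structures that 4-connectivity would fragment |
| `postprocess.eq10` | tophat | — | `"literal"` reduces the extraction identity to plain erosion (audit mode; erases all thin structures) |

The diffusion constants $\psi$, $k_a$ and the iteration count are not
dictated by the method itself; the defaults above are standard
Perona–Malik practice for 8-bit imagery and are deliberately
conservative ($\psi = 1/8$ is the stability bound).

## Numerical and design choices

**Isodata initialisation.** The threshold loop splits values at $T$,
recomputes the two class means, sets $T$ to their midpoint, and stops
when $T$ moves less than `tol` (cap: 100 iterations; the sequence is
bounded by the value range, so it always terminates). If the start value
lies outside the value range it falls back to the *range midpoint*
rather than snapping to the nearest extreme: a start at the extreme puts
every pixel in one class and parks the iteration on a degenerate fixed
point at the minority tail (on an FOV-restricted fundus histogram this
returns a threshold inside the background mode and floods the OD mask).
Midpoint initialisation is standard isodata practice. If one class is
empty at some step its mean is taken as the current $T$, which keeps $T$
fixed and terminates cleanly on near-constant images; a constant image
returns that constant with an empty, flagged mask.

**FOV-restricted histograms.** Both threshold stages compute class means
over FOV pixels only (`threshold.fov_only`). With the dark surround
included, the isodata split lands between surround and retina, the
subsequent mask multiplications become no-ops, and the top-hat stage
empties — the staged figure sequence (bright OD candidates; thin bright
vessels in $G$) is only reproducible with the restriction. Full-frame
histograms remain available for audit.

**Extraction identity.** As printed, the extraction identity
$I = G - (G - G \ominus s)$ collapses algebraically to plain erosion by
$s$, which would erase every structure thinner than 15 px — i.e. every
vessel — and contradicts the staged outputs the method reports. The
implementation therefore uses the disc top-hat
$G - \mathrm{open}(G, \mathrm{disc}(15))$, which does what the
surrounding text describes (keeps thin structures, removes bulk
regions). The literal reduction is preserved behind
`postprocess.eq10 = "literal"` and the equality of that mode with plain
erosion is asserted in the test suite.

**Structuring elements.** Disc($r$) contains exactly the integer offsets
at Euclidean distance ≤ $r$ from the origin (library disc definitions
vary; this one is fixed and tested). Line($L$, $\theta$) contains
exactly $L$ distinct cells rasterised along the dominant axis through
the origin, angles counterclockwise from the +column axis, 180° ≡ 0°.
Border rules: erosion treats out-of-image cells as foreground (the frame
never erodes the FOV), dilation as background. Greyscale erosion/
dilation are min/max filters with the same conventions; openings are
erode-then-dilate and idempotent.

**Border clearing and holes.** Structures 4-connected to the frame are
removed by reconstruction from a border marker (binary flood fill;
greyscale reconstruction-by-dilation with the image minimum as floor).
Hole filling after border clearing is an addition: vessel shadows can
punch holes into the raw FOV mask and the downstream erosion would
widen them; it is config-disableable (`mask.fill_holes`).

**OD stage.** After thresholding the diffused plane, candidates are
intersected with the *dilated* FOV and only the largest 8-connected
component is kept — the thresholded image can retain interior bright
lesions or speckle, and the OD is by construction the dominant bright
blob. An image with no bright region yields an empty result (area 0),
not an error. Zero fill is the default OD replacement; mean fill is
offered because a zero-filled disc is re-inverted into a bright blob in
the vessel working image, which nudges the isodata class mean (and hence
the vessel threshold) upward by a few grey levels; the final OD-mask
exclusion removes the blob itself either way.

**Determinism.** No stage draws random numbers; segmenting the same
image twice is bit-identical.

## The phantom generator

`generatePhantom()` renders the structure the pipeline assumes, with
exact ground truth: a circular FOV (radius 0.47 of the image side) on a
black surround; an OD disc (radius 18 px; red 230, green 180 on a 90/70
background) with its rim softened by a 2-px Gaussian; a vessel tree
grown by a seeded random walk from the OD rim outward (6 roots, 3-px
steps, branching probability 0.02 per step, initial width 4 px decaying
×0.7 at each branching with a 1-px floor, heading jitter 0.05 rad per
step so paths drift only ≈ 5° per template length, as real vessels do);
vessels darken the green plane by 45 grey levels (blue by a quarter of
that; red untouched); Gaussian noise (σ = 3) is added last; intensities
are clamped to [0, 255]. Truth masks (vessel, OD, FOV) are the exact
geometric sets, rendered before noise and without anti-aliasing;
anti-aliasing (a 0.5-px Gaussian on the stroke field) applies to the
intensity image only.

Each sample consumes one private seeded stream in a fixed order — OD
placement (when drawn), tree, noise — so switching noise off never
reshuffles geometry, and regeneration under the same spec and seed is
bit-identical. The caller's RNG state is saved and restored.
`generatePhantomSuite(n, baseSeed)` draws OD centres uniformly inside
the FOV with seeds `baseSeed … baseSeed + n − 1`.

**What the phantom does not emulate** — and hence what passing tests do
*not* establish about real data: lesions (microaneurysms, haemorrhages,
exudates), non-uniform illumination and colour casts, central vessel
reflexes, JPEG artefacts, vessel tapering with eccentricity, background
texture, and inter-observer ambiguity in the ground truth. Phantom
metrics are calibration checks of the pipeline mechanics, not estimates
of benchmark performance.

**A structural property worth knowing.** At the phantom's 256×256 scale
the FOV radius is ≈ 120 px, so the 10-px FOV erosion that removes the
bright outer circle discards ≈ 16% of the FOV area
($1 - (110/120)^2$) — and with it the roughly proportional share of
ground-truth vessel pixels lying in that rim annulus, which bounds
attainable sensitivity well below 1 before any detection error (at
DRIVE scale, FOV radius ≈ 270 px, the same erosion costs about half
that). The suite's measured sensitivities reflect this geometry; the
acceptance report (`scripts/acceptance.R`) computes them afresh on every
run rather than quoting numbers here.

## Known limitations

- No GIF decoding (DRIVE's manual/mask files need converting to
  PNG/TIFF/PPM first; dataset layout patterns are configurable).
- Thin (≈ 1-px), strongly curved or short (< 10 px) vessel segments are
  below the resolution of a 10-px, 15°-spaced line bank; the method
  cannot recover them by design.
- The hard binary output has no probabilistic score, so ROC analysis
  does not apply.
- Evaluation choices (FOV-only counting, macro averaging) materially
  affect specificity and accuracy; comparisons across tools must match
  them.
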