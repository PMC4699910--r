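---
title: "Methods: from plate video to walk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plate video to walk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormpath)
```

wormpath quantifies the locomotory behavior of a single *C. elegans* crawling
on an agar plate, from raw grayscale frames to a statistical classification of
its search strategy. This vignette explains each stage's model and
assumptions, the parameters that matter, and the design choices made where
the problem was genuinely open.

## Segmentation and the centroid

A worm on agar images as an elongated dark blob (roughly 1 mm by 0.06–0.25 mm
depending on optics) on a lighter, noisy background that also carries
immobile dark nuisance objects — salt precipitates, air bubbles, agar dents.
Per frame the chain is:

1. **Gaussian smoothing** (`sigma`, default 1 px). Homogenizes intensity
   across the worm body so uneven illumination does not punch holes in the
   segmentation. The kernel is truncated at 3 sigma and renormalized at the
   borders, so constant images are exactly invariant.
2. **Adaptive ratio threshold** (`threshold_ratio` 0.80, `window` 25 px). A
   pixel is on-worm when its intensity is below 80% of its local window
   mean. The ratio form makes the rule insensitive to slow illumination
   gradients; the window (about 2–3 worm widths at 128 px/mm, implemented as
   the window's intersection with the image at borders) must be wide enough
   to contain background next to any body pixel.
3. **Morphological closing** with a disc of diameter `disk_width` (default
   5 px, about one worm width). Fills interior holes left by bright patches
   on the body. Pixels outside the image count as background for both the
   dilation and the erosion, so masks near the border are not guaranteed to
   be supersets of the input there.
4. **Largest 8-connected component.** Nuisance blobs are smaller than the
   worm, so the maximal-area component is taken as the body; 8-connectivity
   keeps diagonally-touching body pixels together, and area ties break
   toward the component seen first in raster-scan order.
5. **Centroid**: the unweighted mean of on-pixel x and y coordinates
   (x = column, y = row, 0-based, origin top-left).

A frame is *discarded* (not interpolated) when the component's area falls
outside `[min_area, max_area]` or when the body touches the image border.
Two details matter:

* Border contact is judged on the **pre-closing** threshold pixels in the
  component's neighborhood, because the erosion half of closing pulls masks
  2 px away from the border and would otherwise hide genuine edge contact.
* `min_area` should sit between the largest nuisance blob (after closing) and
  the smallest plausible worm remnant. For the bundled synthetic world
  (20 px/mm, worm about 185 px²) the pipeline defaults to 60 px²; at the
  native 128 px/mm optics the default band is 50–5000 px². If `min_area` is
  set below the artifact size, a frame whose worm is lost at the edge can
  return an artifact as a "valid" worm.

When a dark artifact lies within about half a body length plus the closing
bridge of the worm, the threshold-and-close chain genuinely produces one
merged blob; the centroid then blends worm and artifact and there is no
single-blob ground truth. Keeping such contacts rare is the tracker's job
(below); the segmentation fidelity tests therefore score sub-pixel accuracy
on contact-free frames and only coarse localization on contact frames.

## Difference-image tracking

The recording loop keeps the worm in the camera view by simple motion
detection: a reference frame captured after each camera move is subtracted
from the current frame, so everything immobile cancels exactly and only the
moving animal remains. This package re-implements the loop offline (virtual
camera over a recorded or rendered world, `track_stream()`): the difference
image is Gaussian-smoothed (`diff_sigma` 2 px) and its peak taken as the worm
estimate; when the estimate drifts beyond `recenter_frac` (25%) of the view
from center, a camera move re-centers the view and refreshes the reference.
After 20 frames and the first camera move, the search is restricted to a
crop window (`crop_size`) around the last estimate.

**Difference polarity.** The subtraction leaves *two* blobs: the worm at its
current position, and a "ghost" of opposite sign where it sat when the
reference was captured. With an absolute difference the ghost is exactly as
strong as the worm, and once the crop window locks onto the ghost the camera
stops following. Because the worm is darker than the agar, the package
defaults to the signed, clipped difference `max(reference − current, 0)`,
which lights up only where the scene *darkened* — the worm's new position —
and leaves the ghost black. `polarity = "light"` mirrors this for bright
subjects and `"abs"` retains the symmetric form.

The peak of the smoothed difference rides the moving end of the body, so the
raw tracker estimate is only accurate to about a body length; it is used for
re-centering only, while path positions come from segmentation. Subsampling
(`subsample_hz`, default 10 Hz) gives the worm time to move between
comparisons so it does not subtract itself out.

## Path reconstruction and movement features

Per-frame centroids live in view coordinates; adding the logged camera
offset and dividing by the calibration (`calibration`, default 128 px/mm
from a 1280×960 sensor over a ~10 × 7.5 mm field) yields the global path in
millimetres relative to the initial camera position. Invalid frames become
gaps; features are never computed across a gap.

Movement features are windowed finite differences over `delta` (default
1 s): speed, acceleration, heading, angular speed. Two conventions:

* Heading uses the **two-argument arctangent**, so left- and rightward motion
  are distinguished over the full circle (−180°, 180°]; a plain arctangent
  would fold the plane onto two quadrants and make turn detection
  unreliable.
* All angular differences are wrapped to (−180°, 180°] before division by
  `delta`, so a 350° right turn is a −10° turn, never +350°.

Zero displacement leaves heading undefined (flagged `NA`, with the previous
heading carried forward inside the step detector).

## Cell occupancy and locality

The plate is divided into square cells of `cell_size` (1 mm, about one body
length); occupancy `O_k` is the number of distinct cells visited during
interval `tau` (60 s). The grid anchors at the floor of the path's minimum
coordinates by default; anchoring is exposed because counts can shift by a
boundary cell. Visitation is sample-based — a cell crossed between samples
without a sample landing in it is not counted — which slightly undercounts
at high speed or coarse sampling; this matches centroid sampling and is a
documented limitation.

Locality `L_k = E[v_k] / O_k` divides the interval's mean instantaneous
speed by its occupancy: a fast worm circling inside one cell scores high
(area-restricted, "local" search), a dispersing worm scores low. Since
intervals are equal-length, `E[v_k]` is proportional to distance travelled,
so L contrasts effort with fresh area searched.

## Turning events and step lengths

The path is resampled at `dt` (1 s) by nearest-valid-sample selection (gaps
longer than `dt` break the path; steps never span breaks). Walking the
resampled points, the reference heading `phi_p` is set at the most recent
turning event; when the current inter-sample heading deviates from it by
more than `theta`, a turning event is declared at the vertex where the new
segment starts. The first point of every contiguous segment is an event by
definition. A step is the Euclidean chord between consecutive events.

* `theta` defaults to 40°: the head of a worm moving straight swings roughly
  ±30°, so 40° separates genuine course changes from gait wiggle.
* `phi_p` is by default the heading the step *sets out with* (first segment
  after the event); the alternative — the heading *into* the previous event —
  is available via `reference = "inbound"`. The outbound reading makes an
  event mean "the course established at the last turn has changed".
* A terminal step from the last event to the final sample is appended so the
  path is fully partitioned; without it, a long final relocation — exactly
  the kind of step that decides a heavy tail — would be silently dropped.
* Zero-length sampled segments carry the previous heading forward.

Decreasing `theta` can only add events, so step counts are monotone in the
threshold; a curvy path yields many short steps and a straight one few long
steps.

## Power-law fit and walk classification

Step lengths of a Lévy flight follow a power law `p(S) ~ S^-alpha` above
some lower cut-off `xmin`. The tail exponent is the continuous maximum
likelihood estimate

```
alpha_hat = 1 + n / sum(log(S_j / xmin)),   S_j >= xmin,
```

which is scale invariant and errors out distinctly when all tail values
equal the cut-off. The cut-off is chosen by the standard
Kolmogorov–Smirnov scan: every distinct observed step value whose tail
retains at least `min_tail` (10) points is tried, the exponent fitted on its
tail, and the KS distance between the empirical tail CDF and the fitted
model CDF computed; the candidate minimizing the distance wins, ties
breaking toward the smaller cut-off (larger tail, more power). The KS
statistic is computed on cumulative distributions — a density-based distance
is ill-defined for continuous samples — so the `distance` column of the
bundled reference table, which may be on a density scale, is not directly
comparable to the distances this package reports. No goodness-of-fit
bootstrap is computed; only the distance is reported.

Classification follows the standard exponent regimes: `alpha <= 1`
ballistic (non-normalizable tail), `1 < alpha <= 3` **Lévy flight**
(normalizable, divergent variance — clusters of small steps broken by rare
long relocations), `alpha > 3` **Brownian** (finite variance, diffusive).
Fits are restricted to the first `window_minutes` (20 min) of a recording by
default, the window over which food-deprived worms show the local-to-global
transition.

**Variance of the cut-off estimate.** On composites (noise below a true
cut-off, power law above), the KS objective has a flat valley across the
pure-power-law region: nested tails give strongly correlated distances, so
the argmin wanders over tens of neighboring candidates even though the
*value* of the estimate concentrates near the true onset (median at the
truth, most runs within ~10%). Single-run cut-offs should therefore be read
with that spread in mind; the exponent is much more stable.

## The synthetic world

Because the original recordings are not required, every stage is testable
against generators with known ground truth:

* `simulate_trajectory()` draws Brownian walks (correlated random walk;
  wrapped-normal turns, Rayleigh speeds), Lévy walks (Pareto(α, 0.3 mm)
  straight relocations at constant speed, uniform directions), ballistic
  courses, and a two-phase local-then-global switch. Defaults — 0.15 mm/s
  mean speed, 20 min duration, 100 mm arena with reflecting walls — match a
  freshly food-deprived adult on a 150 mm plate. Seeds fix all randomness
  and the caller's RNG stream is left untouched.
* `render_view()` / `make_world_source()` draw the worm as a thickened,
  sinusoid-perturbed centerline oriented along the instantaneous heading
  (amplitude 0.08 mm), intensity ~70 on a noisy background of ~180, with
  immobile dark artifacts — enough to exercise segmentation and tracking,
  with no claim to postural biomechanics. The test world uses 20 px/mm and a
  200×150 px view so a full 20-minute virtual recording at 1 fps runs in
  seconds.

What the generators do *not* emulate: body-shape dynamics (omega turns,
reversals as postures), defocus blur during camera moves, illumination
drift, and multi-worm scenes. Passing tests therefore demonstrate the
correctness of the algorithms under controlled conditions, not robustness to
every artifact of real plate video.

## Problem sizes used by the test-suite

The suite validates the estimator on 200 Pareto samples of n = 1000 per
exponent, cut-off recovery on 50 seeded composites of n = 1000, segmentation
on 500 rendered frames, and closure (render → track → segment → reconstruct
→ steps → fit) on twenty 20-minute virtual recordings at 1 fps — sizes
chosen so the whole suite runs on a laptop in minutes while keeping Monte
Carlo error well below the tolerances tested.

## Known limitations

* Reversals and omega turns are not classified; a reversal appears only as a
  ~180° turning event.
* Sample-based cell visitation undercounts cells at coarse sampling.
* The tracker's virtual camera moves are instantaneous; motor dynamics and
  the blur they cause are out of scope.
* Alternative heavy-tail models (lognormal, truncated power law with upper
  cut-off) and likelihood-ratio comparisons are not implemented; a fit in
  the Lévy regime is consistent with, not proof of, a Lévy flight.
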