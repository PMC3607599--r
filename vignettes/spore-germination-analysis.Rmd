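---
title: "Timing germination and outgrowth of individual spores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing germination and outgrowth of individual spores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporeflow)
```

# The measurement model

A field of dormant *Bacillus* spores imaged with phase contrast shows bright
disks on a mid-gray background. Three spore-level processes are timed:

1. **Germination.** Water influx during germination collapses the refractive
   contrast: the spore center turns from phase-bright to phase-dark along a
   roughly sigmoidal intensity curve. Because the asymptotes of that curve
   are approached slowly, the event is timed relative to its own *drop
   range*: with settled intensities $I_\mathrm{pre}$ before and
   $I_\mathrm{post}$ after the transition, and
   $\Delta I = I_\mathrm{pre} - I_\mathrm{post}$, the start of germination
   is the crossing of $I_\mathrm{post} + 0.9\,\Delta I$, the end is the
   crossing of $I_\mathrm{post} + 0.1\,\Delta I$, and the germination time
   is their difference. This normalization makes the timing invariant to
   affine intensity changes (gain/offset), a property the test suite checks
   explicitly.
2. **Outgrowth.** The emerging cell's footprint area is tracked per frame;
   the outgrowth time is the interval from the end of germination to the
   first cell division.
3. **Vegetative growth.** Microcolony area doubles once per generation, so
   the generation time is the reciprocal of the slope of
   $\log_2 A(t)$ versus $t$ (slope in doublings per minute) over the window
   from first division to the end of the linear part of the plot. The area
   of the whole colony (including inner gaps) stands in for total biomass —
   an approximation that is exact only for large colonies but, applied from
   the first division on, has historically fit with correlation above 0.99.

Spores are scored into three fates: *outgrow* (germinated and divided),
*germinate-only* (turned dark but never divided within the movie), and
*dormant* (still phase-bright at the end; superdormant spores fall here).
Spores already dark at $t=0$ are flagged *pre-germinated*: they count as
germinated in the fractions but are excluded from timing statistics, since
their transition predates the movie. Two conditions are compared
metric-by-metric with an F-test on the variances at $\alpha = 0.05$,
followed by the pooled t-test if the variances are compatible and Welch's
t-test otherwise; fractions are compared as percentage-point deltas. No
multiple-testing correction is applied across the four timing metrics,
matching the protocol the package reimplements.

# Assumptions about the input

* Single-channel grayscale stacks, one field of view per stack, constant
  frame interval (typically 30–60 s), negligible stage drift. Any camera bit
  depth is accepted (8/16-bit integer or float); all thresholds can be
  re-expressed by the user, so no absolute intensity scale is assumed.
* Spores are isolated at $t=0$ (on the order of a dozen per field). Touching
  spores at $t=0$ are deliberately kept as one marker and censored when
  colonies meet, rather than split — the analysis is designed for sparse
  fields.
* The observation window is long enough (hours) that the fates of interest
  occur inside it; "dormant" always means "dormant within the movie".

# Tunable parameters

All parameters live in one `RunConfig` object; defaults are chosen so a
headless run on a typical stack needs no hand-tuning.

| parameter | unit | default | rationale |
|---|---|---|---|
| `brightThreshold` | intensity | `NA` → Otsu on frame 0 | the threshold is a researcher decision; Otsu is a reproducible default |
| `darkThreshold` | intensity | `NA` → background − half the bright contrast | marks a center as phase-dark; halfway to the dark phase separates cleanly |
| `colonyDelta` | intensity | `NA` → half the bright contrast | foreground cutoff for \|frame − background\|; catches bright spores and dark colonies alike |
| `centerRadiusPx` | px | 2 | center-region disk for intensity traces; small enough to stay inside the spore core at ~0.065 µm/px |
| `minSporeAreaPx`, `maxSporeAreaPx` | px | 5, 2000 | generous size filter; no size filter is inherent to the method |
| `settleTolerance` | intensity | 4 | plateau membership tolerance (≈ 2 camera-noise SDs in the simulated world) |
| `burstJumpFraction` | — | 0.2 | minimal single-frame relative area jump reported as a coat burst |
| `fitMinR` | — | 0.99 | quality bar for the final log2-area fit, from the reported typical fit quality |
| `collisionMarginPx` | px | 2 | "touching" is not defined quantitatively anywhere; two pixels of dilation is the smallest margin robust to rasterization |
| `divisionMaxErosion` | px | 6 | deepest erosion tried when looking for a two-object split |

# Numerical choices

**Plateau estimation.** $I_\mathrm{pre}$ is the median of the frames before
the first frame that drops more than `settleTolerance` below an initial
estimate (the median of the first five frames); $I_\mathrm{post}$ is the
median of up to ten frames starting at the first frame within
`settleTolerance` of the trace minimum. Medians over short windows are
robust to pixel noise; the two-pass scheme avoids biasing $I_\mathrm{pre}$
with transition frames.

**Crossing times.** The transition midpoint is located first (50% level);
the start is the *last* down-crossing of the 90% level before it and the end
the *first* down-crossing of the 10% level after it, each refined by linear
interpolation between the bracketing frames. Both crossings may fall inside
a single frame interval (an instantaneous drop yields a duration below one
interval, not zero). Traces with several large drops use the first sustained
one and log a warning.

**Background and segmentation.** The per-frame background is the median
intensity, which absorbs slow illumination drift — but flips to the colony
intensity once colonies cover more than half the field, so it is anchored
back to the frame-0 background whenever it moves further than `colonyDelta`
from it. A germinating spore passes *through* the background gray level
mid-transition; tracking therefore coasts over frames where the object
vanishes and re-acquires it at the original seed, instead of declaring it
lost. Components that fragment at the threshold during this fade are treated
as the spore's own pixels, not as colliding neighbors.

**Censoring.** A trace is censored (half-open: the censoring frame itself is
excluded) at the first frame where the component dilated by
`collisionMarginPx` meets foreign foreground of at least `minSporeAreaPx`
pixels, or comes within the margin of the image border. Increasing the
margin can only censor earlier, a monotonicity property under test. An
object that vanishes for good is truncated with the reason `lost` — an extra
reason beyond touching/end-of-movie, kept because lysis and defocus happen
in practice.

**Division detection.** The tracked footprint is eroded iteratively (up to
`divisionMaxErosion` 3×3 erosions); the earliest frame whose footprint
splits into at least two sub-objects above `minSporeAreaPx`, persisting for
two consecutive frames, is the automatic first division. This is a
shape-based stand-in for the manual marking the protocol originally used —
manual division times are therefore first-class overrides, recorded with
`source = "manual"` in the output.

**Fit window.** The window starts at first division. Rolling 10-frame
windows advance while their local slope stays at or above half the initial
post-division slope; the window ends with the last qualifying rolling
window. An |r| threshold on these *short* windows was considered and
rejected: at fine temporal sampling a 10-frame window spans a small fraction
of one doubling, so pixel-quantization noise alone pushes local |r| far
below any meaningful bar even for perfectly exponential growth. The 0.99
quality bar (`fitMinR`) is instead applied to the final fit over the whole
window — the scale on which it is meaningful — and fits failing it are
flagged `low_r`. Spores without a qualifying window (e.g. censored shortly
after division) are excluded from generation-time statistics; their n is
therefore smaller than the outgrown count, as in the original data.

# The simulator: what it emulates, what it does not

`simulateMovie()` renders, deterministically for a given seed: bright disks
for dormant spores; a logistic center-intensity drop whose scale is chosen
as $s = d/(2\ln 9)$ so that the 90%→10% crossings fall exactly at the
scripted start and start + duration (the timing definition holds for ground
truth *by construction*); a dark footprint that ramps to twice the spore
area at first division and then follows
$A(t) = a_0\,2^{(t-t_\mathrm{div})/g}$, rendered as a two-lobe shape after
division (the minimal geometry that exercises contour tracking and division
detection); persistent relative area jumps for coat bursts, constrained to
the outgrowth window; and Gaussian pixel noise added last. Population
scripts place spores on a jittered grid with guaranteed separation and
assign fates by exact counts, so scripted fractions are recovered exactly by
a correct classifier.

Defaults encode the studied conditions: 90 spores per experiment, one frame
per 30 s, 481 frames (4 h), 0.065 µm/px; an untreated population with 94.0%
germinating and 84.7% outgrowing, start of germination 63 ± 56 min
(lognormal), germination time 3.5 ± 0.9 min, outgrowth 254 ± 34 min,
generation time 62 ± 14 min; and a wet-heat-stressed population (85 °C,
10 min) with 52.9%/36.3% fractions, start 82 ± 68 min and germination time
5.3 ± 1.7 min. The test suite runs on a *compressed timeline* (short starts,
30-min outgrowth) so whole life histories fit desk-scale movies; fractions
and event definitions do not depend on the absolute time scale, and tests of
the timing arithmetic state their own scale.

The simulator makes no attempt at optical realism: no phase halos, no
shading, no focus drift, uniform object intensities, circular geometry. A
green end-to-end test therefore establishes that the *algorithms* implement
their definitions correctly on data that satisfy the model assumptions — it
does not establish robustness to optical artifacts of any particular
microscope, which still requires the manual-inspection overrides the tool
carries for that purpose.

# Known limitations

* Area-based growth rates average over the whole microcolony; per-cell
  growth rates inside a colony are out of scope.
* Stage drift and focus loss are not corrected; markers are fixed to frame-0
  positions.
* The division detector assumes near-convex pre-division shapes; long
  filaments could split spuriously under erosion (the two-frame persistence
  rule is the guard).
* With the published summary moments for the start of germination
  (63 ± 56 vs 82 ± 68 min at n = 171/152), the F-then-t procedure has
  power ≈ 0.78 at α = 0.05 — a property of those numbers, not of the
  implementation; the corresponding acceptance check documents this.
* The timing-statistics denominators are "detected events with valid
  plateaus", which can be smaller than the germinated counts used for the
  fate fractions; the source data show the same pattern without specifying
  the exclusions.
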