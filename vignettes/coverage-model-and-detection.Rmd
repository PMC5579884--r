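---
title: "Detecting small plants from CIE-Lab point readings: the models behind labweed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small plants from CIE-Lab point readings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labweed)
```

## The problem

Site-specific herbicide application needs a sensor that can look at a small
patch of ground (a circular *measuring spot* of roughly 20 cm² at a 5 cm
lens diameter), decide in real time whether a plant is under it, and — in a
second stage — which kind of plant. labweed implements the decision side of
such a system for *true-color* sensors that deliver readings in the CIE-Lab
color space: `L` is luminance (0 = black, 100 = white), `a` the green–red
axis and `b` the blue–yellow axis. Lab is convenient here because green
vegetation separates from mineral and soil backgrounds strongly in `L` and
`a`, and because the Euclidean distance

$$\Delta E = \sqrt{\Delta L^2 + \Delta a^2 + \Delta b^2}$$

is an established measure of perceived color difference ([`delta_e()`],
with the conventional perceptual bands in [`delta_e_category()`]).

Everything downstream rests on two empirical ingredients shipped as the
packaged database `lab_db()`:

* ten characterized **background surfaces** (seven anthropogenic — paving
  stones, asphalt, gravel, stone steps, fine chippings, red paving stones,
  sandy path — and three natural — bare arable land, grassland, grassland
  with dew), each with a per-channel mean and standard deviation; the
  standard deviation is the *noise* of that surface as the sensor sweeps
  over it;
* four **reference green tones** from bright to dark green, characterized
  by median, mean, minimum and maximum per channel.

## The mixing model

The simulator's — and the coverage model's — central assumption is
area-weighted linear mixing: a spot covered by a fraction $f$ of an object
over a background reads, per channel,

$$\mathrm{ch}_{MA} = (1 - f)\,\mathrm{ch}_{BG} + f\,\mathrm{ch}_{Obj},$$

so the reading moves along the straight segment from the background color
to the object color as the plant grows. This is an idealization of a
point-spectral sensor integrating reflected light over its spot; it ignores
shadowing, specular dew reflections and any nonlinearity of the optics. It
is also exactly the assumption that makes the three pieces below agree with
one another, which is why it is stated explicitly rather than buried.

## Detectors

Four detection rules are provided, all comparing one reading against the
calibrated background:

1. **`detect_delta_e()`** — fire when $\Delta E$ to the background mean
   strictly exceeds a threshold. Scenario presets from field practice ship
   as `threshold_preset()`: 5 for green objects on paved ground, 12 in a
   young wheat stand, 7 for broadleaf dock on grassland.
2. **`detect_channels()`** — per-channel thresholds on $|\Delta L|$,
   $|\Delta a|$, $|\Delta b|$ (typically 5/2/2 on paved ground), combinable
   as *any* or *all*. The triggered channels say *why* a reading is
   suspicious.
3. The **virtual d-channel** `virtual_d()`, $d = |a - b|$, an auxiliary
   feature: large for most greens, modest for most mineral surfaces.
4. **`detect_statistical()`** — the existence rule: an object exists if in
   at least one channel
   $$|\mathrm{ch}_{MA} - \mathrm{ch}_{BG}| \ge
     \sigma_{\mathrm{ch},BG} + \sigma_{\mathrm{ch},Obj}.$$
   No tuned threshold; sensitivity follows from calibrated noise.

Boundary conventions are deliberate constants, documented where they live:
the threshold detectors use strict `>` (a reading exactly at the threshold
does not fire), the statistical rule uses `>=` (a reading exactly at the
noise boundary does). Raising any threshold can only remove detections,
which the property tests assert.

## The minimum-coverage model

Combining the mixing model with the existence rule gives the smallest
detectable plant directly: a plant at coverage $f$ displaces channel
`ch` by $f\,|\mathrm{ch}_{Obj} - \mathrm{ch}_{BG}|$, so the rule first
fires at

$$A_{\mathrm{ch}} = 100 \cdot
  \frac{\sigma_{\mathrm{ch},BG} + \sigma_{\mathrm{ch},Obj}}
       {|\mathrm{ch}_{Obj} - \mathrm{ch}_{BG}|} \quad [\%].$$

`required_coverage()` computes one cell, `coverage_table()` the full
10 backgrounds × 4 greens × 4 channels grid, and `min_plant_area()`
converts percent coverage to cm² for a given lens (3% of a 5 cm spot is
about 0.6 cm²; of a 10 cm spot about 2.4 cm²). The consistency between
model and rule is asserted to 1 part in 10⁹ in the test suite: a noise-free
mixed reading at exactly $f = A/100$ sits on the existence-rule boundary,
for every background × green × `L`/`a`/`b` combination. The `d` channel has
no existence-rule boundary (the rule is defined on `L`, `a`, `b`), so its
coverage cells are reported as a derived screening quantity only.

Two conventions deserve emphasis:

* **Quarter-range σ for greens.** The reference green characterizations
  carry no standard deviation, only min/max. `sigma_of()` estimates
  $\sigma \approx |\max - \min|/4$ per channel — for small samples the
  range spans roughly four standard deviations. With it, the published
  bright-green luminance coverage cells reproduce exactly after one-decimal
  rounding (0.5% on bare field up to 6.5% on dewy grassland); cells in
  other channels deviate from the published grid by up to a few tenths to a
  few percent, because whatever σ the original characterization used is not
  recoverable. The convention is overridable per database entry and is the
  single most consequential interpretation in the package.
* **Absolute-difference denominator.** Dimensional consistency with the
  existence rule requires the plain absolute mean difference in the
  denominator (a squared difference would make $A$ unit-dependent), and
  only this form reproduces the published cells.
* **d-channel noise.** Where the `d` channel is tabulated, its noise is
  propagated conservatively as $\sigma_a + \sigma_b$, an upper bound on the
  standard deviation of $a - b$ under any correlation of the two channels.

## Green-tone classification

The multistage differentiation procedure is: flag suspicious readings with
$\Delta E$; inspect the individual channels; then compare all channels
*relative to each other* so that plant size drops out. `classify_green()`
formalizes the last step geometrically: under linear mixing the difference
vector $v = \mathrm{reading} - \mathrm{BG}$ equals $f \cdot u_g$ with
$u_g = \mathrm{green}_g - \mathrm{BG}$, so the *direction* of $v$
identifies the green regardless of $f > 0$. The classifier returns the
candidate maximizing the cosine similarity of $v$ and $u_g$. The virtual
`d` difference can join as a fourth component (`use_d = TRUE`) but is off
by default, being a function of `a` and `b`.

Exactness and limits, both established by the test suite: on noise-free
mixtures the true green is recovered with score 1 for all four greens on
all ten backgrounds at coverages from 2% to 50%. With realistic grassland
noise at 25% coverage, the two dark greens are recovered in ≥95% of draws,
but the two bright greens are confused with *each other* in roughly a fifth
of draws — their departure directions from grassland are only about 16°
apart, comparable to the angular noise. Direction matching removes size
dependence, not noise; plants much smaller than the spot classify less
reliably than they detect.

## The transect simulator

Field recordings of the original carrier runs are not published, so the
package ships a synthetic stand-in, clearly labeled as such:
`scene_spec()` + `make_transect()` sweep the circular spot along a track
(defaults emulate the stationary carrier: 150 cm at 0.1 m/s sampled at
10 Hz, i.e. one reading per cm) over a homogeneous background strewn with
disc-shaped objects. Per reading:

* coverage is the exact circle–circle intersection (`disc_overlap_area()`,
  lens formula, cross-checked against a Monte-Carlo rejection-sampling
  oracle) summed over objects and capped at 1 — summation is a documented
  approximation for overlapping objects, and the largest-overlap object
  supplies the green tone (per-reading multi-green mixing is out of scope);
* the color is `mixed_color()` with Gaussian channel noise whose σ
  interpolates linearly between background and object noise — the simplest
  model consistent with both endpoints, since nothing is known about the
  intermediate regime;
* ground truth (coverage fraction, dominant green) is recorded alongside,
  and the per-object overlap matrix is attached for object-level scoring in
  `evaluate_detection()`.

One seeded generator per transect makes identical scene specifications
bit-identical. What the simulator does *not* emulate — sun and shadow,
dew optics, wind-moved leaves, sprayer dynamics, real leaf shapes —
bounds what passing tests mean: they validate the algorithms under the
stated mixing and noise model, not sensor hardware in the field.

A simulated analog of the paved-ground detection run (grey paving stones,
four 1 cm-radius objects of the four greens, ΔE threshold 5) detects all
four objects with zero false-positive readings in well over 95% of seeds,
matching the qualitative field result that all green objects are filtered
out at that threshold.

```{r paved}
db <- lab_db()
objects <- data.frame(center_x = c(30, 60, 90, 120), center_y = 0,
                      radius = 1,
                      green = I(lapply(paste("Green", 1:4),
                                       function(nm) db_green(db, nm))))
tr <- make_transect(scene_spec(db_surface(db, "Grey paving stones"),
                               objects, seed = 1))
dec <- decide_stream(tr, db_surface(db, "Grey paving stones"),
                     "delta_e", t = threshold_preset("paved"))
evaluate_detection(dec, tr)[c("n_objects_detected", "fp")]
```

## Numerical choices and degenerate inputs

* Readings with non-finite channels are rejected at construction; values
  outside nominal gamut (e.g. `L` slightly above 100 after calibration
  drift) pass with a warning.
* Coinciding channel means make the required coverage infinite
  (`A = Inf` with a warning, not an error): the channel simply carries no
  signal. `A > 100` is representable and means "undetectable at full
  coverage".
* A reading exactly equal to the background mean has no direction and is
  rejected by the classifier, as are exact similarity ties (within 1e-12),
  which are reported with the tied candidates.
* Transcribed characterization tables are stored *as printed*; cells whose
  min/max ordering is impossible are flagged `suspect` in the database and
  the quarter-range convention uses `|max - min|` so a swapped pair is
  harmless.
* Sample (n−1) standard deviation throughout: calibration streams can be
  short.
* Test problem sizes: Monte-Carlo recovery tests use 10⁴ readings; the
  disc-overlap oracle uses 10⁶ rejection samples per configuration; the
  paved-ground detection claim is evaluated over 100 seeded transects of
  150 readings. These sizes put the Monte-Carlo standard errors well below
  the asserted tolerances.

## Deployment shape

The intended field loop (mirrored by the `labweed` CLI) is: calibrate the
background on a weed-free patch (`labweed calibrate`), pick the operating
mode — *positive* recognition sprays on any detection; *negative*
recognition suppresses spraying where the crop is detected — select
algorithm and database, run detection (`labweed detect`), and let each
decision drive one valve (`spray_decision()`). `labweed coverage-table`
prints the detectability grid for planning which channel to trust on which
background, and `labweed simulate` generates annotated synthetic transects
for bench-testing a configuration before mounting anything on a sprayer.
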