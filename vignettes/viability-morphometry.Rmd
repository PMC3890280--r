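---
title: "Color-threshold morphometry of NADH-TR stained muscle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-threshold morphometry of NADH-TR stained muscle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadhtr)
```

## The measurement

The NADH-tetrazolium-reductase (NADH-TR) reaction deposits blue-purple
formazan wherever mitochondrial dehydrogenase activity survives, so on a
cross-section of skeletal muscle the stained area marks metabolically intact
tissue. **Muscle fiber viability** is the area-fraction statistic built on
that observation:

$$
V = \frac{\left|\text{positive-stain pixels} \cap \text{fiber pixels}\right|}
         {\left|\text{fiber pixels}\right|},
$$

computed per photographed field, averaged over the fields of one animal
(ten per slide in the reference design), and finally expressed as a percent
of the mean of untreated control animals. Because slow oxidative (Type I)
fibers are mitochondria-rich and stain intensely while fast glycolytic
(Type IIb) fibers stain lightly, the same statistic is also computed per
fiber type, with the denominator restricted to that type's fiber area.

A pixel counts as *positive* when each RGB channel lies inside a closed
interval; the defaults are the published instrument settings — red 160/0,
green 130/0, blue 175/66, read as inclusive high/low bounds on the 0–255
scale and combined by AND. This matches the convention of commercial
threshold dialogs and the spectral signature of formazan (low red and
green, mid-to-high blue). Bounds are inclusive so that 8-bit data segment
deterministically; widening any channel interval can only grow the positive
mask (a property the test suite checks as a superset relation).

```{r thresholds}
channel_thresholds()
```

### Fiber delineation and typing

The published protocol measures "the total area of muscle fibers" without
describing how fibers were delineated; this package makes that step explicit
and parameterized. `segment_fibers()` marks pixels darker than
`luminance_factor` (default 0.92) times a high-percentile luminance
reference — the pale interstitium/background level — then applies
morphological closing (disc radius 2 px, meant to heal noise-pitted
outlines; set `close_radius = 0` for clean images) and hole filling, so
unstained patches *inside* fibers still count toward fiber area. A
`bg_floor` guard (default 180 luma) keeps the reference meaningful on
fields with no visible background at all.

Typing is per fiber object, not per pixel, because the protocol categorizes
*fibers*: each instance is scored by its mean optical density (255 − luma)
over its positive pixels (falling back to all of its pixels when none are
positive — an almost fully infarcted fiber is pale everywhere), and the
score distribution is split in two. The default split is an exact Otsu
threshold on the per-fiber scores, which assumes both types are present in
the field; a fixed-threshold mode is available for single-type fields.
Scores at the threshold go to the denser class, Type I, so the tie-break is
deterministic. A per-pixel fallback is deliberately not the default: with
object-level labels the two type masks partition the fiber mask exactly.

### Undefined fractions and normalization

A field with no Type I fiber has an *undefined* Type I viability, not a
zero; `field_viability()` returns `NA` and `animal_mean()` excludes such
fields from that measurement's average (with a warning) while keeping them
for the others. The original report never addresses this case; silent zeros
would bias group means downward, which is why exclusion was chosen.

Normalization is measurement-matched: Type I values are divided by the
control animals' Type I mean, Type IIb by the Type IIb mean, total by the
total mean. The reference table prints all three control means as exactly
100.0, which is only consistent with per-measurement normalization — and it
makes the control group's normalized mean 100.0 by construction, a property
the acceptance suite asserts exactly. Group summaries report mean ±
s.e.m. with the sample (n − 1) standard deviation.

## The synthetic-histology generator

No images were published alongside the reference study, so the package
ships a seeded generator whose ground truth makes the whole pipeline
testable by parameter recovery. One `synthetic_section_spec()` describes a
field:

* **Geometry** — `n_fibers` seeded random centres, one optional Lloyd
  relaxation pass (evens out fiber sizes), Voronoi tessellation, and an
  interstitial border carved where the distances to the two nearest centres
  nearly tie (`interstitium_width_px`, default 3 px). This is the simplest
  construction giving the close-packed polygonal adjacency of real muscle
  cross-sections.
* **Stain loss** — real injury presents as focal, droplet-like loss of
  formazan, so per-pixel i.i.d. deletion would be unrealistic. Instead a
  spatially correlated field (bilinearly upsampled coarse Gaussian noise
  with correlation length `patch_scale_px`, default 8 px) is thresholded
  *per fiber* at the empirical quantile that leaves exactly
  `retention(type) × control_coverage` of the fiber's pixels stained (to
  the nearest pixel). Pixel-exact targets mean the field-level ground truth
  equals the nominal condition up to rounding, which keeps the parameter
  recovery tolerance budget for the measurement itself.
* **Rendering** — stained pixels take the type's colour (defaults: Type I
  (70, 60, 130), Type IIb (130, 110, 160)), everything else the background
  (230, 225, 220); these are artifact choices constrained only to
  satisfy/violate the default positive predicate, which the spec
  constructor enforces. A multiplicative illumination ramp (default 5%
  darkening across the width) and Gaussian pixel noise (default SD 4) are
  applied last. Ground truth is recorded *before* noise, so noise can flip
  measured but never true classifications.

`control_coverage` (default 0.80) is the raw stained fraction of a fully
viable fiber at the default thresholds: healthy muscle stains strongly but
not wall-to-wall, and a ceiling below 1 leaves room for above-average
control animals. Because every group is normalized by the control mean, the
recovered percent-of-control values are insensitive to this choice.

The Type I probability `p_type1` defaults to 0.47, calibrated from the
reference table itself: total viability is the area-weighted mean of the
two per-type values, and the printed totals across the four ischemia
durations imply a Type I area share of 0.45–0.57 (mean ≈ 0.47).

### Condition presets and the study layout

`condition_preset()` encodes the seven-group design: untreated Control,
4/6/8/9 h ischemia, and 8/9 h ischemia + 2 h reperfusion. Ischemia-only
retentions are the printed normalized group means divided by 100 (e.g. 8I:
Type IIb 0.291, Type I 0.201). No numbers were printed for the reperfusion
groups; their defaults follow the qualitative findings — 8IR at the 9I
level, 9IR at one third of it ("near-complete cessation") — and are flagged
`uncalibrated` in the spec and in every ground-truth sidecar, so downstream
consumers can tell calibrated from extrapolated conditions.

`generate_study()` adds between-animal biology: per animal and fiber type,
the retention is jittered around the preset. Three design choices matter:

1. **Additive on the percent-of-control scale** (default SD 0.09): the
   printed s.e.m. are a roughly constant 3–6 points at every injury level,
   which an additive — not proportional — animal effect reproduces.
2. **Centred draws**: the jitter is forced to zero mean within each group,
   so the realized group-level ground truth *equals* the preset while the
   between-animal spread (hence the s.e.m.) is preserved. The presets are
   the study conditions being emulated; letting the 6-animal group mean
   wander around them would confound measurement error with sampling noise
   in a parameter-recovery benchmark.
3. **Feasibility by rejection**: draw vectors are redrawn until every
   animal's stained fraction lands in [0, 1]. This truncates the spread for
   groups near the floor, mildly shrinking their s.e.m. — as the printed
   table itself shows at 9 h.

All randomness flows from the single top-level seed; field specs carry
derived seeds, and a fixed seed reproduces the study bit for bit. Studies
are held as lightweight per-field specs and rendered on demand (a 240-field
study of 512×512 rasters would otherwise occupy gigabytes).

### What the generator does not emulate

The renderer is deliberately not photorealistic: no cutting or freezing
artifacts, no capillaries or nuclei, no intra-fiber texture, no chromatic
aberration, and — most consequentially — unstained fiber regions share the
interstitium's background colour. In real sections a dead fiber remains
visible as a pale outlined profile, so a human (or software acting on that
contrast) can still delineate it; in the synthetic rendering that cue does
not exist, and luminance-based fiber delineation is only reliable on
near-fully-stained fields. `segment_field()` therefore accepts the
generator's geometry as the fiber-instance source
(`instance_source = "truth"` in `measure_study()`, the default for
synthetic studies, including the acceptance pipeline), while the positive
mask — the measurement under test — is always recomputed from the rendered
image by colour thresholding. Passing parameter recovery consequently
validates the thresholding, area accounting, typing, averaging and
normalization chain, not fiber-outline discovery on degraded real-world
images.

## The statistical layer

The analysis plan mirrors the reference study: Shapiro–Wilk normality per
group, two-way fixed-effects ANOVA (condition × measurement) for viability
tables, Scheffé post-hoc comparisons between groups, and Pearson
correlation of viability against hours of ischemia (control = 0 h,
reperfusion groups excluded). ANOVA and Shapiro–Wilk delegate to R's
standard routines behind the package's interfaces (the test suite holds
them to brute-force sums-of-squares and naive-formula oracles); the Scheffé
procedure is implemented here: for groups $i, j$,

$$
S_{ij} = \frac{(\bar y_i - \bar y_j)^2}{MS_{res}(1/n_i + 1/n_j)},
\qquad
\text{significant} \iff S_{ij} > (k-1)\,F_{1-\alpha}(k-1,\ df_{res}),
$$

with $p = P\!\left[F_{k-1,\,df_{res}} > S_{ij}/(k-1)\right]$. Only balanced
complete designs are accepted (the reference design is n = 6 everywhere);
unbalanced input is an error pointing to this documented limitation, not a
silently approximate answer. α = 0.05 throughout.

Two open choices were settled as follows. The correlation can be computed
on per-animal values (n = 30 pairs, the default) or on group means (n = 5);
the original report does not say which it used, so both modes exist.
Post-hoc "between group" comparisons after a two-way ANOVA are taken on the
condition *marginal* means (all three measurements pooled, n = 18 per
condition) with the two-way residual mean square — the most powerful
reading consistent with the stated analysis; per-measurement one-way
comparisons can be had by passing a single-measurement table.

### The sensitivity harness and an honest discrepancy

`simulate_consecutive_power()` asks: at the printed effect sizes, with
within-group SD calibrated as printed s.e.m. × √6, how often does Scheffé
flag each consecutive-duration pair (Control–4I, 4I–6I, 6I–8I, 8I–9I) in a
simulated 6-animal study? The reference text reports all consecutive
differences significant at P < .001. The simulation shows that claim is not
reproducible from the printed summary statistics: the 8I–9I gap (24.3 vs
12.1, s.e.m. 5.7 and 2.9) corresponds to roughly t ≈ 1.9 on its own, and
even the pooled two-way Scheffé flags it in only about half of simulated
studies. The corresponding acceptance test states the ≥ 95% expectation and
fails; the package reports the discrepancy rather than recalibrating the
generator's variance below the published values to force agreement.

## Numerical and scale choices

* 8-bit arithmetic is exact: thresholds are integers, bounds inclusive,
  images rounded once at render time.
* Per-fiber stain targets are met by order statistics (the k smallest
  patch-field values), so ground-truth fractions are exact to one pixel per
  fiber and recomputable from the rasters.
* The field raster defaults to 512×512 px with 120 fibers (no pixel size is
  attached to the reference's "600×" magnification, so field size is a free
  parameter); unit tests run 96–256 px fields with 12–60 fibers, and the
  study-scale validations use the full reference design — 4 groups × 6
  animals × 10 fields at 512×512 — which runs in a few minutes on one core.
  The Voronoi nearest-two-seeds kernel is the only compiled code.
* `viability_study()` / `generate_section()` restore the caller's RNG state;
  reruns with the same seed are bit-identical, and tests assert it.

## Worked example

```{r example, fig.width = 5, fig.height = 4}
vs <- viability_study(c("Control", "8I"), n_animals = 3, fields_per_animal = 2,
                      seed = 42,
                      overrides = list(width_px = 192, height_px = 192,
                                       n_fibers = 30),
                      stats = FALSE)
vs$groups
plot(vs)
```

## Known limitations

* Parameter recovery certifies the measurement chain on idealized renders;
  stain batch effects, chromatic shifts and focus variation in real
  micrographs are out of scope (no color deconvolution or stain
  normalization is attempted).
* Otsu-based typing misclassifies fields that genuinely contain a single
  fiber type; use the fixed-threshold mode there.
* The ANOVA layer is balanced-only by design.
* Reperfusion presets are plausibility-scaled, not calibrated; treat `8IR`
  and `9IR` outputs as qualitative.
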