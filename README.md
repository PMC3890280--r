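# nadhtr

Color-threshold morphometry of NADH-tetrazolium-reductase (NADH-TR) stained
skeletal muscle cross-sections, for quantifying ischemic and
ischemia-reperfusion injury as **muscle fiber viability** — with a seeded
synthetic-histology generator that makes the whole measurement chain
testable by parameter recovery.

The NADH-TR reaction deposits blue-purple formazan in metabolically intact
fibers; loss of stain marks loss of viability. The package is for
experimental-surgery and muscle-pathology groups who score such sections by
software thresholding and need the full chain — segmentation, fiber typing,
area-fraction morphometry, control normalization, statistics — reproducible
and validated.

## The statistic

Per photographed field,

    V = |positive-stain pixels ∩ fiber pixels| / |fiber pixels|

where a pixel is *positive* when each RGB channel lies in a closed interval
(defaults: red ∈ [0, 160], green ∈ [0, 130], blue ∈ [66, 175] — the
published instrument settings "red: 160/0, green: 130/0, blue: 175/66").
Fibers are additionally typed by stain density — intensely stained Type I
(slow oxidative) vs lightly stained Type IIb (fast glycolytic) — and V is
recomputed per type over that type's fiber area. Field values are averaged
per animal (10 fields/slide in the reference design) and expressed as
percent of the untreated-control mean; groups are reported as mean ±
s.e.m. (n = 6). The statistics layer provides Shapiro–Wilk normality,
balanced two-way ANOVA (condition × measurement), Scheffé post-hoc
comparisons and Pearson correlation of viability vs hours of ischemia.

Because no micrographs were published, the package ships a generator of
NADH-TR-like sections (Voronoi fiber tessellation, two stain-intensity
populations, spatially correlated patchy stain loss calibrated to the
published group means, illumination gradient, pixel noise) with per-pixel
ground truth. See the methods vignette
(`vignettes/viability-morphometry.Rmd`) for the model and every design
choice.

## Worked example

```r
library(nadhtr)

vs <- viability_study(c("Control", "8I"), n_animals = 4, fields_per_animal = 4,
                      seed = 7,
                      overrides = list(width_px = 256, height_px = 256,
                                       n_fibers = 40),
                      stats = FALSE)
vs
#> Muscle fiber viability study (synthetic): 8 animals x 4 fields, seed 7
#>
#> Normalized muscle fiber viability (% of control), mean ± s.e.m.
#>  condition             total             type1            type2b
#>    Control 100.0 ± 3.1 (n=4) 100.0 ± 7.0 (n=4) 100.0 ± 3.7 (n=4)
#>         8I  24.6 ± 1.6 (n=4)  20.1 ± 2.0 (n=4)  29.1 ± 3.5 (n=4)
```

The 8-hour-ischemia preset encodes per-type stain retentions of 0.201
(Type I) and 0.291 (Type IIb); the pipeline — colour thresholding, per-fiber
Otsu typing, area fractions, per-animal means, percent-of-control
normalization — recovers 20.1% / 29.1% / 24.6% (Type I / Type IIb / total;
total is the area-weighted mix of the types). Control is 100.0 exactly by
construction. Dose-response on the reference group means:

```r
pearson_cor(c(0, 4, 6, 8, 9), c(100, 60.5, 43.8, 24.3, 12.1))
#> Pearson correlation: R = -0.999; R^2 = 0.999; P = 2.23e-05 (n = 5)
```

A thin CLI over the same functions lives at `inst/cli/nadhtr.R`
(subcommands `synth`, `segment`, `measure`, `stats`, `simulate-and-run`).

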