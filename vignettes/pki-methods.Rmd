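---
title: "Mapping a flowering invader with a species-targeted spectral index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a flowering invader with a species-targeted spectral index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkimapper)
```

## The problem and the model

*Pedicularis kansuensis* is an annual/biennial hemiparasitic herb that has
expanded aggressively through alpine grassland–wetland mosaics. During its
peak flowering window the canopy turns purplish-red, and in multiband surface
reflectance that expresses as three stable band-level contrasts against
native pasture: **higher blue** (inflorescence coloration), **lower green**
(flowers masking leaf area), and **higher red and red-edge** (reduced red
absorption with intact canopy structure). Greenness indices cannot exploit
this — a vigorous sedge meadow and a flowering invader can have identical
NDVI — so the package implements an index built directly on the contrast:

$$\mathrm{PKI_{raw}} = \frac{\rho_{RedEdge} + \rho_{Blue}}{2.5\,\rho_{Green}}$$

The numerator accumulates the two bands the flowering canopy elevates, the
denominator is the band native vegetation dominates, and the factor 2.5
normalizes the decision boundary so that flowering targets sit above 1 and
green backgrounds below it. Because the index is a pure ratio it is invariant
to multiplying all bands by a positive constant, which buffers multiplicative
illumination differences; it is *not* invariant to additive radiometric
offsets, a limitation discussed below.

A pixel-wise ratio is still noisy: soil flecks, shadow boundaries and sensor
noise produce isolated high values without the spatial coherence of real
patches. The raw surface is therefore refined by **grayscale morphological
opening** — windowed minimum (erosion) followed by windowed maximum
(dilation) over a flat 3 × 3 structuring element:

$$\mathrm{PKI} = \delta_B\!\left(\varepsilon_B(\mathrm{PKI_{raw}})\right)$$

Opening levels any bright structure that cannot contain the full element
(isolated pixels, one-pixel-wide filaments) while exactly preserving plateaus
that do — which matches the biology: the species forms compact clustered
patches, not single 3 m pixels. Presence is then one fixed rule,

$$\text{present}(x) \iff \mathrm{PKI}(x) \ge 1.0 \;\wedge\; \rho_{Red}(x) > 0.05,$$

with the red floor suppressing dark surfaces (water, shadow, wet soil) whose
near-zero green denominator can push any ratio index above threshold. Both
boundary semantics are deliberate: the index comparison is inclusive, the red
comparison strict.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `scaling_factor` | 2.5 | denominator scaling of the raw index; places the flowering decision boundary at 1 |
| `se_size` | 3 | structuring-element side (pixels); the smallest patch structure treated as real |
| `pki_threshold` | 1.0 | fixed decision threshold on the opened index (inclusive) |
| `red_min` | 0.05 | red-reflectance floor (strict); dark-surface suppression |
| `cell_size_m` | 300 | density-grid cell for hotspot maps and marginal profiles |
| `n_boot` | 1000 | bootstrap replicates for metric confidence intervals |

All are exposed as arguments but the zero-flag configuration is the reference
configuration; the point of the method is that it needs no year-specific
re-tuning.

Benchmark indices (RI, NDVI, NDRE, GNDVI, CIRE, CIG, ARI) have no comparable
universal threshold, so they are segmented by the **Tukey boxplot whiskers**
of the target-class sample distribution: the most extreme observed values
inside $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, quartiles by
linear interpolation (type 7), computed per index and per year on
target-class samples only. Whether the original interval construction also
used background samples is not derivable from the published tables; the
target-only convention is the most standard reading and is isolated behind
`whisker_range()` so it can be swapped without touching anything else.

## Numerical and design choices

**Separability statistic.** The separability measure is implemented as
$M = |\mu_1 - \mu_2| / (\sigma_1 + \sigma_2)$ with sample ($n-1$) standard
deviations. Some typesettings of this statistic drop the difference operator;
a product of class means is dimensionally inconsistent with a separability
measure, so the standard absolute-difference form is used. $M > 1$ is read as
good separability. Degenerate spreads are handled explicitly: equal means
give $M = 0$, unequal means with zero spread are flagged infinite rather than
overflowing.

**Morphology border and mask policy.** Neighborhoods are clipped at image
borders, and invalid pixels (nodata, zero denominators) are excluded from
every neighborhood while remaining invalid in the output. Under this
clipped/masked definition the erosion–dilation pair is an adjunction on the
valid domain, so the opening is *exactly* anti-extensive, increasing and
idempotent — properties the test suite asserts bit-for-bit against a
brute-force double-loop oracle. Clipping avoids inventing padding values and
keeps constant images fixed points; excluding invalid pixels prevents a
nodata hole from erasing an otherwise valid patch, and prevents a bright
invalid pixel from leaking into its neighbors' dilation.

**Persistence typology.** The three published classes — ephemeral (one
year), strictly continuous (≥ 3 consecutive years), recurrent (re-appearance
after ≥ 1 absence year) — cannot cover a pixel present in exactly two
consecutive years, yet published class areas sum to the full footprint. The
package therefore computes a four-way typology with an explicit
`short_continuous` class and a merge flag (default: fold it into
`continuous`), which reproduces three-class totals while keeping the
ambiguity auditable. Category areas partition the ever-present footprint
exactly; shares sum to 100%.

**Recurrence rate.** No formula is published for the per-year recurrence
rate. The implemented definition — pixels present in year $t$, absent in
$t-1$, present somewhere before $t-1$, divided by year-$t$ invaded area —
makes the rate read as "share of this year's extent that is re-colonization"
and is confined to `recurrence_stats()`. It is documented as this package's
definition, not asserted as the original one.

**Density profiles.** Hotspot maps aggregate presence into 300 m grid cells
(density = presence fraction per cell) with marginal profiles as mean cell
density per grid row/column. Grid aggregation is deterministic and
parameter-light compared to kernel smoothing, whose bandwidth would be an
invented parameter.

**Trend inference.** Annual area trends use ordinary least squares with the
two-sided $t$-test ($n-2$ df) for the slope; on the published five-year
series (250.00, 2168.16, 2042.48, 797.52, 159.73 ha) this reproduces all four
printed statistics (mean 1083.58 ha, slope −155.12 ha yr⁻¹, $R^2$ = 0.06,
$p$ = 0.68) at printed precision.

**Confidence intervals.** Published accuracy intervals do not state their
method; the package uses the nonparametric percentile bootstrap
(case-resampling, default 1000 replicates, explicit seed required).
Degenerate resamples are skipped and counted.

**Raster storage.** Scenes and maps are stored as band-per-page 32-bit-float
TIFF with a JSON sidecar carrying band order, georeferencing, nodata and —
for index maps — an affine value scaling, since float TIFF samples are stored
in [0, 1]. Round-trip error is bounded by (value range) × 2⁻²⁴: effectively
exact for reflectance and binary data, and range-relative for wide-range
indices such as ARI. Reflectance outside [0, 1] is accepted with a warning
rather than rejected, and scaled-integer products are auto-detected by
maximum value (a heuristic, surfaced in a message and overridable), because
the numeric encoding of commercial reflectance products varies.

## What the synthetic generator does and does not show

`generate_scene()` emulates the structure the method assumes: spatially
clustered elliptical target patches (parent–child placement, matching the
species' compact patch habit), a grass matrix with soil and dark-water
features, one-pixel linear spectral mixing at patch edges, independent
per-band Gaussian noise (default sd 0.01), and an optional additive per-band
offset inside a sub-rectangle — the cross-scene mosaic-normalization artifact
that is the method's known failure mode. The class templates are synthetic
constants chosen to satisfy the qualitative flowering contrasts (raw index
≈ 2.06 on targets, ≈ 0.65 on grass, ≈ 0.77 on soil; dark water deliberately
lands *above* 1 with red ≤ 0.05 so the red floor is exercised). They are not
measured reflectances.

Passing tests on these scenes therefore demonstrate internal correctness of
the chain — index arithmetic, opening behavior, rule semantics, bookkeeping
of areas, persistence and recurrence — and qualitative failure-mode behavior
(offset-induced false positives confined to the offset region). They do not
demonstrate real-world accuracy: real alpine scenes contain phenological
variation, mixed canopies of spectrally similar native species, spatially
correlated noise and topographic illumination effects that the generator
does not model. Published real-data accuracies are not reproducible without
the commercial imagery and the field validation set, neither of which is
redistributable.

Noisy-scene performance is evaluated on pure-label pixels only (patch
interiors and unmixed background); mixed edge pixels are excluded from
scoring as ambiguous by construction, mirroring validation sampling from
patch centers.

## Problem sizes

The test suite and the acceptance script run on 120–160 px synthetic scenes,
20 noise seeds, 100 random 16 × 16 images for the morphology oracle and 1000
random sample sets for the whisker oracle — sizes chosen so the full suite
completes in well under a minute while every property is exercised at
non-trivial scale.

## Known limitations

- Additive radiometric offsets (mosaic color balancing) defeat the ratio
  structure and create false positives; the generator reproduces this
  qualitatively, and the only mitigation is upstream radiometric hygiene.
- Species with near-identical visible/red-edge signatures (e.g. co-occurring
  *Gentiana* at high density) are not separable by any fixed band-ratio rule
  at this spectral resolution.
- The 0.05 red floor is a reflectance-unit constant; data not scaled to
  [0, 1] reflectance must be rescaled before segmentation.
- Georeferencing is carried via sidecar metadata, not embedded GeoTIFF tags;
  interoperability with GIS stacks requires the sidecar to travel with the
  file.
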