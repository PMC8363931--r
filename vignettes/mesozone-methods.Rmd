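---
title: "Compartment-aware quantification of multiplexed IHC cores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-aware quantification of multiplexed IHC cores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesozone)
```

## The analysis this package implements

Malignant pleural mesothelioma (MPM) grows as tumor-cell sheets embedded in
a fibroblast-rich stroma. A pixel-based way to ask whether stromal biology
carries prognostic information is to image a tissue-microarray (TMA) core —
a 1.0 mm circle of tumor tissue — across two multiplexed immunofluorescence
staining rounds carrying seven fibroblast markers (PDGFRA, PDGFRB, aSMA,
FAP, SPARC, POSTN, collagen I) next to tumor-cell markers (CK5 or a
CK5/CK5-6/calretinin mix) and a nuclear counterstain, then:

1. **overlay** the two staining rounds of each core (rigid integer-pixel
   registration of the shared counterstain channel);
2. **mask** each pixel as autofluorescent debris, blood vessel, background,
   or tissue with a trained pixel classifier;
3. **segment** tissue into the mesothelioma (tumor-cell) compartment and
   total stroma using the tumor-marker signal;
4. **zone** the stroma into concentric 12 µm rings at increasing Euclidean
   distance from the mesothelium (meso zones 1–4) and from vessels (vessel
   zones 1–4);
5. **quantify** each marker's mean intensity per compartment and zone,
   average the per-core values per patient (two cores per patient), and form
   the PDGFRB-positive fraction of the tumor-cell area;
6. **screen** the resulting `marker × {meso, stroma, meso_Z1..4,
   vessel_Z1..4}` variables (70 for seven markers) against overall survival
   with univariate Cox models, Bonferroni correction over the screened
   family, multivariable Cox models adjusted for age, sex, side, clinical
   stage and histology, and Schoenfeld-residual diagnostics.

The package implements all six stages plus a synthetic-data layer — core
phantoms with exact geometric/intensity ground truth and survival cohorts
with known hazard structure — so that every stage has an oracle it can be
tested against. No patient imaging data ship with the package; everything in
the test suite is simulated.

## Phantoms: geometry, intensity and noise

A phantom is a circular core of diameter 1 mm (configurable) rasterized at
`pixel_size_um`. Pixel centers sit at `(i + 0.5) · px` (0-based `i`); a
pixel belongs to a disc iff its center is inside. This makes every area
oracle a closed-form count. Masks are assigned with a fixed priority where
shapes overlap: outside-core background, then autofluorescent debris, then
vessels, then tumor; remaining in-core pixels are stroma. By construction
the four masking classes partition the frame and `tumor ∪ stroma = tissue`
— the conservation identities the segmentation stage must preserve exactly.

Channel intensity is `baseline + offset(compartment)`, optionally plus a
stromal radial gradient `slope · d(pixel, tumor)` in intensity units per µm,
clamped to [0, 1], plus additive Gaussian noise (again clamped), quantized
to the 16-bit grid `k/65535`. Quantization mirrors scanner bit depth and
makes TIFF round trips bit-exact. The paper trail for tests is the
`ground_truth` object: exact masks, per channel-by-compartment noise-free
means, and zone maps computed by brute-force nearest-source search —
deliberately *not* the production distance-transform code path.

Two staining rounds are emulated by splitting the rendered stack and
displacing round 2 by a small integer shift; registration must undo it.
Because the phantom renders compartment-constant intensities (plus noise),
it does not emulate cell-level texture, optical point-spread, spectral
bleed-through, or illumination gradients. Passing tests therefore certify
the geometry, bookkeeping and statistics of the pipeline — not robustness
to every optical artifact of real scanners.

## Registration and QC

Rounds are overlaid by maximizing the normalized cross-correlation of the
nuclear channel over integer shifts up to `max_shift_um` (default 50 µm).
No rotation or deformation is modeled: serial rounds of the same physical
section differ mainly by stage offset. A constant reference channel or a
best shift on the search boundary raises a registration error; such cores
fail QC whole. Pixels that leave the frame after alignment are flagged
invalid and excluded from every downstream mask and mean. A core passes QC
when tissue covers at least `min_tissue_fraction` (default 0.1, inclusive)
of the core disc.

## Pixel masking and compartment segmentation

The masking classifier is a seeded random forest (default 50 trees) over
each channel's raw intensity plus Gaussian-smoothed versions at two scales
(σ = 1 and 4 px) — the transparent stand-in for interactive
pixel-classification tools, same model family, fully reproducible. In
simulation runs it is trained on ground-truth-labeled pixels pooled across
several cores (default 8) so the forest keys on masking cues that
generalize across patients' marker levels; on real data the same function
accepts user scribbles. Posterior probability maps are kept; hard masks are
the per-pixel argmax, so the four masks always partition the frame.

Tumor/stroma separation thresholds the pixelwise maximum of the smoothed
(σ = 2 px) tumor-marker channels at an explicit threshold or Otsu's value
computed over tissue pixels, followed by morphological closing-then-opening
with a disc of radius 2 px. The cleanup radii are exposed; both operators
are monotone, so raising the threshold can never grow the tumor area, and
`tumor + stroma = tissue` holds exactly because stroma is defined as the
set difference. The tumor-class confidence used by the positive-area filter
is the tissue-class posterior restricted to tumor pixels — the direct
analogue of a CNN's class confidence in this two-stage design, with the
published ≥ 0.85 cut as default.

## Distance zones

Zone `k` around a source compartment contains the stroma pixels whose
Euclidean center-to-center distance `d` to the nearest source pixel obeys
`(k−1)·w < d ≤ k·w`, with `w` = 12 µm and four zones by default; stroma
beyond `n·w` keeps label 0 but still belongs to the total-stroma variable.
Meso zones and vessel zones are computed independently, so a pixel may
carry both labels. Distances come from an exact Euclidean distance
transform; squaring and rounding recovers exact integer squared distances
in px², so zone labels agree *exactly* with the brute-force
nearest-source-pixel oracle — an equality the tests assert on random mask
pairs, not just on discs.

One rasterization property deserves honesty: for a stroma pixel at radius
`r` outside a rasterized disc of radius `R`, the nearest source *pixel
center* is at distance ≥ `r − R`, because all source centers lie inside the
circle. Lattice distances therefore exceed the continuous
distance-to-region by a small ε (≈ 0.19 px on average, ≤ px·√2), which
shifts every ring boundary slightly inward. The innermost ring, whose inner
edge is pinned to the tumor, can only lose pixels: at 2 µm pixels and
12 µm rings around a 120 µm disc the deficit is ≈ 3.3 %, while outer rings
shift at both edges and stay within ~1–3 % of the analytic annulus areas.
This is a property of the (deliberately fixed, reproducible) center-to-center
convention, not of the implementation; the exact-oracle equality is the
normative test.

## Quantification conventions

`mean_intensity` is the arithmetic mean over mask pixels; an empty mask is
*missing*, never 0, and missingness propagates into the screens as
complete-case analysis per model with `n_used` reported. Per-patient
variables are arithmetic means over the patient's QC-passed cores. The
×1000 scale exists only in the statistics layer (`scale_for_cox`, which
refuses to run twice); since Cox coefficients transform as `β/c` under
covariate scaling by `c`, this is presentation, not science. Positive-area
fractions pool pixel areas across a patient's cores before forming the
ratio (the pooled-fraction estimator), rather than averaging per-core
ratios.

## Survival statistics

Cox models are fit by partial-likelihood maximization with Efron tie
handling (survival months in practice are tied; Efron is the less biased
default), tight convergence (`eps = 1e-12`), Wald 95 % intervals and
p-values. Monotone likelihood (perfect separation) and non-convergence are
errors, not numbers. On tie-free data ≤ 8 subjects the fitted coefficient is
checked against golden-section maximization of a hand-coded partial
likelihood to 1e-6. Bonferroni correction is `min(1, m·p)` with the family
size `m` an explicit, logged parameter defaulting to the number of screened
variables (7 markers × 10 compartments = 70). Proportional hazards are
tested by regressing scaled Schoenfeld residuals on event time (identity
transform). The auxiliary tests — log-rank, Mann–Whitney U (exact
enumeration when `n_x·n_y ≤ 400` and tie-free), Spearman rank correlation
(exact permutation null for n ≤ 8 without ties) — wrap the standard
implementations and are verified against enumeration oracles in the tests.

## The cohort simulator

Survival times are exponential with hazard
`h₀ · exp(β · 1000 · marker)` — the simplest generator satisfying
proportional hazards, which is all a semiparametric Cox analysis assumes.
Raw marker intensities default to Beta(2, 18) (mean 0.1, i.e. ~100 scaled
units), so hazard ratios of 1.01–1.02 per scaled unit correspond to
realistic effect spreads; the baseline hazard defaults to 0.02/month
(median survival of order 1.5–3 years). Censoring is administrative:
`C ~ Uniform(0, H)` with `H` solved so the expected censored fraction hits
`censor_rate` (default 0.04, matching a cohort with 3 of 74 patients
alive at follow-up end). Covariates (age, sex, side, histology, stage
dichotomized low I–II / high III–IV) are drawn from fixed
mesothelioma-typical frequencies and carry no hazard effect unless the
user injects one.

## The pipeline and reproducibility

`run_pipeline()` chains simulate → register/QC → mask → segment → zones →
quantify → screen under a single `run_config()`. One run seed fans out to
per-stage seeds by hashing the stage name, so any stage can be re-run in
isolation and identical configs reproduce every numeric output bit for bit.
Run directories receive the tables, reports, logs and a provenance manifest
containing the config hash; resuming into a directory whose manifest hash
differs is refused. A thin command-line wrapper
(`inst/cli/mesozone`) exposes `simulate`, `run` and `survive` over YAML
configs; the per-stage operations are exported functions.

## Problem sizes used by the checks

Verification runs were sized to be decisive yet quick: the zone-geometry
oracle uses a 120 µm tumor disc at 2 µm pixels (200×200 raster); intensity
recovery uses the same raster with noise SD 0.05; Cox recovery uses
n = 2000 over 20 seeds and 200 coverage replicates at n = 1000; the
family-wise-error simulation runs 500 all-null screens of 70 variables at
n = 100; the end-to-end recovery experiment injects HR 1.02 per scaled unit
on `PDGFRB_meso` in cohorts of 300 patients (one core per patient,
12 µm pixels) over 20 seeds — between-patient marker variance dominates
per-core measurement error by two orders of magnitude, so one core per
patient leaves the ranking behavior unchanged while the per-patient
averaging path is exercised separately by the default two-core fixture.

## Known limitations

* Registration is integer-pixel and rigid; sub-pixel or non-rigid motion is
  out of scope.
* Phantoms are piecewise-constant; classifier accuracy on them does not
  bound accuracy on textured real tissue.
* Distance zones are straight-line Euclidean, not geodesic within tissue; a
  geodesic variant would be a natural extension.
* The positive-area operation thresholds a fluorescence channel; membrane
  morphology of brightfield DAB staining is not modeled.
* The Bonferroni family size is configuration, not inference: if you screen
  a different variable count, set `m` accordingly.
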