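---
title: "Measuring and modelling body-colour plasticity with chromashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling body-colour plasticity with chromashift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromashift)
```

## The measurement problem

Many fishes signal social status and health through changes in melanin-based
body coloration that unfold over hours to days. Quantifying such change from
photographs requires three things: a colour representation in which
"lighter", "more saturated" and "different hue" are separable and roughly
perceptually uniform; control over illumination differences between
photographic sessions; and a statistical model that separates treatment
effects from genetic-line effects and from the identity of the individual
fish, which is photographed repeatedly.

chromashift implements this workflow for designs in which each individual is
photographed at 0, 24 and 48 h, against a colour chart, with a hand-drawn
binary mask delimiting the fish. It was designed around experiments on
near-isogenic selfing lines of the mangrove killifish, where within-line
genetic variation is minimal and the random-intercept variance is therefore
directly interpretable as non-genetic individuality.

## Colorimetry

Images are 8-bit sRGB (IEC 61966-2-1): channel values are scaled to [0, 1],
decoded with the two-piece transfer function (linear slope 1/12.92 below
0.04045, exponent 2.4 above), and mapped to XYZ with the standard sRGB/D65
matrix. We adopt the classic 6-decimal matrix whose middle row sums to
exactly 1, and define the reference white as the matrix row sums. Two exact
identities follow, used as anchors by the test suite: the 8-bit white
(255, 255, 255) has Y = 1 and maps to L\* = 100, a\* = b\* = 0; black maps to
(0, 0, 0). CIELAB uses the CIE 1976 two-branch function with δ = 6/29 and
offset 4/29.

A mask pixel is included iff its grey value exceeds 127 on the 0–255 scale.
Each included pixel is converted to Lab individually and L\*, a\*, b\* are
averaged over the region — averaging after the nonlinear conversion, not on
raw RGB, so the region mean lives in the approximately perceptual space. Hue
and chroma are then computed from the *mean* a\*, b\*:
h\* = atan2(b̄, ā) in degrees in [0, 360), C\* = √(ā² + b̄²), with h\* = 0 by
convention when C\* = 0. Computing hue per pixel and averaging would be
wrong for a mottled animal: hue is circular and pixel-level hue of
near-neutral pixels is noise.

Hue is reported in degrees and this unit is recorded in the pipeline's run
log. Published analyses of this kind sometimes report hue coefficients two
orders of magnitude smaller than degree-scale shifts, suggesting radians or
a normalised ratio internally; we adopt degrees (the convention of the
aquaculture colorimetry literature this workflow descends from) and flag the
unit explicitly rather than guessing at conversions.

## Calibration

Illumination differences between sessions are modelled as a 3×3 linear map
acting on linear-light RGB, estimated by ordinary least squares from the
observed vs nominal colours of chart patches (≥ 3 non-collinear patches
required; the bundled synthetic chart has 24, including a 6-step neutral
ramp). There is no offset term — a cast is a change of illuminant, and zero
light must stay zero — and corrected values are clipped to gamut, never
renormalised, so neutral patches stay neutral.

Two numerical facts shape the tests. With noiseless (continuous) patch
measurements and no gamut clipping, the fit recovers the inverse cast
essentially exactly, and the only error left in a calibrated photograph is
its own 8-bit rounding: within one quantisation step per channel. Once the
*chart itself* is quantised to 8 bits, however, quantisation errors on
bright patches propagate through the least-squares fit and are amplified by
the steep dark end of the transfer function (the encode slope near black is
12.92 × 255 ≈ 3300 per linear unit), so a patch with a nominal channel of 8
can land 2 steps off. The quantised-chart guarantee is therefore stated on
the matrix itself (recovery to 1e-2), not per dark channel. Casts used in
fixtures are drawn diagonally dominant with small positive off-diagonals so
that no patch clips; a cast that clips destroys information and is not
invertible from the chart alone.

## Shift assembly

Colour change is the within-individual difference later − earlier over the
0–24, 0–48 and 24–48 h intervals, so a positive ΔL\* means the fish got
lighter. Hue differences use the signed shortest angular distance in
(−180, 180] (a move from 350° to 10° is +20°, not −340°), which keeps the
interval-additivity identity Δ(0–48) = Δ(0–24) + Δ(24–48) exact for L\* and
C\* and exact modulo 360 for hue. Individuals missing one of the three time
points are dropped with a warning and listed in the output's `dropped`
attribute; no imputation is attempted. a\* and b\* shifts are computed for
completeness but are not part of the modelled attribute set (L\*, h\*, C\*).

## Statistical model

The response is one attribute's shift table: 3 rows (intervals) per
fish × context unit. The full fixed-effect structure is
line × treatment × time, with a per-individual random intercept capturing
consistent individuality across an individual's repeated intervals.

- **Time coding.** `time_h` is the interval-end hour (24, 48, 48) by
  default, treating time as a continuous slope; the interval factor is also
  available for a categorical coding. Both are supported because published
  designs are ambiguous on this point; a single time slope is the default.
- **Candidate ladder.** Four models per attribute: additive and fully
  crossed fixed effects, each with and without the random intercept. All
  candidates are fitted by maximum likelihood; AIC = 2k − 2·logLik with k
  counting every estimated parameter including variances.
- **Equivalence rule.** Candidates within 2 AIC units of the minimum are
  treated as statistically equivalent and the simplest is chosen — fewest
  parameters, then fewest interaction terms, then the fixed-effects-only
  model before the mixed one. The tie-break is deterministic so reruns are
  reproducible.
- **Simplification.** Backward elimination: at each step the removable term
  (marginality-respecting: no main effect leaves while an interaction
  containing it remains) whose removal lowers ML AIC the most is dropped,
  until no removal lowers AIC. The elimination path is retained. The final
  model is refit by REML for reporting, since ML variance estimates are
  biased low; both AICs are kept.
- **Random-effect test.** A likelihood-ratio χ² between ML fits with and
  without the intercept, with degrees of freedom equal to the parameter
  difference (1 for a single variance). Because the null value lies on the
  boundary of the parameter space, the χ²₁ reference is conservative. Some
  published reports give d.f. = 2 for this comparison, which a single added
  variance cannot produce; we report the parameter-count difference and
  note the discrepancy rather than reproduce it.
- **Degrees of freedom.** Satterthwaite approximation (via lmerTest) for
  mixed models, residual df for OLS; the method in use is recorded in each
  fit and in the run log, since fractional and integer df conventions are
  often mixed in the literature this serves.
- **Post hocs.** Estimated marginal means per factor level, averaged over
  the other terms, with Tukey-adjusted pairwise comparisons (the lsmeans
  default); the adjustment is configurable.

Singular random-effect fits (variance estimated at the boundary) are
flagged on the fit object, not hidden; the zero-variance limit makes the
LRT statistic exactly 0.

## The synthetic-data module

No raw photographs or phenotype records are available for the study designs
this package emulates, so the generator is a first-class, tested component
rather than a test fixture.

**Images.** An elliptical body with base colour in Lab plus independent
zero-mean Gaussian mottle per pixel (default SDs 6, 1, 2 in L\*, a\*, b\* —
visible mottling of the right order for a grey, mottled killifish), on a
uniform dark background (L\* = 25), rendered to 8-bit sRGB with gamut
clipping. The recorded ground truth is recomputed from the *rendered 8-bit
pixels*, not the pre-quantisation target, so the extraction path can be
validated to 1e-9. The default test size is 64×64 with larger 128×128
renders used where a full experiment is instantiated; fixtures are written
as lossless PNG to avoid compression noise.

**Designs.** The social design has two lines (DAN, R) with 8 control fish
per line and 9 test fish per line observed under both a single-fish and a
group context — 34 unique fish, 52 fish × context units, 156 interval rows
per attribute; the random intercept tracks the true fish identity across
contexts. The infection design has 80 fish (40 per line, 20 infected and 20
uninfected controls per line), 240 interval rows — matching one photograph
per fish and time point, 240 in all.

**Effect simulation.** Shifts are drawn directly from
y = Xβ + u_individual + ε with named fixed-effect coefficients, a Gaussian
random intercept shared across an individual's rows, and Gaussian residuals
— the exact model family the inference stage assumes. An alternative
trajectory mode simulates raw attribute values at 0/24/48 h (baseline +
per-hour drift + noise) and lets the shift-assembly stage difference them,
exercising both pathways. Default recovery-test effect sizes (treatment
effects ~2 L\* units, time slopes ~0.08 per hour, individual SD 1.5,
residual SD 2) are of the same order as published coefficient tables for
this kind of experiment; they are conveniences for simulation, not claims
about any real population.

What the generator does *not* emulate: real fish shape and pattern
(mottling is i.i.d., real melanophore pattern is spatially correlated),
specular highlights, shadows, chart placement, JPEG compression, or
non-Gaussian residuals. Passing recovery tests therefore demonstrate that
the pipeline is correct and well-calibrated *for data meeting its
assumptions*; they cannot certify segmentation quality or robustness to
photographic artefacts in field data.

## Numerical choices and scales

- Negative tristimulus guard: −1e-9 (below: error; tiny negatives from
  floating-point are clamped to 0).
- Singularity threshold for random-effect variance: 1e-10 (flagged as a
  boundary fit).
- Simulation sizes: parameter-recovery and type-I-error suites run the
  80-individual × 3-interval infection design with 500 and 1000 replicates
  respectively — large enough that empirical coverage has a standard error
  under 1% — and complete in a couple of minutes; oracle-equivalence checks
  use 100 random 32×32 image/mask pairs at tolerance 1e-9.
- All stochastic components take explicit integer seeds; identical seeds
  give byte-identical outputs, including rendered PNG fixtures and pipeline
  CSVs.

## Known limitations

- Masks are inputs: there is no automatic fish segmentation.
- The calibration model is linear with no offset; strong non-linear casts
  (mixed illuminants, camera tone curves beyond sRGB) are out of model.
- Hue modelling treats angular differences as linear responses, which is
  adequate for the small shifts the design targets but would fail for
  near-180° swings.
- Random slopes are not offered — the designs modelled here identify an
  intercept per individual from three intervals, and more structure would
  not be estimable.
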