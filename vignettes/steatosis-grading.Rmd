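---
title: "Grading hepatic steatosis from calibrated liver photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading hepatic steatosis from calibrated liver photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoscope)
```

## The problem

Hepatic steatosis (HS) — fat accumulation in hepatocytes — is the leading
reason donor livers are discarded before transplantation. The reference
measurement is needle biopsy, which is slow and not always feasible during
procurement, so surgeons often judge steatosis visually: steatotic livers
look yellower (higher CIELAB b\*), less red (lower a\*), and coarser in
texture. That judgement is error-prone. `steatoscope` implements an
image-analysis pipeline that formalises it: a photograph of the liver with a
neutral grey card in frame is colour-calibrated, the liver is divided into
random non-overlapping patches, each patch is classified as coming from a
*valid* (HS at or below a threshold, 15% or 30%) or *non-valid* liver, and
the patch votes are aggregated into a liver-level decision.

## Pipeline and model

1. **Linearisation.** Phone cameras store sRGB-encoded intensities; scene
   radiance is recovered by raising pixel values to the power 2.2. A pure
   power law is used rather than the piecewise sRGB curve — the difference
   is small and the single exponent is configurable.
2. **Grey-card white balance.** The card colour `g` is estimated as the
   per-channel median over a user-supplied ROI (median, so specks and glare
   points do not bias it). Per-channel gains `mean(g)/g_k` neutralise the
   illuminant tint; by default a further scalar maps the card to the
   canonical 18% reflectance so exposure is also comparable across images.
   Post-gain values are clipped to [0, 1] and the clipped fraction is
   reported as a quality warning. Whether exposure should be normalised in
   addition to chromaticity is genuinely open; we default to yes because
   the L\* histograms and the luminance-IQR patch filter otherwise shift
   with exposure, and a `normalize_exposure = FALSE` switch preserves the
   chromaticity-only behaviour.
3. **CIELAB.** Calibrated linear RGB is converted with sRGB primaries and
   the D65 whitepoint. L\* in [0, 100]; a\* (green–red) and b\*
   (blue–yellow) carry the steatosis colour signal.
4. **Masking.** The liver mask is an input (PNG, nonzero = liver). A
   baseline colour-threshold segmenter (a\* > 10, L\* in [15, 85], largest
   morphologically-closed component) is provided for calibrated scenes
   where the liver is the dominant reddish object; it is a fallback, not a
   replacement for a proper segmenter, and segmentation quality is not an
   evaluated claim of this package.
5. **Patching.** The liver area sets the plan:
   `side = clip(round(sqrt(area)/12), 60, 120)` pixels and
   `n = clip(round(area/(7 side^2)), 15, 25)` patches. The constants 12 and
   7 put a one-megapixel liver at the typical operating point of about
   twenty 80-pixel patches. Candidate squares are drawn uniformly; a
   candidate is kept if it lies fully on the mask, does not overlap an
   accepted patch, and its mean luminance lies inside the liver's L\*
   interquartile range. The IQR rule is applied two-sided by default
   (rejecting specular highlights above Q3 and shadowed/occluded patches
   below Q1); a `highlights_only` switch makes it one-sided for users who
   read the rejection rule as targeting highlights only. Rejected draws
   are replaced up to `50 n` attempts; fewer than 8 accepted patches is an
   error ("insufficient valid area").
6. **Features.** Per patch: 32-bin histograms of L\*, a\*, b\* on fixed
   ranges (L [0, 100], a\*/b\* [−128, 127], out-of-range values clipped to
   the edge bins) and 256-bin histograms of classic radius-1, 8-neighbour
   local binary patterns computed per CIELAB channel (bit `i` set iff
   neighbour `i` ≥ centre, clockwise from the top-left diagonal; the raw
   256-code histogram rather than uniform-pattern LBP keeps the
   brute-force oracle test exact). Optionally a standardized clinical
   block (age, sex, BMI, AST, ALT, GGT, bilirubin) is appended; its
   centering (median) and scale (SD) statistics are fitted on training
   donors only and stored in the model, so no test-set statistics leak.
7. **Classifier.** A class-weighted random forest (or RBF SVM) at the
   patch level, weights `N/(2 N_c)` — inversely proportional to class
   frequency. Patches inherit their case's label: *non-valid* iff the mean
   of the two lobe biopsies exceeds the HS threshold (a `max` lobe rule is
   selectable). SVM margins are mapped to [0, 1] by the logistic (Platt)
   link fitted on training data.
8. **Aggregation.** A liver is called non-valid when the fraction of
   non-valid patch votes reaches 20% (inclusive at the boundary — the
   conservative direction for flagging steatosis).
9. **Evaluation.** Donor-level stratified nested cross-validation: the
   outer loop is repeated stratified 70/30 shuffle splits (the stated
   70/30 fractions do not form a k-fold partition, so shuffle splits are
   the natural reading; 10 repeats by default), the inner loop one
   stratified 90/10 split of the outer-train donors per hyperparameter
   grid point, selected by inner liver-level AUC. Metrics are accuracy,
   precision and recall (positive class: non-valid) with case-level
   percentile-bootstrap 95% CIs (B = 1000), the ROC/AUC of the non-valid
   patch fraction, an exact two-sided McNemar test against the surgeon's
   visual estimate, and feature importance both as the forest's mean
   decrease in impurity and as permutation AUC drop.

## The synthetic cohort

Clinical liver photographs cannot be redistributed, so the package ships a
seeded generator that renders the study conditions end to end: an
elliptical liver on a surgical drape, coloured in CIELAB by
`a* = 25 − 0.15 HS + ε`, `b* = 10 + 0.35 HS + ε` (case-level ε, SD 2, plus
per-pixel chroma variation, SD 4), textured by a smoothed-noise grain whose
correlation length grows with HS (`2 + 0.08 HS` pixels, with per-case
lognormal jitter, SD 0.6 — tissue texture is biologically variable, so the
length relation is treated as a mean, like the colour model), specular
highlight discs (Poisson(2), L\* ≈ 95), a grey card square at exactly 18%
linear reflectance, then a per-image illuminant (per-channel gains
U[0.7, 1.3], exposure U[0.8, 1.2]), clipping, and gamma encoding. True HS
is drawn from a two-component mixture: with probability 0.28 a high
component `15 + 45 Beta(1.6, 3.3)`, otherwise a low component
`15 Beta(1, 4)`; no liver exceeds 60%. Donor biochemistry is HS-linked
(`log ALT = log 30 + 0.020 HS`, `log AST = log 35 + 0.012 HS`,
`log GGT = log 40 + 0.008 HS`, `BMI = 26 + 0.09 HS`, noise SDs 0.20
log-scale and 2.5), while bilirubin, age and sex are independent of HS.
Each lobe biopsy reads the true HS with SD-3 sampling noise, and a
"surgeon estimate" with SD 10 provides the human comparator.

Choices worth flagging:

- The case-level chromaticity noise (SD 2) is about 5.7 HS percentage
  points when read through the b\* slope, so cases within roughly six
  points of the 15% threshold are intrinsically ambiguous. The mixture
  shapes keep that band thin (about 7% of cases) while leaving the 15–30%
  range populated. Real cohorts are denser near the threshold; liver-level
  AUC on real photographs will therefore be lower than on this synthetic
  cohort, and passing the synthetic recovery test shows pipeline
  correctness, not clinical performance.
- Texture is deliberately a *secondary* cue (the grain-length jitter makes
  it noisy); colour carries the dominant signal, so removing calibration
  visibly hurts, and clinical covariates add a measurable but small AUC
  increment — the qualitative behaviour reported for the clinical
  counterpart of this pipeline.
- The generator does not attempt photorealism: no camera noise model, no
  specular roughness, no vignetting, no anatomical shape variation beyond
  the ellipse. Consequences: the baseline segmenter looks better than it
  would on real data, and LBP reads texture more cleanly than it would
  through sensor noise.

## Numerical choices and degenerate inputs

- Card estimate uses medians; any zero median channel is an error (the
  card is unusable).
- White balance clips to [0, 1]; clipping above 1% of values warns.
- Quartiles use R's default (type-7) quantile.
- Patch sampling is rejection sampling; determinism comes from an explicit
  seed, and the RNG state of the caller is always restored.
- `lab_histogram` clips out-of-range values into the edge bins, so
  histograms always sum to exactly 1.
- LBP uses the ≥ convention: a constant patch maps to code 255.
- Ties in inner-loop model selection resolve to the first grid point;
  inner folds with a single class fall back to accuracy for selection.
- Bootstrap resamples in which a metric is undefined (e.g. precision with
  no positive predictions) are dropped; more than half undefined is an
  error.
- McNemar is the exact binomial form `min(1, 2 P(X ≤ min(b, c)))`, 1 when
  there are no discordant pairs.

## Problem sizes used by the shipped experiments

The package's own verification experiments (test suite and
`scripts/acceptance.R`) use a 200-case cohort at 768×768 pixels, nested CV
with 3 outer repeats and a two-point forest grid (200 trees, depth
unlimited vs 10, mtry = sqrt), repeated over three CV seeds. The package
defaults for real use are larger (10 outer repeats, the full 8-point
forest grid); the reduced sizes are the vignette-stated experiment scale,
chosen to keep the experiments reproducible on a laptop in minutes while
leaving the estimates stable to within a few hundredths of AUC.

## Limitations

- The embargoed clinical dataset behind the original study is not
  available; all quantitative results shipped with the package are on the
  synthetic cohort above, and the clinical headline numbers (AUC 0.82,
  accuracy 85% at the 15% threshold) are not reproducible here.
- Automatic grey-card detection is out of scope; the card ROI is an input.
- The nn-U-Net liver segmenter of the clinical system is replaced by mask
  input plus the baseline colour-threshold segmenter.
- Only macrosteatosis is modelled; microsteatosis is out of scope.
- Patch labels inherit the organ label, as in the source method; a
  lobe-specific labelling would need lobe-tagged photographs.
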