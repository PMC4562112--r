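---
title: "Length-adjusted radiographic bone level: model, geometry and reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-adjusted radiographic bone level: model, geometry and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relrbl)
```

## The measurement model

A periapical radiograph of a tooth is annotated with a small, fixed set of
landmarks: the crown reference `INC_OCL` (incisal edge on anteriors, the
most elevated cusp on bicuspids and molars), one `APEX` per root, and per
measured aspect (mesial/distal) one cemento-enamel junction `CEJ` and one
alveolar crest `AC`.  A restoration margin `RM` may be stored but enters no
measurement.  Coordinates are pixels relative to the upper-left image
corner, y increasing downward, with a scalar `mm_per_px` calibration.

Every distance in this package is a difference of *axis coordinates*: the
landmark's vertical pixel coordinate times the calibration
(`axis_coordinate()`).  The horizontal coordinate is discarded entirely —
the landmarks are projected onto an imaginary vertical axis parallel to the
vertical edge of the receptor.  This is a deliberate modelling choice, not
a simplification: mesial and distal landmarks sit several millimetres off
the tooth axis, and a 2-D Euclidean distance between them would mix
horizontal placement (which carries no bone-level information and varies
freely with where the examiner clicks along the crest) into a vertical
quantity.  All distances are absolute values, so image orientation never
flips a sign.

From one annotated site the package derives, per aspect:

* tooth length `a` = |axis(INC_OCL) − axis(APEX)|, one value per root;
* direct bone level `b` (RBL) = |axis(AC) − axis(CEJ)|;
* the length-adjusted bone level relRBL = 100 · b / a (percent).

On multi-rooted teeth the mesial aspect is adjusted by the mesial-root
length and the distal aspect by the distal-root length; single-rooted teeth
use their one length for both aspects.  The pairing is a documented package
choice — nothing in the measurement protocol forces either per-root or
whole-tooth pairing, but per-root pairing keeps each ratio internal to the
structure whose projection distorts together.  A site missing an AC or CEJ
is reported `incomplete` for that aspect rather than failing; `b > a` is
anatomically implausible and triggers a warning but is returned unclamped,
because silent clamping would bias condition means.

Computations run in full precision; only report-level printing rounds to
0.1 mm / 0.1 %, matching how such tables are conventionally published.

## Why the ratio is invariant

Let a projection multiply every vertical distance near the tooth by a
common factor *s*.  Then `a → s·a` and `b → s·b`, so `b/a` is unchanged for
any *s*.  Under **parallel projection** this is exact for arbitrary
receptor tilt α_r and tooth tilt α_t, because a parallel projection is a
linear map: all landmarks on (or laterally offset from) one axis scale by
the identical factor `cos α_t / cos α_r`.  The package asserts this as a
property — relRBL recovered through the full pixel-annotation path equals
the model truth to 1e-9 over randomized teeth and angles — while the direct
`b` is biased by exactly `1/cos α_r` under receptor tilt.

Under a **point-source (central) beam** the magnification `f/(f − z)`
varies with the landmark's distance *z* from the receptor, which a tilted
receptor couples to height.  The invariance then holds only to first order
in (tooth size)/f.  This is a genuine, physical residual bias of the
indirect technique, not a numerical artefact; at a clinically typical
focal distance it is a fraction of a percentage point, and the package's
convergence property shows the deviation from the parallel-mode value
shrinking monotonically as f grows through 150, 300, 600, 1200 mm.

## Projection geometry

The receptor plane passes through the origin; the central beam runs along
−z; in central mode the source sits at (0, 0, f).  Receptor tilt is a
rotation about the horizontal x-axis, so the receptor's in-plane vertical
is (0, cos α_r, sin α_r); the tooth axis may independently be tilted α_t
away from the receptor vertical.  `project_point()` intersects the
source-to-point ray (or the parallel beam direction) with the tilted plane
and returns in-plane (u, v) mm; it is cross-checked in the tests against an
independent solver that represents the plane by three points and solves the
3×3 linear system.  The tooth is centred vertically on the beam axis, which
is how a holder positions a receptor behind a tooth.

The local vertical scale of the image is

    scale = f/(f − d) · 1/cos α_r · cos α_t

(`scale_factor()`), with the first factor 1 in parallel mode.  A tooth
standing d = 15 mm off the receptor at f = 300 mm magnifies by 300/285 ≈
1.053 — the familiar ~5 % of routine intraoral imaging.

`bias_comparison()` puts the two techniques on one scale for the
object-size trade-off: a bone-level-like segment ending 2 mm below the
crown is projected under two geometries; the direct bias is the change in
its projected length, the ratio bias is the change in b/a re-expressed in
mm by multiplying with the true tooth length.  For a 7 mm object a 0°→30°
receptor-tilt change produces about 1.1 mm of direct bias and zero ratio
bias; for a 1 mm object the direct bias is ~0.15 mm — below most examiners'
click precision, which is why the indirect technique pays off for larger
objects and adds little for objects well under ~2 mm.

## Reliability statistics

* **Paired t-test** (`paired_t_test()`): two-sided, pairing per-site means
  across the two angle conditions, 5 % significance, no multiplicity
  correction across the three metrics (none is conventional for a
  three-row summary table).  Zero-variance differences are reported with
  an explicit flag (`t = 0, p = 1` if all differences are zero; `p = 0` if
  they are constant and nonzero) rather than erroring mid-pipeline.
* **Inter-examiner ICC** (`icc_inter()`): the two-way random-effects,
  single-measure, *absolute agreement* coefficient ICC(2,1), with the
  F-based 95 % interval of McGraw & Wong.  The rationale: examiners are a
  random sample of specialists, each contributes single readings, and
  systematic examiner shifts must count as disagreement — absolute
  agreement, not consistency.  Repeated reads are averaged within examiner
  first.  The estimator is verified against brute-force sums-of-squares
  oracles on all small design shapes and against the classic 6×4
  illustration matrix (ICC(2,1) = 0.29).
* **Intra-examiner ICC** (`icc_intra()`): one-way random-effects
  single-measure ICC across an examiner's repeats, per examiner, pooled by
  site-count-weighted average.  Within one examiner there is no rater
  factor to model, hence one-way.
* Degenerate grids (no between-site variance) return `NaN` with an
  explanatory flag; a reliability coefficient fabricated from a flat
  design would be meaningless.

The ICC forms are defaults of this package: the underlying reliability
literature admits several variants and the choice is switchable in
analysis code by calling the estimators directly on any sites × examiners
× repeats array.  Each site-at-angle combination is one reliability unit,
since each image is read independently.

## The synthetic study

`run_experiment()` regenerates, in silico, a dry-mandible validation
experiment:

* **Cohort** (`cohort_spec()`): 20 teeth; lengths uniform on 18.2–24.1 mm
  (the span of the physical specimens) or an explicit caliper list; CEJ
  2 mm below the crown reference; an artificial marginal bone level
  targeted at 7.0 mm — the level at which severe periodontitis becomes the
  relevant clinical comparison — with between-tooth SD 1.0 mm, because
  re-seating teeth in softened wax achieves the target only approximately
  and a literally constant level would leave the bone-level metric with no
  between-site variance at all (its reliability coefficient would be
  undefined).  About 30 % of teeth are modelled with separate mesial and
  distal roots, the distal 0.5–1.5 mm shorter.
* **Imaging**: parallel mode at receptor tilt 0° and 30°.  Parallel
  projection is the idealisation the long-cone paralleling technique is
  designed to approach, and it makes the ratio invariance exact, which is
  the property under study; 30° is a receptor-angle discrepancy that
  plausibly occurs between two clinical exposures of the same site.
  Central mode with f = 300 mm, d = 15 mm is available for magnification
  studies, and is not the default precisely because its height-dependent
  magnification adds a small real relRBL bias that would confound the
  noise-only null the dual-angle comparison is meant to exercise.
* **Readers** (`reader_model()`): 4 examiners × 2 blinded repeats; each
  landmark click gets isotropic Gaussian noise of SD 0.15 mm on the
  receptor.  Click precision is not a published quantity; 0.15 mm (2–3
  pixels at 0.06 mm/px) is a realistic figure for a trained examiner on a
  displayed radiograph and places the simulated ICCs in the 0.8–1.0 band
  reported for such panels.  It is a configuration knob, not a claim about
  any particular examiner.  An optional per-examiner bias shifts only the
  AC landmark — the crest is the hardest point to call — because a
  constant shift of all landmarks cancels in every distance and would be
  unobservable.
* **Stability**: the holder/stent assembly is modelled as perfect — no
  tooth movement between exposures — so the angle change is the only
  systematic difference between conditions.

Pixel conversion uses 0.06 mm/px and frame offsets that keep all simulated
coordinates non-negative; simulated landmark CSVs are indistinguishable in
format from hand-annotated ones and can be fed back through
`cli_measure()`.

What the generator does **not** emulate: grey-scale image content and
detector blur (landmarks are clicked on coordinates, not found in pixels),
anatomical ambiguity of the crest under superimposition, examiner drift
over a session, patient motion, or disease progression.  Passing the
simulated-study checks therefore shows that the measurement chain and the
statistics behave correctly under the stated geometry and noise model — it
does not certify performance on clinical images, where landmark
identifiability dominates.

## Numerical conventions and problem sizes

* Tolerances: exact-invariance properties are asserted to 1e-9 mm (the
  projection arithmetic is closed-form); estimator-vs-oracle identities to
  1e-10.
* Degenerate inputs fail with classed conditions (`relrbl_input_error`,
  `relrbl_degenerate_error`), which the CLI maps to exit codes 2 and 3.
* Randomized property tests run 1000 geometry configurations and 1000
  tooth/angle draws under fixed seeds; Monte-Carlo recovery checks use 500
  replicates at the statistics level and 150 down-scaled end-to-end
  replicates (6 teeth, 2 examiners), sizes chosen to keep the default test
  run fast while leaving Monte-Carlo error well below the asserted bounds.
* The default experiment seed (1) is recorded in every output; identical
  seeds give byte-identical CSV and JSON outputs.

## Known limitations

* The single-angle description of a projection maps the full
  source–receptor–tooth configuration onto one receptor tilt (plus an
  optional tooth tilt); clinical mispositioning can combine both with
  off-axis beam placement, which is representable as tooth `center` offset
  but not exercised by the default scenario.
* relRBL inherits any error in the apex or crown landmark into every
  bone-level ratio of that tooth; its reliability is therefore bounded by
  tooth-length reliability, and it cannot rescue images where the apex is
  cut off or obscured.
* The paired analysis pairs sites (N = 40, two aspects per tooth); aspects
  of one tooth share a bone level and are not strictly independent, which
  the paired design absorbs into the site effect but a variance-component
  purist would model hierarchically.
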