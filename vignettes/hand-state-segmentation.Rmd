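---
title: "Segmenting continuous hand-joint motion into discrete semantic states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting continuous hand-joint motion into discrete semantic states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handstates)
```

## The model

A *motion primitive unit* is one joint moving in one motion form; ten of
them (finger MCP/PIP flexion, finger abduction, thumb MCP/IP flexion,
thumb abduction, wrist flexion/extension, wrist radial/ulnar deviation)
span the pose space of intentional hand gestures, with the finger DIP and
thumb TMC flexions treated as linearly coupled followers. The working
hypothesis, grounded in the mirror mechanism — the perception and the
execution of a gesture engage the same representations — is that each
primitive's continuous angle range carries only a small number of
discrete *semantic states*, and that the same state boundaries govern
observers and performers.

The perceptual analysis follows the method of constant stimuli. For a
standard gesture at angle $s$ and a contrast gesture at angle $x$, the
difference degree $p(x)$ is the proportion of observers judging the pair
semantically different. Its probit $Z(x) = \Phi^{-1}(p(x))$ is assumed
linear in $x$ on either side of the standard, and is fitted by ordinary
least squares after excluding cells with $p \in \{0, 1\}$ (an optional
$1/(2n)$ continuity correction can retain them instead). The criterion
$Z^\ast = \Phi^{-1}(0.75) \approx 0.6745$ — conventionally reported as
0.67, but compared at full precision — marks a just-noticeable semantic
difference. Key derived quantities:

* the **curve maximum**: the fitted $Z$ at the aROM endpoint opposite the
  standard (the fitted lines are monotone away from their standard, so
  this is the maximum over the range; extrapolation beyond the aROM is
  forbidden);
* the **semantic median**: the angle where the two boundary-standard
  curves intersect, carrying equal difference from both extremes.

The decision tree in `segment_round1()` yields one state (both maxima
below $Z^\ast$), two states split at the median ($Z$(median) below
$Z^\ast$), or a referral to the median-standard round. In
`segment_round2()` the median-standard judgments are fitted in two
sections, split strictly below/above the median (a cell at the median
itself is excluded — its difference from itself is zero by
construction); if both section maxima clear $Z^\ast$, the boundaries are
the intersections of each section with the corresponding boundary curve,
and each intersection's $Z$ must stay below $Z^\ast$ for the three
regions to be internally homogeneous. Should an intersection land
outside the aROM, the primitive is flagged unresolvable with
diagnostics; clamping would silently fabricate a boundary, so it is
deliberately not performed. Deeper recursion (four or more states) is
flagged but not pursued: no primitive in the study domain requires it.

## Choices on points the analysis leaves open

Several procedural details admit more than one reading; the package
fixes them as follows and exposes flags where an alternative is
defensible.

* **Pooling.** The "average Z score" is the probit of the proportion
  pooled across participants and the two swapped presentations — one
  binomial cell per (primitive, standard, contrast). Fitting
  per-participant curves and averaging coefficients is statistically
  noisier at 40 Bernoulli trials per cell and is not the default.
* **ICC variant.** Inter-rater reliability uses ICC(2,1): two-way random
  effects (both the subject sample and the two experimenters are treated
  as random), absolute agreement, single measure, computed from the
  two-way ANOVA mean squares. Constant data (every subject executing
  exactly 0°) leaves no variance to apportion; the ICC is reported as
  undefined with a note rather than as an error or a fabricated 1.0.
* **Outlier rule.** Feature angles are means after removing values
  beyond Tukey fences (1.5 × IQR past the type-7 quartiles), applied to
  rater-averaged values; averaging precedes outlier removal. Reported
  feature angles are rounded to whole degrees, matching ruler precision.
* **Boundary adjustment.** When upper-state executions cross a
  perceptual boundary, the new demarcation is the multiple of the
  granularity (default 10°) nearest the midpoint of the feasible window
  — strictly above the lower state's maximum execution, at least the
  criterion-crossing angle, strictly below the upper state's minimum
  execution — with ties rounded up. The published finger-MCP case
  (49°, 47°, 65°) yields 60° under this rule; the rule generalizes the
  one-off published adjustment and is configurable.
* **Range widening.** A feature angle beyond the nominal aROM maximum
  widens the maximum to the next multiple of 10°, reflecting that
  published aROM tables are conservative population bounds.
* **Merging and signs.** Mirrored primitives merge into a signed axis
  with the shared neutral state counted once. For wrist deviation the
  published classification places the two-state side on the positive
  axis (0–40° after widening) and the one-state side mirrored to −20°;
  the source's radial/ulnar labels are internally inconsistent, and the
  package follows its final classification table.
* **Interval convention.** States are lower-closed/upper-open, so a
  boundary-coincident angle belongs to the upper state; the published
  tables print touching ranges without assigning the boundary. A dense
  scan in the test suite confirms the shipped intervals tile each
  (widened) range without gaps or overlaps under this convention.
* **Finger-MCP boundary.** The published real-world table leaves a gap
  (state 2 ending at the adjusted 60° line, state 3 starting at the
  perceptual 70.4° line) while the device-space table uses 70.4°
  throughout. The shipped segmentation uses 70.4°, which tiles the
  range; the 60° line is retained in the segmentation's provenance.
* **Device-space tables.** Applying the fitted mappings to the
  real-space boundaries (`map_segmentation()`) is the package's default
  transfer; the shipped device-space reference reproduces the published
  device table verbatim, whose boundary numbers equal the real-space
  ones. Both are available and clearly distinguished.
* **Sign policy in calibration.** The device reports finger abduction
  with inverted sign; its measurements are fitted as magnitudes. The
  wrist measurements' negative values at 0° are genuine bias and are
  retained.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| criterion `z_criterion()` | `qnorm(0.75)` ≈ 0.6745 | Z | 75%-of-trials JND convention |
| contrast step | 10° (5° for wrist deviations) | degrees | published stimulus grid |
| blocks | 3 × 108 trials | — | published session structure |
| coupling coefficients | 1.0, clamped | — | qualitative "follows" constraint |
| Tukey fence multiplier | 1.5 | IQRs | standard box-plot rule |
| adjustment granularity | 10 | degrees | round gesture-design numbers |
| participants (perception/expression) | 20 | — | study condition |
| subjects (calibration) | 10 | — | study condition |

## What the synthetic generators emulate

The observer model generates Bernoulli judgments with
$P(\text{different}) = \Phi(z_0 + g_s\,|x - s|)$: linear in $Z$ with
distance from the standard, matching the analysis's fitting assumption
(this is a modeling choice of the package, not an empirical claim). The
per-standard slopes $g_s$ are derived from the model's true boundaries
so that the population curves intersect exactly at those boundaries —
the analysis estimand equals the generator truth by construction, which
is what makes parameter-recovery tests meaningful. Default baselines and
slopes place each regime's decision quantities on the intended side of
the criterion with margins of several binomial standard errors at 20
participants: one state (maxima at $Z = 0.1$), two states ($Z = 0.2$ at
the boundary), three states ($Z = 1.2$ at the median). The performer
model draws subject angles from a normal distribution truncated to the
aROM and adds rater noise rounded to whole degrees; the device model
applies an affine bias plus Gaussian noise (default SD 8°, within the
up-to-12° scale the calibration summaries report).

What the generators do *not* emulate: learning or fatigue across blocks,
lapses and response bias, inter-participant threshold heterogeneity,
left/right position effects (the swap flag is carried but does not alter
the generating probability), non-Gaussian device error, and any
dependence between primitives within a pose. Passing recovery tests
therefore show that the pipeline inverts its own assumed data-generating
process at realistic sample sizes — not that real judgment data satisfy
those assumptions.

## Numerical choices and degenerate inputs

Proportions of 0 or 1 map to `NA`, never ±Inf; curves need at least two
finite points with distinct angles. Parallel curves have no
intersection and raise an error, as does inverting a zero-slope mapping.
All angles are decimal degrees with inclusive aROM bounds. Every
simulator takes an explicit seed, restores the caller's RNG state, and
is byte-reproducible; schedule shuffling is a pure permutation, so the
stimulus multiset is seed-invariant. Problem sizes throughout the test
suite mirror the study conditions (20 participants, 10 calibration
subjects) with 8–20 seeded replicates for recovery properties, keeping
the default suite fast while leaving the binomial margins comfortable.

## Known limitations

The pipeline operates on static poses of single primitives; trajectory
semantics, whole-hand dynamics and inter-primitive dependencies are out
of scope. The published boundary values for the shipped classification
derive from the original raw human data and are carried as reference
fixtures — the package re-derives the published affine mapping
coefficients and decision-rule outputs, but not those boundaries, which
would require the deposited per-trial records. ICC is implemented for
exactly two raters; the adjustment rule assumes a single infringing
boundary at a time.
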