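# handstates

Hand gestures convey meaning through the angles of a small set of *motion
primitive units* — one joint moving in one motion form, such as finger PIP
flexion or wrist ulnar deviation. Although each joint moves continuously,
people both perceive and express only a handful of discrete *semantic
states* per primitive (straight / half bent / bent, and so on).
`handstates` implements the full analysis that turns raw psychophysical
and motion-capture data into that discrete semantic space: it is aimed at
researchers in gesture interaction, sign-language coding, and movement
psychophysics who need quantitative state boundaries and typical angles
rather than qualitative labels.

## The analysis

**Perception (constant stimuli).** For each primitive, observers judge
whether a contrast gesture at angle *x* is semantically consistent with a
standard gesture (the two aROM endpoints, then the semantic median). The
difference degree *p(x)* — the proportion of "different" judgments, pooled
over participants and the two swapped presentations — is probit
transformed, *Z(x) = Φ⁻¹(p(x))*, after excluding cells with *p* ∈ {0, 1},
and fitted by ordinary least squares against *x*. The just-noticeable
difference criterion is *Z* = Φ⁻¹(0.75) ≈ 0.67. The decision tree:

* both curve maxima < 0.67 → one state;
* maxima ≥ 0.67 and *Z*(median) < 0.67 → two states, split at the
  *semantic median* (the intersection of the two boundary curves);
* *Z*(median) ≥ 0.67 → a median-standard round is run, its curve fitted in
  two sections; the intersections of those sections with the boundary
  curves become the two boundaries of a three-state segmentation.

**Expression.** Performers report state counts and execute typical
gestures for each state, measured by two raters. The package reconciles
state counts (proprioceptive surplus states at aROM extremes defer to
perception), computes inter-rater reliability as Shrout–Fleiss ICC(2,1),
extracts feature angles as outlier-trimmed means (Tukey 1.5 × IQR
fences), validates executions against the perceptual intervals, re-sets
infringed boundaries by a midpoint rounding rule, widens aROMs that
measured feature angles overshoot, and merges mirrored primitives
(wrist flexion/extension, radial/ulnar deviation) into signed axes.

**Device calibration.** An optical hand tracker is calibrated at 0–100%
of each primitive's range; the affine mapping *measured = α + β·actual*
is fitted by OLS, errors are summarized as the normalized measurement
error |mean measured − actual| / range span, and segmentations are
transferred into device space (open-ended extreme intervals, no
clamping).

**Coding.** Poses encode to vectors of state indices under a
lower-closed/upper-open interval convention and decode back to typical
angles; the shipped eight-primitive classification spans
3·3·2·2·2·2·3·2 = 864 codes.

A synthetic-data module simulates observers (Bernoulli judgments from a
psychometric model linear on the Z scale), performers (Gaussian subject
and rater noise) and devices (affine bias plus Gaussian noise), with
seeds, so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(handstates)

## perception: recover a 3-state segmentation from synthetic judgments
p <- default_primitives()
sched1 <- build_exp1_schedule(seed = 7)                  # 324 stimulus sets
sched2 <- build_exp2_schedule(p[p$id == "finger_pip_flexion", ],
  medians = c(finger_pip_flexion = 55), seed = 8)
obs <- observer_model("finger_pip_flexion", rom = c(0, 110),
  n_states = 3, boundaries = c(30, 80))
j1 <- simulate_judgments(obs, sched1, n_participants = 20, seed = 9)
j2 <- simulate_judgments(obs, sched2, n_participants = 20, seed = 10)
segment_primitive(j1, j2, "finger_pip_flexion")
#> Segmentation [finger_pip_flexion]: 3 state(s), boundaries {29.89, 78.81},
#>   rom [0, 110] (resolved)

## device calibration from the published cell means
maps <- fit_mappings(calibration_reference())
maps$finger_mcp_flexion
#> Affine mapping [finger_mcp_flexion]: measured = 5.58 +0.79 * actual
#>   (r2 = 0.999, n = 5)

## encode / decode a pose against the published classification
segs <- reference_segmentation("real")
code <- encode_pose(c(finger_pip_flexion = 91, thumb_mcp_flexion = 10), segs)
code$state_index
#> [1] 3 1
decode_code(code, segs)
#> finger_pip_flexion  thumb_mcp_flexion
#>                 91                  5
```

The recovered boundaries 29.9/78.8 sit within measurement noise of the
generating truth 30/80; the fitted mapping reproduces the published
equation `measured = 5.63 + 0.78 * actual` to the printed precision; PIP
at 91° is "fully bent" (state 3) and decodes back to that state's typical
angle 91°, while thumb MCP at 10° is the relaxed state, whose typical
angle is 5° (the thumb rests slightly flexed).

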