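---
title: "Methods: thermography knowledge mining with thermoapos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermography knowledge mining with thermoapos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoapos)
```

This vignette is the package's own account of its methods: the model each
stage assumes, the tunable parameters and why their defaults are what they
are, what the synthetic phantoms do and do not emulate, and the places
where the design was genuinely open and a choice had to be made.

## Data model

A `temperature_field` is a rows × cols grid of temperatures in °C,
1-based `(row, col)`, origin top-left. Two conventions carry through the
whole package:

* **Exact 0.0 °C is the reserved background code.** No physical scene in a
  ~25 °C thermostatic chamber contains a 0 °C pixel, so a zero cell always
  means "classified as background by the filter".
* The on-disk dialect (`.tgrid`) is little-endian, row-major, with an
  8-byte header (rows, cols as 32-bit unsigned) and a 16-bit unsigned
  payload in centi-degrees. It is lossless to 0.01 °C — the thermal
  sensitivity scale of clinical detectors — and round-trips bit-exactly.
  The phantom generator rounds to the same 0.01 °C so that in-memory and
  file-backed runs are identical.

## Background filtering

The filter assumes a *bimodal* global temperature histogram: an ambient
mode (chamber air, walls) well below a skin mode. The steps are
histogram → Gaussian smoothing → first-two-peak detection → threshold →
zeroing. Parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| `bin_width` | 0.1 | °C | one order above the 0.01 °C raw precision; stabilizes peak detection without blurring the modes |
| `smooth_size` | 5 | bins | size-5 discrete Gaussian operator; σ = size/5 = 1.0 bin, a conventional discretization when only the size is prescribed |
| `min_prominence_frac` | 0.05 | fraction of max frequency | noise wiggles on a counting histogram need a qualification floor; 5 % of the modal frequency rejects them while keeping any mode of real mass |
| `threshold_mode` | `"midpoint"` | — | see below |

Boundary handling of the smoother is half-sample reflection, which together
with the normalized symmetric kernel conserves total count mass. Peak
prominence uses the standard topographic definition; a curve end is an open
side and contributes no valley floor (otherwise the lowest-temperature
mode, which often sits at the histogram edge, would be assigned zero
prominence).

"The median between the two peaks" admits two readings: the midpoint
(t₁+t₂)/2 of the peak temperatures, or the median of the pixel temperatures
strictly between them. Both are implemented; the midpoint is the default
because it is parameter-free and symmetric, and the segment median is
available as `threshold_mode = "segment-median"`. On well-separated modes
the two nearly coincide.

"First two peaks" is read as the two *lowest-temperature* qualifying
maxima: in a 25 °C room the background mode always sits below every skin
mode, so these are the ambient mode and the first body mode, and the
threshold falls in the valley between background and body.

**Idempotence.** A field that already contains coded zeros is returned
unchanged. The alternative — re-thresholding the nonzero remainder — is
wrong on purpose: a filtered body is itself multimodal (regional
temperature structure), and a second bimodal cut would remove real skin.

## ROI segmentation

Segmentation is anchor-driven: 12 manually marked landmarks generate 18
quadrilaterals, symmetric about the midline (the vertical through the mean
column of forehead, chin, belly-button and crotch anchors). The exact
vertex formulas are a documented, overridable rule table
(`roi_geometry()`); the defaults are:

* **palms**: silhouette run at the wrist row, extended down to the last
  silhouette row in that column band;
* **forearms / upper arms**: wrist–elbow and shoulder–elbow row bands,
  columns from the arm's silhouette run at the band midpoint;
* **anterior elbows**: a square centered on the elbow anchor with side
  half the wrist–elbow distance (the "same-size scale": anthropometric
  lengths set region sizes so the rule transfers across body sizes);
* **face halves**: forehead-to-chin rows, columns from the head silhouette,
  split at the midline;
* **clavicle fossae**: chin-to-shoulder rows between each shoulder anchor
  and the midline;
* **chest**: shoulder row down to the midpoint of the armpit and
  belly-button rows, armpit column to midline on each side;
* **upper / lower abdomen**: chest bottom to belly-button row
  (shoulder-column band), and belly-button to crotch rows (torso
  silhouette run).

Pixel membership is decided at cell centers with the even-odd rule,
boundary inclusive — midline pixels therefore belong to both members of a
left/right pair, a deliberate choice that keeps mirror symmetry exact.
Silhouette runs must lie within 3 px of the governing anchor's column;
otherwise the ROI raises a labelled segmentation error (this is what turns
"arm out of frame" into a diagnosable failure rather than a silently wrong
region). Anchors on background cells only warn: medial landmarks sit close
to the silhouette edge.

Background pixels inside a quad are *retained* at this stage; the
granulation step is the one that knows what a zero means.

## Granulation

Each ROI's temperature multiset is clustered by 1-D K-means (Lloyd
iterations), with everything that is normally random pinned down:

* K = 4 iff the ROI contains a zero (background) cell, else K = 3;
* initial centers: (0, nonzero min, nonzero mean, nonzero max) for K = 4,
  (min, mean, max) for K = 3;
* assignment ties go to the lower-index center; an empty cluster keeps its
  previous center; convergence when the largest center shift < `tol`.

`tol = 1e-6` °C and `max_iter = 300` are far below the 0.01 °C data
precision and far above the observed iteration counts, so they act as pure
safety rails. The result is bitwise reproducible, and on separated-mixture
inputs it coincides with the exhaustive contiguous-partition optimum (the
test suite checks this against a dynamic-programming oracle up to 200
values).

The binary attributes compare each ROI's extreme nonzero cluster means
against the whole-body averages T̄min and T̄max; boundary equality fires
the attribute (inclusive ≤ / ≥), so a body whose 18 ROIs are identical
carries every attribute — the informative case is deviation from the
whole-body norm. "Largest cluster" is read as the largest-*mean* nonzero
cluster, symmetric with the explicitly nonzero smallest cluster; averaging
a background cluster at 0 °C into a whole-body skin reference would be
physically meaningless. Clustering operates on temperatures, not gray
levels: the grayscale standardization (`render_grayscale`, tfw = 10 °C,
tfs = max − tfw) exists to normalize display and palette effects, while
the attribute definitions are stated in °C.

The formal context has a fixed column order `ROI1-H, ROI1-L, …, ROI18-L`
and row order equal to input order, so serialized contexts are
reproducible byte for byte.

## APOS

The attribute partial order structure is realized as a coverage-ordered
intent trie plus an explicit extent-containment relation. This satisfies
the four generation principles — more-covered attributes higher; similar
objects adjacent (shared prefixes); higher nodes more universal; one branch
per object intent — which are the only normative content available for the
construction. Equal coverages are broken lexicographically by attribute
name; the tie-break is arbitrary but documented and stable, which is what
determinism requires. Objects with empty intents cannot be placed on an
attribute path; they are kept on a designated root branch with a warning
rather than dropped. Graph layout (how "close" similar branches are drawn)
is delegated to the DOT renderer; it is a presentation concern, not a
property of the structure.

A full formal-concept lattice is deliberately *not* built: branches of the
trie already reconstruct the context losslessly (tested), and concept
enumeration would add exponential cost without changing any downstream
statistic.

## Verification statistics

The mined rule points at the face (ROI9∪ROI10) and chest (ROI13∪ROI14).
Features are face-minus-chest differences of the mean, max and min of the
pooled nonzero pixels; pooling the two sides is the default (a
`pool = FALSE` alternative averages per-side statistics first — with
symmetric regions of similar size the two differ little, and pooling is
the natural reading of "the face").

Both t-test variants are computed side by side — Welch with
Welch–Satterthwaite fractional df, and the pooled equal-variance test —
because standard statistical software prints both rows and reported tables
mix them; a Brown–Forsythe helper (`select_t_variant`) recommends one, but
the package does not silently choose. Confidence intervals from summary
triples use mean ± t(df, 0.975)·SE. Post-hoc power recovers the pooled SD
from the standard error of the difference (SD = SE·√(n/2)) and evaluates
the two-sided noncentral-t power with both rejection regions counted, so a
null effect yields power exactly α. The direction of subtraction is
face − chest and the group contrast is case − control; positive values
mean the case group's face is relatively warmer.

## The synthetic phantoms

`generate_phantom()` renders a parametric silhouette — head ellipse, neck,
torso, two hanging arms, expressed in fractions of the image so the same
anatomy works at any resolution — at a skin baseline of 32.5 °C plus
per-region offsets, over a 25 °C background, with independent Gaussian
pixel noise (0.3 °C default). The offsets follow the qualitative
physiology of skin temperature: warm depressed areas (clavicle fossae
+2.0 °C, anterior elbows +0.8 °C, face +1.3 °C), cool extremities (palms
−1.2 °C), near-baseline trunk — giving the few-degrees whole-body spread
and the bimodal global histogram the pipeline assumes.

`generate_cohort()` adds, per subject, a whole-body baseline shift
(SD 0.5 °C, which cancels in difference features) and a face-specific
shift: N(effect, subject SD) for cases, N(0, subject SD) for controls. The
design point — 43 per group, effect 2.74 °C, between-subject SD 1.53 °C —
is the study design the statistics target; the SD is derived from a
reported standard error of 0.33 °C at n = 43 via SD = SE·√(n/2), a derived
rather than printed value.

What the phantoms do **not** emulate: anatomical realism, posture
variation, anchor-marking error, vignetting or other detector artifacts,
spatially correlated noise, and confounders (exercise, alcohol, drafts)
that an acquisition protocol controls away. Passing tests therefore
demonstrate the *computational* correctness of each stage and the
recoverability of an implanted group effect — not clinical validity on
real thermograms.

## Problem sizes in the test suite

Unit tests run on 128 × 168 phantoms and cohorts of 2–3 per group; the
end-to-end checks use a full-size 256 × 336 phantom, one 43-per-group image
cohort, a 100-seed effect-recovery study and a 1000-replicate null study at
the feature level (drawing the per-subject difference features directly
from the between-subject model, which is the same quantity the image
pipeline estimates but without re-rendering 86 images per replicate).
K-means is checked against its DP oracle up to 200 values, and APOS
against brute-force intent enumeration on contexts up to 6 × 6.

## Known limitations

* The default ROI vertex rules are one concrete geometry consistent with
  the anchor governance table; they are an extension point, not a claim
  that they reproduce any particular clinic's rules.
* Peak detection needs a separable background: scenes without one (or
  crops containing only skin) error by design rather than guessing.
* The midline split assumes an approximately upright, frontal posture.
* No multiple-testing correction is applied across the three difference
  features; the three tests are reported side by side.
* Single-person scenes only; no morphological cleanup of the body mask.
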