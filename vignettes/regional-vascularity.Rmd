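---
title: "Methods: regional vascularity quantification in colour Doppler ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional vascularity quantification in colour Doppler ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicad)
```

## The problem and the model

Thyroid nodules are routinely triaged with grey-scale ultrasound (GSU) and
colour Doppler. Malignant nodules tend to be hypervascular, and the *spatial
distribution* of flow matters: central vascularity is the classical red
flag, peripheral flow leans benign. Visual grading of that distribution is
notoriously observer-dependent. `vicad` replaces it with three numbers per
nodule — peripheral, central and overall **vascular index (VI)** — computed
from a hand-outlined region of interest (ROI):

* the *primary ROI* is the filled interior of the outline (the whole
  nodule);
* the *secondary ROI* (central region) is an inward offset of the primary by
  a distance equal to `offset_pct`% of the primary's maximum Feret diameter;
* the *peripheral region* is the set difference;
* `VI = 100 × (colour pixels) / (all pixels)` within each region, where a
  pixel is "colour" iff its channel spread `max(R,G,B) − min(R,G,B)`
  exceeds `tau`.

At cohort level, the *optimum offset* is the level at which the VI of benign
and malignant nodules differs significantly (two-tailed p < `alpha`) in
**both** regions; on the study cohort's summary statistics (84 benign / 27
malignant) that level is 22%, and it is unique. ROC analysis then fixes VI
cut-offs, and three rules classify a nodule as malignant: at least one
suspicious GSU feature; all three VIs at or above their cut-offs; or both at
once.

## Recovering the ROI from the outline

The outline is matched by **exact** colour equality against
`annotation_color` (default pure green, `(0,255,0)`): Doppler colour maps
live in red/yellow and blue/cyan, grey tissue has `R = G = B`, so pure green
cannot collide with either. Exactness is also why lossy formats are
rejected — JPEG chroma noise would both blur the outline and create phantom
"colour" pixels.

The interior is recovered by flood-filling the background from every image
border pixel with outline pixels as barriers, using 4-connectivity for the
fill. A closed 8-connected curve blocks every 4-connected path (the digital
Jordan property), so a 1-pixel hand-drawn contour is already watertight, and
any thicker contour trivially so. The interior is whatever is neither
outline nor reachable background; enclosed background islands are filled
(the nodule is a solid region), and outline pixels themselves are excluded
from the mask. Several disjoint closed outlines raise an ambiguity error
unless `select_largest = TRUE`.

## Inward offsetting

`offset_px = round_half_up(offset_pct/100 × max_diameter(mask))`, in pixel
units between pixel centres. The maximum diameter is computed over the
convex hull of the boundary pixels, which provably equals the brute-force
all-pairs maximum.

Two modes realize the offset:

* **`distance`** thresholds the exact Euclidean distance transform:
  `central = {d(p, background) > offset_px}`. This is the geometric
  reference — on a disc of radius r it returns a concentric disc of radius
  `r − offset_px` up to discretization.
* **`erosion`** (default) iteratively erodes the mask with 3×3 structuring
  elements, which is the classical raster realization of contour-preserving
  inward offsetting and mirrors how such algorithms are typically
  implemented. Each iteration removes one pixel of depth along the axes.

The erosion schedule deserves a note. No convex combination of the
city-block cross and the Chebyshev square reproduces the Euclidean ball: the
cross under-reaches diagonals (support 0.707/iteration), the square
over-reaches them (1.414), and *both* over-reach the 22.5° directions. A
strict 1:1 alternation accumulates up to ~11% directional error, which at a
29-pixel offset visibly squares off the central region (Jaccard overlap with
the exact mode drops to ~0.83 on a disc). `vicad` therefore uses the minimax
mixture — two cross erosions, then one square, repeating — whose composite
element stays within ~6% of the Euclidean ball in every direction; measured
Jaccard overlap against the distance mode is ≥ 0.90 for smooth blobs at all
offsets from 5% to 25% (≥ 0.94 on discs). Users wanting exact geometry
should simply use `mode = "distance"`; the erosion mode exists because it is
the operation the quantification procedure is defined by.

Edge policies: `offset_pct = 0` returns the identity partition; an offset
that exhausts the region yields an *empty central mask with a warning*, not
an error — small or elongated nodules genuinely have no interior at large
offsets — and the VI of an empty region is reported as missing (`NA`), never
0, so cohort statistics are not biased downward.

A remark on the offset ceiling: offsets are percentages of the maximum
*diameter*, so a 25% offset on a disc already leaves a central disc of only
half the original diameter. Literature sometimes describes the central
region as "the inner 90% of the diameter", which cannot be reconciled with
this parameterization; `vicad` implements the diameter-percentage definition
throughout.

## Statistical machinery

* **Two-sample tests from summaries.** Published cohorts come as
  (n, mean, SD) triples, so `two_sample_t()` implements the summary-form
  t-test directly. The default is **Welch** (unequal variances,
  Welch–Satterthwaite df). That choice is substantive, not cosmetic: on the
  study's per-offset summaries only Welch makes 22% the *unique* offset
  with both regions significant — the pooled Student variant would let 25%
  qualify as well (central p = 0.0076-scale shifts push it to 0.026).
  Degenerate inputs follow the convention t = 0, p = 1 for identical
  zero-variance groups. No multiple-testing correction is applied across
  offsets, matching the original analysis; `alpha` defaults to 0.05,
  two-tailed.
* **Summary-table quirk.** One published offset row (23%) prints its four
  cells in an order inconsistent with every other row; `study_vi_summaries()`
  restores the common column order, consistent with the neighbouring rows.
  Its printed significance marks do not reproduce from the printed summary
  statistics under any variant; this does not affect the selected offset.
* **ROC cut-offs.** `roc_cutoff()` scans the observed scores as candidate
  cut-offs under the rule "positive iff score ≥ cutoff" and maximizes the
  Youden index J = sens + spec − 1, breaking ties toward the lower cutoff
  (favouring sensitivity at equal J). The published cut-offs (19.7 / 9.1 /
  20.2 for peripheral / central / overall VI) ship as `study_cutoffs()`;
  the optimality criterion behind the published values is not documented,
  so they are treated as study-derived defaults, not as reproduction
  targets.
* **Diagnostic metrics** are kept at full precision internally; reports
  format to one decimal with *half-up* rounding (banker's rounding would
  mis-render values such as 56.25). `counts_from_rates()` inverts the
  metric computation (tp = round(sens·n⁺), tn = round(spec·n⁻)) so that
  published tables can be checked for arithmetic closure — the validation
  suite reproduces every published NPV/PPV/accuracy cell this way.
* **Decision rules.** Cut-off comparison is inclusive (≥). A nodule with an
  empty central region is conservatively called benign by the VI rule: the
  rule requires all three indices to reach their cut-offs and an absent
  index cannot. The combined rule is the record-wise conjunction of the GSU
  and VI rules. The "overall" component uses the representative image's
  whole-nodule VI (offset-independent); regional components use the chosen
  offset — matching the sequencing in which the representative image is
  selected before regional analysis.

## What the synthetic data emulates — and what it does not

**Phantoms** emulate exactly the features the pipeline touches: a
blob-shaped ROI (disc with low radial harmonics) on Rayleigh-distributed
grey speckle, a closed outline in the annotation colour, and colour pixels
from a red/blue Doppler-like palette planted as independent Bernoullis at
the target densities in the true peripheral/central zones (partition taken
from the exact distance mode). The generator returns the true mask,
partition and planted counts, so outline recovery can be checked
pixel-for-pixel and VI recovery to the Bernoulli sampling error (±2
percentage points at region areas ≥ 1000 px). Phantoms are *not* physical
ultrasound simulations: no point-spread function, no attenuation, no
burned-in overlays or colour bars. Real scanner exports must be cropped to
the image area before analysis.

**Cohorts** emulate the study's statistical structure: per-offset regional
VI as truncated normals on [0, 100] with the study's group means/SDs,
overall VI likewise, GSU features as independent Bernoullis at the group
prevalences. Two honest modelling choices:

* *Mean calibration.* Several groups have SD ≥ mean (benign central VI is
  11.9 ± 15.1), and a normal truncated at 0 with those parent parameters
  would realize a mean ~5.6 points too high. The generator therefore
  calibrates the parent location (one-dimensional root-find against the
  closed-form truncated mean, integrated over the latent factor) so the
  *realized* group mean equals the nominal one. The realized SD then falls
  below nominal in strongly truncated groups — unavoidable, since a
  truncated-at-0 normal cannot have coefficient of variation above 1.
* *Latent coupling.* A per-nodule latent factor (correlation `rho`, default
  0.7) couples VI across offsets and regions, because a nodule
  hypervascular at one offset is hypervascular at its neighbours;
  independent draws would be physiologically absurd and would break
  representative-image logic. The true joint distribution is unknowable
  from group summaries, so `rho` is a modelling default, not an estimate.

GSU features are drawn independently of VI within group (only marginal
prevalences are published), so composite-rule performance on synthetic
cohorts should be read qualitatively: the conjunction rule looks better on
synthetic data than it would on a real cohort where GSU and vascularity are
correlated.

A consequence worth stating plainly: at the study's sample sizes (84/27)
the per-offset Welch tests have only moderate power, so across simulated
replicates the offset 22% qualifies (both regions significant) in a
majority of cohorts, but the *smallest* qualifying offset fluctuates below
22 whenever sampling noise makes an earlier peripheral test significant —
the central-region difference is genuinely significant at every offset from
5% to 22%, so the conjunctive rule hinges on the peripheral tests alone.
Exact recovery of 22 as the selected optimum is therefore a minority event
(~15% of replicates) under honest resampling of the published effect
sizes; the published selection reflects the one observed dataset. The
validation suite asserts both properties at their face values.

## Validation problem sizes

The shipped validation suite uses phantoms of 72–192 px side (region areas
up to ~11 000 px), 100-phantom partition sweeps, ROC brute-force checks up
to n = 200 scores, and 60–100 replicate cohort simulations at the study's
group sizes — sizes chosen so the full suite runs in well under a minute
per file on a laptop while keeping every Monte-Carlo margin wide.

## Known limitations

* Manual outlining is required; there is no automatic segmentation.
* Lossy-compressed inputs are rejected rather than tolerated; `tau` (10–20)
  exists for users who must analyze images that passed a lossy pipeline,
  at their own risk.
* Doppler overlays (colour bars, callipers) burned into the image area are
  counted as colour pixels; crop them out beforehand.
* Cut-off defaults are study-derived from a single cohort dominated by
  papillary carcinoma; they are not population constants.
* The erosion mode is a raster approximation; its residual anisotropy
  (≤ ~6%) is documented above and bounded by tests, with the exact
  distance mode available wherever geometry matters.
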