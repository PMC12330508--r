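---
title: "Simulating and analyzing individual variability in category-selective visual cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing individual variability in category-selective visual cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(votcsim)
```

## The scientific problem

Ventral occipitotemporal cortex (VOTC) contains a mosaic of
category-selective regions. The visual word form area (VWFA), a
text-selective patch on the occipitotemporal sulcus (OTS), is small and
sits at noticeably different cortical locations in different people; the
fusiform face area (FFA) is larger and spatially more consistent. This
combination has a well-known methodological consequence: an analysis
that averages subjects on a common surface template can fail to show any
text-selective cortex even when every individual has a perfectly
identifiable VWFA, because the patches do not land on the same template
vertices. `votcsim` packages that whole argument as testable code: a
forward simulator with known ground truth, and the standard analysis
chain — per-vertex GLM, contrast t-maps, percent-signal-change (PSC)
maps, threshold-based ROI definition inside anatomical limits, Dice
overlap, probabilistic maps and group ROIs, vertex-wise group t-tests,
and selectivity comparisons between native and template-defined ROIs.

Because every map has a known generating truth, claims that are
qualitative in real data ("group averaging washes out the VWFA") become
parameter-recovery statements that the test suite can check.

## The forward model

**Surface.** Maps live on a regular 2-D grid mesh (default 48 × 48
vertices at 1 mm spacing); an icosphere is available when spherical
topology matters. The full-scale surface template has 163,842 vertices per
hemisphere; the simulator works at desk scale and treats its grid as the
common template, with per-subject misalignment modeled explicitly (see
below). A `votc_mask` marks the VOTC territory (default 40 × 40 mm) and
splits it into an OTS-like band and a fusiform-like band; ROI rules
confine text/pseudofont/limb clusters to the former and face/object
clusters to the latter, emulating drawing ROIs within anatomical
boundaries.

**Patches.** Each subject carries five category patches. Defaults
(radii/jitter in mm):

| patch      | band     | radius | center jitter (children / adults) | amplitude (% signal) |
|------------|----------|--------|-----------------------------------|----------------------|
| text       | OTS      | 4      | 10 / 3                            | 1.2                  |
| pseudofont | OTS      | 3.5    | rides on text at +3 mm offset     | 1.0                  |
| limb       | OTS      | 6      | 3                                 | 1.2                  |
| face       | fusiform | 8      | 2                                 | 1.5                  |
| object     | fusiform | 5      | 3                                 | 1.0                  |

Choices worth explaining:

- *Text is small and variable, face large and stable* — the central
  empirical asymmetry being modeled. The "children" cohort (default
  n = 30) has text jitter 2.5× the patch radius; the "adults" cohort
  (default n = 15) has modest jitter. The magnitudes are chosen as
  plausible for the phenomenon, not fitted to any dataset.
- *Patches are hard-edged discs by default.* A Gaussian amplitude skirt
  (`falloff_sd`) is optional; it matters in the task-modulation analyses,
  where a soft detection boundary is the mechanism by which attentional
  gain changes suprathreshold extent. With hard edges and high SNR, ROI
  size saturates at the disc and task effects on size vanish.
- *Within-subject mosaic.* Distinct patch cores never overlap inside one
  subject: the text patch is placed first (its location is the variable
  of interest), and later patches are redrawn, or pushed to core
  tangency, if they collide. Across subjects, however, the limb
  territory (group center 2 mm from the text group center) heavily
  overlaps the text territory — the same OTS cortex is text-selective in
  one person and limb-selective in another. That between-subject
  interdigitation, with within-subject tiling, is what makes a template
  ROI capture non-text cortex in most individuals.
- *Pseudofonts ride on text.* The pseudofont patch is attached to the
  realized text center at a fixed 3 mm offset, giving the intended
  partial overlap between script-like and text-selective cortex.
- *Amplitudes.* A non-selective visual response (0.5% signal to every
  stimulus category) covers the whole VOTC; patch amplitudes add on
  top. Each subject has one log-normal responsiveness scale
  (`amp_cv = 0.35`) shared across categories: between-subject gain
  heterogeneity without reordering category preferences. (Independent
  per-category draws would let a fifth of subjects genuinely prefer
  pseudofonts inside their own text patch, which contradicts the
  phenomenon the simulator is meant to produce.) The one-back task
  multiplies all stimulus responses by `oneback_gain = 1.3`; the gain
  magnitude is a free parameter of the model, set to a modest
  attentional enhancement.

**Design and signal.** A localizer run is 65 back-to-back 4-s trials
(four 800 ms images with 200 ms gaps per trial, represented as a 4-s
boxcar), randomized with category counts balanced to within one, TR
1.19 s, two runs per task. The BOLD signal is
`baseline × (1 + Σ_c amp_c/100 · x_c(t))` with `x_c` the category boxcar
convolved with a unit-peak double-gamma HRF (peak ≈ 5 s), normalized so
one isolated trial peaks at 1. Noise is iid Gaussian per vertex-volume
(optional AR(1)); the default `noise_sd = 1.4` (baseline = 100) was
calibrated once so that the four-run in-patch text t-statistic is ≈ 8, a
realistic localizer SNR and the reference point for the recovery
analyses. No hemodynamic nonlinearity, physiological noise, motion, or
session drift is simulated.

**Registration error.** Projecting a native map or ROI to the template
is modeled as a per-subject rigid shift (`registration_sd = 2` mm) with
nearest-vertex resampling — a deliberately minimal stand-in for
surface-registration misalignment. Zero shift is the identity; ROI
vertices shifted off the mesh are dropped (boundary clipping).

## The analysis chain

**GLM.** All runs are fit jointly by ordinary least squares with one
HRF-convolved regressor per stimulus category (shared across runs;
blank is the unmodeled baseline) plus per-run intercept and linear
drift. Task-specific analyses refit the same model per task pair.
Contrast t-maps use `t = c'β / sqrt(σ² c'(X'X)⁻¹c)`; "category versus
others" weights are +1 on the target and −1/4 on the four other
stimulus categories — equal weights, since trial counts are balanced
(trial-count weighting would change nothing here). PSC maps are
`100 · β / baseline` with the baseline taken as the mean run intercept;
the blank category maps to identically zero.

**ROIs.** Manual drawing is replaced by a deterministic rule: vertices
with `t > 3` (strict) intersected with the region's anatomical
subregion, so clusters crossing the boundary are clipped; an optional
minimum-cluster-size drops speckle a human rater would ignore. An ROI
may legitimately be empty — the region is then "not identifiable" in
that subject, and downstream summaries exclude (and log) the subject
rather than fabricating a response.

**Dice.** Cross-task consistency uses
`DSC = 2|A∩B| / (|A| + |B|)` with the standard set-cardinality
denominator. Two empty ROIs get `DSC = 0` with a flag (not `NaN`), so
population summaries stay computable.

**Group analyses.** Native ROIs are transported to the template with
each subject's registration shift; the probabilistic map is the
per-vertex fraction of subjects covering that vertex, and the group ROI
keeps vertices *strictly above* 0.2 — "more than 20% of participants" —
so a vertex at exactly 0.2 is excluded. Vertex-wise group inference is a
one-sample t-test of subjects' template-space contrast values against
zero (dof = n − 1), displayed at |t| > 3. Overlap-indicator maps label
every template vertex `text_only` / `face_only` / `both` / `neither`
from the union of subjects' text and face ROIs; percentages of the
template total are reported to one decimal place, matching the printed
precision convention for such counts.

**Selectivity.** Response profiles are mean PSC per category over ROI
vertices. The text-selectivity index is
`(T − O) / (|T| + |O|)` with `T` the text PSC and `O` the mean of the
other four stimulus categories (pseudofonts included, blank excluded):
bounded in [−1, 1], positive iff text exceeds the mean other response,
robust to negative PSC, with `0/0` defined as 0 and flagged. The exact
index formula used in the literature varies and is rarely printed; this
choice is documented rather than claimed canonical. Note one
non-obvious property: for `T < 0 < O` the index saturates at −1, so it
is strictly monotone in `T` only on the preferred side. Comparisons
between ROI families (native vs group/template) use within-subject
differencing with paired t-tests — for balanced designs this is the
exact counterpart of a subject-random-intercept model, which is why no
mixed-model fit is needed at this scale.

## Numerical choices

- **Zero-variance sentinels.** Noise-free data make `σ² = 0` up to
  floating-point dust; residual variances below `var_tol = 1e-10` are
  treated as exactly zero, and the t-statistic becomes `±Inf` when the
  contrast is meaningfully non-zero (|c'β| > √var_tol) and 0 otherwise.
  The same rule applies to between-subject variance in group t-maps.
  Without it, t-maps at zero noise are ratios of rounding errors.
- **Transport.** Nearest-vertex resampling; on the grid this is exact
  index arithmetic. Values transported from outside the mesh are 0.
- **Drift.** Orthogonal polynomials per run; order 1 by default.
- **Determinism.** Every sampler is a pure function of (config, seed);
  the pipeline derives per-subject, per-run seeds from the master seed,
  and rerunning a configuration reproduces outputs byte-identically.

## The washout demonstration

The package's headline scenario runs the children-like cohort (n = 30,
text jitter 2.5× radius) with `noise_sd = 0`: between-subject variance
then comes *only* from spatial topography (patch jitter, amplitude
heterogeneity, registration error), which is the phenomenon under
study. This makes the demonstration sharp: every subject has an
identifiable native text ROI, yet no vertex of the group text-contrast
t-map reaches t = 3 — any "significant" vertex would have to be
explained by geometry, not sampling noise. (With measurement noise
included, signal-free vertices follow an exact Student-t null, so a few
of several thousand vertices exceed 3 by construction and the statement
would have to be about clusters instead.) The face contrast, driven by
the large stable patch, keeps a large supra-threshold cluster in the
same run. The group VWFA derived from the stable adult-like cohort,
applied to the washout cohort's template-space maps — exactly how
published template ROIs are used — lands on cortex that is limb- or
pseudofont-selective in most of those subjects and yields a mean
selectivity index at or below zero, while the native ROIs' mean index
is strongly positive.

## Problem sizes and what the tests show

The test suite and the acceptance script run at desk scale: a 2,304
vertex mesh, 30 + 15 subjects, four 232-volume runs per subject —
chosen so the full chain re-runs in minutes while keeping every
analysis statistically meaningful (in-patch t ≈ 8, group dof ≥ 14).
Passing tests show that the *analysis chain* behaves as claimed on data
with the assumed statistical structure: exact GLM inversion at zero
noise, nominal t-nulls under pure noise, ROI recovery with Dice ≈ 0.99
at calibrated SNR, task-gain effects on ROI size in the right
direction, cross-task text preference in ≥ 95% of subjects, and the
washout contrast between individual and group analyses. They do not
show that real cortex satisfies those assumptions: the simulator's
noise is Gaussian and spatially unstructured, its registration error is
a rigid shift, its patches are discs, and its task effect is a single
multiplicative gain. The package is an argument about analysis methods,
not a substitute for data.

## Known limitations

- The grid mesh has boundary effects: patches jittered near the VOTC
  edge are clipped, and transported maps lose content shifted off the
  mesh. The defaults keep patch territories well inside the mask.
- Probabilistic maps and group ROIs inherit the nearest-vertex
  transport; sub-millimetre shifts round to whole vertices at the
  default spacing.
- The mosaic constraint resolves collisions greedily in a fixed
  category order; under extreme jitter the pushed centers can compress
  against subregion boundaries.
- Imported template ROIs are supported as FreeSurfer label files, but no
  true spherical registration is performed — the package's template is
  its own mesh.
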