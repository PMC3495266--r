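---
title: "Longitudinal vertex-wise surface morphometry with hippomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal vertex-wise surface morphometry with hippomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippomorph)
```

## The problem

Volumetry often misses localized structural change. When every subject's
surface shares one template topology — vertex *i* is the same anatomical
location in everyone — change can instead be measured *per vertex*:
displacements at baseline, rates of displacement over follow-up, and
group contrasts of either, corrected for the thousands of simultaneous
tests. hippomorph implements this analysis for closed genus-0 surfaces
such as the hippocampus, in a design with three groups (healthy controls
and two treatment arms), five scheduled visits over two years, and heavy,
group-dependent dropout.

## The measurement model

**Geometry.** Volumes use the divergence-theorem signed-tetrahedron sum
over faces, which is exact for polyhedra and translation-invariant for
closed surfaces. Vertex normals are area-weighted averages of incident
face normals, forced outward by a centroid test; on a level-3 icosphere
the worst angular deviation from the true radial direction is about
0.01 rad, shrinking with refinement — adequate for projecting millimetre
displacements.

**Slopes.** For subject *s*, hemisphere *h*, vertex *i*, the scalar
trajectory is $d_i(t) = (v_i(t) - v_i(0)) \cdot n_i(0)$ with $n_i(0)$ the
*subject's baseline* outward normal (not the template normal: follow-up
surfaces are expressed relative to the subject's own baseline geometry,
mirroring how longitudinal scans are registered within subject; a template
-normal variant would differ only through baseline shape deviation).
The vertex slope is the least-squares slope of $d_i(t)$ over the available
weeks, times 52 to give mm/year. Week 0 contributes the exact value 0.
Subjects with a single visit have no slope and are excluded. Volume slopes
are kept in mm³/week, matching how such rates are conventionally reported.

**Group statistics.**

- *Percent negative*: fraction of a subject's vertices with slope
  strictly < 0 (exact zeros, a measure-zero event under noise, count as
  non-negative).
- *Large-magnitude percentages*: fractions outside control-derived
  thresholds, compared by one-way ANOVA on hemisphere-averaged values and
  by a mixed ANOVA with hemisphere as the repeated factor, with
  Shapiro–Wilk reported per group as a diagnostic gate and
  Fisher's-LSD-style pooled-*t* post hocs (uncorrected by default, since
  that is how post hoc p-values are conventionally reported after a
  significant omnibus F; Bonferroni is available).
- *Slope CDFs*: empirical distribution of the group mean slope map over
  the combined left+right vertices.
- *Vertex-wise maps*: Mann–Whitney U per vertex (exact by enumeration when
  both groups have ≤ 8 subjects and no ties — the cutoff keeps ~13k-vertex
  map comparisons fast — otherwise normal approximation with tie and
  continuity corrections), thresholded by Benjamini–Hochberg step-up FDR
  at q = 0.05. All tests are two-sided.

**Control thresholds.** "Very negative" means more than 1 SD below the
control mean slope; "very positive" more than 1 SD above. Three reference
distributions are offered. The default, `mean_map`, takes moments over the
vertices of the *control group mean slope map*. The alternatives pool all
control subjects' vertex slopes (`pooled_vertices`) or use per-subject
mean slopes (`subject_means`). The default matters: individual slope maps
are several times noisier than the group mean map (per-vertex measurement
noise and subject fields do not average out within a subject), so
thresholds derived from pooled individual slopes would sit so far from
zero that control tail percentages would fall to ~16%, whereas thresholds
from the mean-map distribution put control tail percentages in the
observed mid-30s range. The method used is always recorded in the output.
Reference moments can also be supplied directly via `threshold_pair()`;
with a control mean of −0.011 mm/year and SD 0.057 mm/year the thresholds
are −0.068 and +0.046 mm/year.

**Baseline analyses.** Week-0 volumes enter a two-way mixed ANOVA
(patient status between, hemisphere within — with two within levels this
reduces exactly to ANOVAs on per-subject means and differences, which is
how it is implemented), plus ANCOVAs adjusting for sex and total
gray-matter volume (supplied as a per-subject covariate) and an
illness-duration-adjusted comparison of the treatment arms. Shape uses
PCA per hemisphere on the flattened 3V-vectors (SVD of the centered
subject × 3V matrix, 20 components by default) followed by Wilks' Λ
MANOVA with Rao's F; covariate control residualizes the scores first.
MANOVA is run per hemisphere rather than jointly — the per-hemisphere
Wilks values are the quantities of interest, and a joint repeated-measures
MANOVA would not change the substantive comparisons.

**Mixed model for volume.** A linear mixed model with fixed effects
group, categorical week and their interaction, a subject random intercept
and i.i.d. residuals (compound symmetry — the simplest structure
consistent with repeated measures, with no evidence available to fit
anything richer). The single variance ratio is profiled out and estimated
by 1-D REML optimization; time and group×time are Wald F tests under
sum-to-zero contrasts with containment denominator df
(N − n_subjects − numerator df), which reproduces the classical
repeated-measures ANOVA exactly in the balanced case. Groups that lack
entire visit weeks create missing design cells; the non-estimable columns
are dropped, as standard mixed-model software does.

## The synthetic cohort

The generator is the package's stand-in for trial MRI data and defines the
default study conditions:

| parameter | default | why |
|---|---|---|
| group sizes | CON 51, OLZ 67, HAL 67 | the emulated trial's arms |
| visits (weeks) | 0, 12, 24, 52, 104; controls 0, 12, 52 | scan schedule; controls were not scanned at 24/104 |
| retention | per group/visit, e.g. HAL week 104 = 0.164 | observed availability; independent per visit |
| template | bent tapered ellipsoid, icosphere level 3 (642 vertices/hemisphere), volumes L 2528 / R 3010 mm³ | control mean volumes; head/body/tail and lateral/medial zones for targeting fields |
| baseline patient deformation | −0.55 mm on head + lateral zones, smoothed | anterior-lateral inward deformation pattern |
| subject baseline variation | scalar offset SD 0.25 mm (shared across hemispheres, +0.12 mm for males) + smooth field SD 0.25 mm | gives ~300 mm³ between-subject volume SD and a low-rank shape space |
| group slope fields | mean −0.011 / −0.022 / −0.066 mm/year + shared susceptibility pattern scaled to SD 0.049/0.049/0.071 | reproduces the group mean-map moments (SD ≈ 0.057/0.057/0.077 after adding the averaged-out subject noise) |
| subject slope variation | scalar SD 0.057 mm/year + smooth field SD 0.12 mm/year | between-subject mean-slope SD ≈ 0.057 |
| vertex noise | 0.13 mm per visit | puts individual slope-map vertex SD near 0.22 mm/year |

Smooth fields are white noise averaged 20 times over the mesh graph —
spatially coherent, effectively low-rank (which is why ~20 principal
components capture > 90% of baseline shape variance), and different for
every subject, so the *locations* of strong slopes vary across
individuals. The spatial variation of the *group* slope fields rides on a
single susceptibility pattern shared by all groups; consequently the
HAL−OLZ difference is nearly uniform over the surface, small at every
single vertex relative to between-subject variability. That is precisely
what produces the design's central dissociation: a strongly significant
group effect on the large-magnitude slope percentage coexisting with
few or no vertex-wise FDR rejections. Because group means of the subject
scalar offsets fluctuate (SD ≈ 0.057/√n), occasional cohort realizations
draw a larger-than-nominal group gap and then show a nonzero but modest
rejection fraction — single-cohort vertex-wise results are genuinely
unstable in this regime, which is the methodological point.

The per-subject slope noise depends strongly on follow-up: a subject seen
only at weeks 0 and 12 has ~8× the slope noise of one followed to week
104. Dropout therefore not only shrinks n but inflates the patient
percentage SDs, as reflected in the wider patient columns of the
percentage summaries.

Everything is a deterministic function of the config seed; two cohorts
with the same config are byte-identical on disk.

### What the generator does not emulate

Real hippocampal anatomy beyond a zoned banana shape; scanner/site
effects and drift; registration error structure; non-Gaussian,
heavy-tailed slope distributions. The last point is visible in the
percent-negative metric: with Gaussian fields, a mean shift moves the
percent-negative and the tail percentages together, so the generator's
percent-negative group effect is stronger than would be seen with
heavier-tailed real data where tail metrics dissociate more sharply from
the median crossing. Passing tests therefore demonstrate correct
recovery of configured effects under Gaussian smooth-field variability,
not fidelity to every distributional feature of real cohorts.

## Numerical choices and degenerate inputs

- 52 weeks/year exactly, everywhere.
- Exact-zero slopes count as non-negative; thresholds use strict
  inequalities.
- Degenerate (zero-area) faces are tolerated with a warning in normal
  computation (synthetic deformations could collapse a triangle); open
  meshes are a hard error for volume computation.
- A constant control slope distribution cannot define thresholds and is
  refused rather than silently producing a zero-width band.
- Constant percentage metrics (e.g. everything at 100%) short-circuit to
  p = 1 rather than 0/0.
- The Mann–Whitney variance guard returns p = 1 when all values are tied;
  rank-deficient ANCOVA designs raise an error naming the collinear
  column; a singular within-group scatter in the MANOVA raises an error
  advising PC truncation, and `shape_manova()` truncates automatically
  (with a warning) to n − k − 1 score columns.
- REML boundary fits (no between-subject variance) collapse to
  λ = 10⁻⁸, i.e. effectively ordinary least squares.

## Problem sizes used in the shipped checks

The package's own verification suite runs the full design — 185 subjects,
level-3 templates (1284 combined vertices), 20 replicate cohorts for the
recovery checks, 50 replicate null cohorts for the FDR calibration, and
2000-replicate null simulations per statistical test — in a few minutes
on one CPU. Mesh resolution is a config parameter: level 4 per hemisphere
(10,242 vertices, ~20k combined — the published scale is ~13k over both)
runs the same pipeline proportionally slower.

## Known limitations

- The divergence-theorem volume is the volume of the *surface model*, not
  of any voxel segmentation it came from.
- The containment denominator df in the mixed model is an approximation
  under unbalanced dropout (exact when balanced); with missing design
  cells the "time" main effect tests the estimable subset of contrasts,
  which (as in any software that drops aliased columns) depends on the
  coding.
- Left/right hemisphere fields are simulated independently given the
  shared scalar offset; real bilateral correlation of local shape change
  is likely stronger.
- The exact Mann–Whitney path requires no ties; tied data always use the
  corrected normal approximation regardless of sample size.
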