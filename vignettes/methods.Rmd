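---
title: "Curvature-based electrode localization and distance-profile labeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based electrode localization and distance-profile labeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameters and design decisions
behind `eeglocate` — what each stage assumes, why the defaults are what
they are, and what the synthetic phantoms do and do not tell you about
real data.

## The problem

Simultaneous EEG–fMRI leaves a free by-product in the T1-weighted
structural scan: every gel-filled electrode appears as a small
protrusion on the scalp. Given a triangulated scalp surface extracted
from that scan and aligned to the fiducial-based subject coordinate
system (SCS), the package answers two questions: *where* are the
electrodes (localization), and *which* montage channel is each one
(labeling).

## Coordinate convention

All geometry lives in the SCS: origin at the midpoint of the left and
right preauricular points, +x through the projection of the nasion,
+y toward the left preauricular point, +z superior. `to_scs()` builds
this frame by Gram–Schmidt orthogonalization of the fiducial vectors;
it is a rigid map, so all inter-point distances — the raw material of
the labeling step — are preserved exactly. The axial cut *z* > 0 used
during localization excludes the nose, cheeks and lips, which would
otherwise contribute high-curvature vertices.

## Localization

### Curvature signal

Two discrete estimators are provided (`vertex_curvature()`):

* **`mean_cotan`** (default): signed mean curvature from the cotangent
  Laplace–Beltrami operator with mixed Voronoi vertex areas, its sign
  fixed by projection onto the outward vertex normal. Units 1/m.
  Electrode bumps are convex, so a *signed* convexity measure keeps
  concave folds (ear creases) from competing with them. On an
  icosphere of radius 0.1 m the estimate is within a fraction of a
  percent of the analytic 10 /m.
* **`angle_deficit`**: `2*pi` minus the incident-angle sum, a discrete
  Gaussian-curvature integral (radians). Cheaper and exactly satisfies
  the Gauss–Bonnet identity (vertex sum `4*pi` on closed genus-0
  meshes), which the tests use as an oracle.

Face orientation is made consistent by winding propagation across
shared edges followed by a signed-volume check, so outward normals do
not depend on the input file's face order. Boundary vertices of open
meshes receive a `-Inf` sentinel and can never become detections.

### Detection pipeline

`localize_electrodes()` runs five stages with these defaults
(`localize_params()`):

| parameter | default | meaning |
|---|---|---|
| `z_min` | 0 m | axial search cut (SCS) |
| `top_k` | 2000 | highest-curvature vertices kept |
| `cluster_radius` | 0.01 m | single-linkage distance, the electrode diameter |
| `min_cluster_size` | 10 | smallest cluster accepted as an electrode |
| `guard_frac`, `contrast_min` | 0.25, 0.5 | baseline-prominence guard (below) |

`top_k = 2000` is sized for a 64-channel cap on a ~10,000-vertex mesh
and is deliberately exposed: denser caps or finer meshes need a larger
budget. Clustering is **single-linkage** (connected components of the
within-radius graph): it is parameter-free beyond the radius,
order-independent, and matches the idea that the vertices within one
electrode's footprint chain together; the alternative reading
(complete linkage, all pairwise distances within 1 cm) was considered
and rejected because it fragments elongated vertex groups. The cluster
**centroid** is the unweighted mean of member vertex positions;
curvature-weighted centroids were not used because the weighting is
estimator-dependent while the unweighted mean is within ~3 mm of the
bump apex at realistic mesh resolutions.

**Baseline-prominence guard.** A fixed top-K budget always selects
*something*: on a mesh whose protrusions occupy fewer than K vertices,
the remainder of the budget lands on smooth scalp, and single linkage
happily chains those scattered vertices into large spurious clusters
that can absorb genuine bump clusters nearby. The guard removes
selected vertices that are not prominent against the scalp baseline:
with `q50` and `q99` the quantiles of the eligible curvature
distribution, the surface is declared protrusion-free (no candidates)
when `(q99 - q50) / |q50| < contrast_min`, and otherwise vertices
below `q50 + guard_frac * (q99 - q50)` are dropped. Electrode bumps
put their cores far above this threshold (apex curvature is an order
of magnitude above scalp curvature), so the guard leaves them intact
while eliminating smooth-scalp selections entirely — a uniform dome
yields zero candidates rather than one giant cluster. Set
`baseline_guard = FALSE` to reproduce the raw top-K behavior.

Ties at the top-K cut are broken by ascending vertex index: stable,
deterministic, and independent of floating-point sort details.

Candidate counts exceed the true electrode count on purpose — empty
electrode holders, reference/EOG sites and image artifacts all
protrude. `prune_candidates()` replaces interactive cleanup with an
explicit keep/drop list so a pruning decision is recorded and
reproducible; `rank_candidates()` (largest clusters first) is a
convenience starting point beyond the core method.

## Labeling

### Distance profiles

For electrode *i* of an *n*-electrode set, the profile is the vector
of its `n - 1` Euclidean distances to the others, sorted descending
(`distance_profile()`). Sorting removes identity and order, making the
profile invariant to any rigid motion of the set — labeling therefore
needs no registration between subject and template. The assumption
doing the work is that for a fixed cap design the *shape* of this
decay curve varies more between montage positions than between
subjects.

An unlabeled electrode is proposed the label of the template electrode
maximizing the Pearson correlation between profiles
(`match_single_template()`). Zero-variance profiles (degenerate
synthetic geometry only) get r = 0 with a warning instead of NaN.
Correlation ties are broken by the earlier label in the montage's
sequential order — the same rule the voting stage uses, so tie
handling is uniform.

### Voting and symmetry resolution

With several templates, each proposes a label per electrode and the
plurality wins; tied pluralities go to the earliest label in the
channel sequence (`vote_labels()`). Symmetry resolution runs **once,
on the voted assignment**, not per template: per-template resolution
would let a single template's midplane failure poison its proposals,
and post-vote resolution keeps all template proposals on the same
footing.

The midplane is the vertical plane through the electrodes labeled FPZ
and OZ (configurable anchors); its normal is `(OZ - FPZ) x z-hat`
oriented to +y, so the positive side is the subject's left. Resolution
order matters and is:

1. any label proposed by `duplicate_unlabel_threshold` (default 3) or
   more electrodes is withdrawn from all of them — three claimants
   cannot be mapped onto a two-member pair;
2. each remaining paired label is flipped to the member matching its
   electrode's side of the midplane;
3. a pair label still duplicated after flipping (both claimants on one
   side) is split by relative signed distance — the farther-left
   electrode keeps the left label;
4. duplicated midline labels keep the best-supported claimant (vote
   count) and unlabel the rest, so the final assignment never repeats
   a label.

The threshold of three follows from the arithmetic of two-member
pairs; it is exposed because sparser montages might warrant stricter
handling. Electrodes exactly on the midplane (side 0) keep their
proposed label. If FPZ or OZ is missing or duplicated the run aborts
with a midplane-undefined error; cohort experiments catch this,
exclude the run, and report the excluded fraction alongside the
aggregates rather than silently dropping it.

All paired labels are compared against the midplane (not only
same-hemisphere proposals): the profile of a mirror twin is nearly
identical, so every paired proposal is potentially on the wrong side.
Mastoids M1/M2 are treated as an ordinary symmetric pair.

## The phantom generator

Real validation data (T1 scans of capped subjects) cannot ship with
the package, so `make_phantom()` / `make_cohort()` build synthetic
heads with known ground truth. Design goals: geometry realistic enough
that every pipeline stage is exercised (including spurious detections
and pruning), fully deterministic under a seed, and solvable — the
generator is a test instrument, not an adversary.

* **Head shape**: an ellipsoid with semiaxes 0.095 x 0.075 x 0.080 m
  (adult head), its center 15 mm above the fiducial plane — on real
  heads the preauricular axis passes below the widest part of the
  vault, so scalp continues below z = 0 just as the nose and ears do.
  A shallow circumferential **rim relief** band (0.6 mm high, around
  brow/temple/inion level) adds the low-amplitude convexity structure
  real scalps carry at the cap edge; it also gives the top-K stage the
  same kind of non-bump competition it faces on real meshes (the
  baseline guard removes it from the final clusters). Meshes are
  subdivided icosahedra (10,242 vertices by default), closed and
  genus 0 by construction.
* **Montage**: the packaged 64-channel cap (`quikcap64_montage()`)
  uses the standard vendor channel sequence, 8 midline labels and 28
  symmetric pairs. Its canonical directions are synthetic: a 10-10
  style layout compressed above the fiducial plane and relaxed to
  near-uniform spacing (minimum inter-electrode pitch 24.8 mm on the
  default head) so that 1 cm clustering can in principle separate all
  64 sites. They are a documented stand-in, not vendor coordinates;
  montage JSON files are user-replaceable.
* **Bumps**: Gaussian displacement along the surface normal, peak
  `bump_height` = 3 mm, scale (sigma) `bump_radius` = 5 mm — the
  ~1 cm electrode footprint. Heights of real protrusions vary with gel
  amount; 3 mm makes detection clear but not trivial (apex curvature
  ~10x scalp). `posterior_attenuation` scales bump height at
  occipital/temporal sites to mimic gel drying at the back of the
  head during long sessions, the usual cause of shallow, hard-to-detect
  protrusions at occipital and lateral sites.
* **Placement jitter**: total angular SD 0.02 rad (~1.7 mm) per
  electrode, decomposed as 75% of the variance in a whole-cap rigid
  rotation and 25% independent per-electrode slip
  (`jitter_rigid_frac`). Caps mostly shift and twist as a unit;
  modeling all jitter as independent would shrink nearest-neighbor
  distances far more than real cap placement does.
* **Dummies**: 15 extra bumps in the belt just below the montage
  (posterior-biased), at least 2 cm — in practice 2.4 cm — from every
  true site, emulating empty holders and reference/EOG electrodes.
  They are the source of the "extra candidates" the pruning step
  exists for.
* **Cohorts**: per-subject semiaxis scatter (SD 5%) plus fresh jitter
  per subject, seeded subject-by-subject so cohorts are reproducible
  element-wise.

**What the phantoms do not emulate**: MR intensity artifacts, hair and
gel smearing, ears and noses as connected high-curvature structures,
mesh defects from surface reconstruction, and truly asymmetric head
shapes. Passing the phantom suite therefore demonstrates the
correctness of the algorithms under the stated geometry, not the
field performance on clinical scans; on real data the detection rate
at occipital and lateral sites is expected to drop and manual pruning
effort to grow.

## Evaluation

`detection_metrics()` matches candidates to ground truth one-to-one,
greedily by ascending distance under a 5 mm tolerance. Greedy matching
was chosen over optimal assignment for transparency; the tests verify
it agrees with the exhaustive optimum on small instances, and at
phantom spacing (>24 mm between electrodes, 5 mm tolerance) the two
cannot differ. The 5 mm default stands in for the visual inspection
used when ground truth has no numeric tolerance; it is configurable.

`labeling_metrics()` scores TP (labeled correctly), FP (labeled
wrongly) and FN (left unlabeled) as percentages of the full electrode
count; an unlabeled electrode is always FN, never FP.

`cohort_experiment()` runs the multi-template evaluation at
phantom scale: each subject in turn is the unlabeled set, the
templates are drawn from the rest (all single-template pairs; a
seeded sample of combinations for 3 and 5 templates, since the
combination count grows combinatorially), and midplane failures are
excluded and counted.

## Problem sizes and numerical choices in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated
data: phantoms at 10,242 vertices; clustering oracles on up to 300
random points against a union-find transitive closure; labeling
cohorts of 12–26 subjects at ~3 mm jitter with 10 sampled template
combinations per subject — sizes chosen so the full suite completes in
about a minute while every stage still runs at its default operating
point. Template-count monotonicity is asserted within two standard
errors of the paired per-subject differences, since sampled template
combinations make the comparison stochastic.

## Known limitations

* The labeling step requires the candidate set to be pruned to exactly
  the montage size first; it does not handle missing or surplus
  electrodes, which the original procedure also resolved by hand.
* Profiles assume one rigid cap design across subjects and templates;
  mixing cap models invalidates the template pool.
* Symmetric-pair resolution assumes approximate left/right symmetry of
  the head; strongly asymmetric heads can defeat the midplane rules.
* The curvature default (`mean_cotan`) needs an orientable, closed (or
  nearly closed) mesh; heavily defective surface reconstructions
  should be repaired upstream.
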