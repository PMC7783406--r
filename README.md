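# eeglocate

Semi-automated localization and labeling of EEG electrodes from
MR-derived scalp surfaces, for simultaneous EEG–fMRI head modeling.

EEG source reconstruction needs the 3D position *and* the montage label
of every electrode on the subject's head. When EEG is recorded inside
the MR scanner, the gel-filled electrodes show up directly in the
T1-weighted structural scan as small protrusions on the scalp — no
digitizer, camera or extra MR sequence is needed. `eeglocate`
implements the two-step pipeline that exploits this:

1. **Localization by curvature.** On a triangulated scalp mesh aligned
   to the fiducial-based subject coordinate system (SCS: origin at the
   preauricular midpoint, +x through the nasion, +z up), each electrode
   protrusion carries much higher convex curvature than the surrounding
   scalp. The pipeline computes a per-vertex discrete curvature (signed
   mean curvature from the cotangent Laplacian, or the angle-deficit
   Gaussian estimate), restricts the search to *z* > 0 (excluding nose,
   cheeks and lips), keeps the 2,000 highest-curvature vertices, drops
   those not prominent above the scalp's baseline curvature, groups the
   survivors by single-linkage clustering at 1 cm (the electrode
   diameter), discards clusters with fewer than 10 vertices, and
   returns one candidate position per cluster centroid. Spurious
   detections (empty holders, reference/EOG sites, image artifacts) are
   removed with an explicit, reproducible keep/drop list
   (`prune_candidates()`).

2. **Labeling by distance profiles.** Each electrode's *distance
   profile* — its Euclidean distances to all other electrodes, sorted
   in descending order — is a rigid-motion-invariant fingerprint of its
   place in the montage: frontal electrodes decay slowly, the vertex
   decays fast. An unlabeled electrode receives the label of the
   template electrode whose profile has the highest Pearson
   correlation with its own. With several labeled templates a majority
   vote decides (ties go to the earlier label in the cap's channel
   sequence). Because left/right mirror positions have near-identical
   profiles, labels are finally checked against the vertical midplane
   through FPZ and OZ: wrong-side labels are flipped to their
   symmetric partner, duplicated pair labels are split one per side,
   and a label claimed by three or more electrodes is withdrawn.

Real capped-head T1 scans cannot ship with a package, so it
ships a synthetic **phantom generator**: ellipsoidal head meshes
(~10,000 vertices) with Gaussian electrode bumps (3 mm high, 5 mm
scale) at 64 montage sites, per-subject head-shape scatter, cap
placement jitter, and ~15 spurious "dummy" bumps at the cap edge —
together with the ground-truth labeled positions, so detection rate and
labeling accuracy (TP/FP/FN) are measurable end to end.

## Worked example

```r
library(eeglocate)

montage <- quikcap64_montage()        # packaged 64-channel cap montage
montage
#> montage_spec: 64 labels (8 midline, 28 symmetric pairs)
#>   midplane anchors: FPZ (anterior) / OZ (posterior)
#>   canonical directions: present

# a synthetic subject: head mesh with electrode bumps + ground truth
params <- phantom_params(seed = 1)
set.seed(1)
ph <- make_phantom(montage, params)
ph
#> phantom_truth: 10242-vertex mesh, 64 labeled electrodes, 15 dummies

# step 1 — localize candidate electrodes from curvature
cands <- localize_electrodes(ph$mesh)
cands
#> candidate_set: 79 candidates (cluster sizes 10..18)
detection_metrics(cands, ph$electrodes)
#> detection_report: 64/64 detected (100.00%), 15 extra, tol 5.0 mm

# step 2 — label one subject's 64 positions using another as template
co <- make_cohort(2, montage, phantom_params(angular_jitter_sd = 0.036,
                                             seed = 2))
unlab <- electrode_set(co[[1]]$electrodes$points, frame = "SCS")
res <- vote_labels(unlab, list(co[[2]]$electrodes), montage)
res
#> labeling_result: 64 electrodes, 1 templates, 60 labeled, 4 unresolved
#>   unresolved: no_majority_conflict x1, triple_duplicate x3
labeling_metrics(res, co[[1]]$electrodes$labels)
#> labeling_report: TP 92.19%  FP 1.56%  FN 6.25% (n=64)
```

All 64 bumps were found within 5 mm (the 15 extras are the dummy
sites, removable with `prune_candidates()`), and a single
3-mm-jittered template already labels 59/64 electrodes correctly; the
four unresolved electrodes were withdrawn by the duplicate-label
safety rules rather than mislabeled. Adding templates raises TP — see
`cohort_experiment()`.

Real data enter through `read_mesh()` (PLY/OFF/STL/FreeSurfer),
`to_scs()` (fiducial alignment) and `read_electrodes()`
(.sfp/.elc/BIDS electrodes.tsv); results leave through
`write_electrodes()`. A command-line front end with `simulate`,
`localize`, `label`, `evaluate` and `experiment` subcommands is in
`inst/scripts/eeglocate` (all logic is in the exported `run_cli()`).

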