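---
title: "Measuring exercise-induced glenohumeral cartilage strain from segmented MRI contours"
author: "cartstrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring exercise-induced glenohumeral cartilage strain from segmented MRI contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Articular cartilage is biphasic: under load, interstitial fluid is exuded
and the tissue thins; after unloading it recovers over tens of minutes.
Imaging a joint at high resolution immediately before and immediately
after a bout of loaded exercise therefore captures exercise-induced
*compressive strain* as a measurable decrease in cartilage thickness. In
the shoulder this is demanding: glenohumeral cartilage is only about
1.0 mm thick on the humeral head and 1.3 mm on the glenoid, so the whole
chain — segmentation, surface reconstruction, inter-session registration,
thickness measurement — has to work at a few hundredths of a millimetre.

`cartstrain` implements that chain for pre/post-exercise studies of the
glenohumeral joint:

1. **Input.** Per-subject, per-session segmented contour stacks: ordered
   2D point lists per axial slice (0.5 mm spacing, ~0.3 mm in-plane point
   density), labeled `humeral_bone`, `humeral_cartilage`, `glenoid_bone`,
   `glenoid_cartilage`. Sub-pixel manual segmentation is emulated; its
   repeatability (SD ≈ 0.04 mm, i.e. ~3.5% of a 1.15 mm pooled mean
   thickness) sets the method's noise floor.
2. **Reconstruction** (`reconstruct_surface`). Contours are lofted
   slice-to-slice into triangle meshes.
3. **Registration** (`icp_align`). Each post-exercise *bone* is rigidly
   aligned to its pre-exercise counterpart by iterative closest point;
   bone does not deform on this timescale, so the bones carry the
   inter-session pose. The recovered transform is applied to the post
   cartilage.
4. **Thickness** (`compute_thickness_map`). At every bone vertex,
   thickness is the Euclidean distance to the nearest vertex of the
   articular (outer) cartilage surface. Because the post cartilage has
   been registered into the pre frame, pre and post thickness live at the
   same bone vertices — the comparison is site-specific.
5. **Regions and strain** (`build_region_grid`, `compute_strain_table`).
   Thickness is averaged in 2-mm-radius sampling regions — 18 on the
   humeral head, 9 on the glenoid — and regional strain is
   `(t_pre − t_post) / t_pre`, positive in compression. Compartmental
   strain is the mean of a surface's regional strains.
6. **Statistics** (`rm_anova`, `tukey_posthoc`, `pearson_corr`). One-way
   within-subject ANOVAs compare regional strains along the
   anteroposterior and superoinferior axes, Tukey tests follow up
   significant effects, and Pearson correlations relate compartment
   strain to per-subject covariates (BMI, body weight). Summaries are
   reported as mean ± 95% CI (t distribution, n − 1 df).

Because no real imaging data ship with the package, every stage is
validated by *parameter recovery* on a synthetic shoulder phantom with
exact ground truth (`generate_phantom`, `slice_to_contours`).

## The synthetic shoulder

The phantom is built from star-shaped analytic surfaces (every surface is
a radial graph about a centre), which makes three things exact: mesh
generation, plane sections (used to emulate segmentation), and ground
truth.

* **Humeral head**: a mildly triaxial ellipsoid (semi-axes 24, 23.3,
  22.6 mm — a literature-typical 24 mm head with a few percent
  asphericity) carrying two smooth Gaussian surface bumps on its
  non-articular side, analogues of the greater and lesser tuberosities.
  The asphericity and bumps are not cosmetic: a perfect sphere has a
  rotational gauge freedom that makes inter-session registration
  ill-posed, whereas the ellipsoid pins the principal axes and the bumps
  break its residual 180° flip symmetries. Cartilage covers a 120° cap
  facing medially, by default 1.0 mm thick.
* **Glenoid**: a shallow spherical socket (30 mm radius of curvature)
  with a pear-shaped footprint (35 mm superoinferior × 25 mm
  anteroposterior, wider inferiorly as in real glenoids — which also
  removes the flip symmetry an elliptical dish would have). Its default
  thickness field rises from 1.2 mm centrally to 1.5 mm at the
  anteroinferior periphery.
* **Deformation**: thickness is applied along the outward bone normal, so
  the cartilage outer surface is exactly `bone + t`; the post-exercise
  scene scales `t` pointwise by `(1 − ε)` for a configurable strain field
  ε — uniform, a linear anteroposterior ramp, or piecewise-constant over
  anatomical thirds (the mode used to impose reference per-third values).
  Ground truth satisfies `ε = (t_pre − t_post)/t_pre` to 1e−12 by
  construction.
* **Sessions**: the post scene is moved by a configurable rigid offset
  (default experiments use 5° about a random axis plus 3 mm, the
  repositioning scale of a shoulder between scans). Left shoulders mirror
  the anteroposterior axis.
* **Segmentation emulation**: surfaces are sectioned analytically at
  0.5 mm slice spacing (accuracy ~1e−12 mm, so the sphere sections used
  in tests are exact circles), resampled at 0.3 mm, and perturbed by
  independent zero-mean Gaussian noise of SD 0.04 mm along the in-plane
  contour normal. Noise lives on contour points, not mesh vertices,
  because segmentation repeatability is a contour-level statistic.

What the phantom does **not** emulate: image intensities and their
artifacts (no DICOM, no sequence contrast), correlated or rater-specific
segmentation bias (noise is independent per point), labrum and rotator
cuff, and biological between-subject variability (cohort phantoms share
one anatomy and differ only in noise and pose). Passing recovery tests
therefore demonstrates that the *computational* chain is unbiased at the
stated noise level — not that manual segmentation of real TruFISP images
achieves it, and not that real cohorts are as homogeneous. One visible
consequence: synthetic-cohort confidence intervals are far narrower than
real ones (subject-to-subject variation is purely technical), so
repeated-measures tests on synthetic cohorts can flag sub-percent
systematic effects that would be invisible in vivo; only imposed effects
of realistic size are meaningful recovery targets.

## Design choices where the procedure was open

* **Reconstruction by lofting.** Adjacent contours are connected by a
  merge-walk strip triangulation over normalized arc length, with the
  cyclic phase of closed contours aligned by FFT cross-correlation;
  closed stacks are capped by centroid fans. Commercial NURBS lofting is
  not reproducible from its description; lofting is branch-free for
  these anatomies, handles the open cartilage arcs naturally, and its
  error (chord-level, ≪ 0.1 mm at 0.3 mm point spacing) is absorbed by
  the thickness tolerances. A signed-distance/isosurface route was
  considered and rejected: it needs a marching-cubes dependency and adds
  a smoothing bias without improving thickness accuracy.
* **ICP variant.** Point-to-point with kd-tree matching and a
  closed-form (Kabsch/SVD) update — the canonical reading of an
  "iterative closest point" alignment. Matching uses at most 20,000
  moving vertices chosen by a deterministic stride. Two refinements
  matter at this accuracy: (i) *area weighting* — vertices are weighted
  by one third of their incident face area, making updates a surface
  integral; without it, the slice-direction density anisotropy of lofted
  meshes (0.3 mm along contours vs 0.5 mm across slices, fixed in the
  scanner frame) biases the converged pose by degrees; (ii)
  *initialization* by weighted principal axes (the four proper sign
  combinations scored by a 500-point probe residual), falling back to
  centroid-only alignment when the top covariance eigenvalues are within
  1% (axes meaningless). Convergence is declared when the weighted RMS
  residual changes by < 1e−5 mm (100-iteration cap); a coarser 1e−4
  threshold was found to stall in the shallow rotational valley of the
  near-spherical humeral head, leaving degree-scale pose errors.
* **Bone-only registration.** Bones are registered independently
  (humerus↔humerus, glenoid↔glenoid) and cartilage is excluded from
  matching — cartilage deforms, bone does not.
* **Footprint rule.** A bone vertex belongs to the cartilage footprint
  when its nearest cartilage vertex lies within 5 mm *and* its outward
  normal points toward the match (dot ≥ 0). The cutoff exceeds the
  thickest plausible cartilage (~2 mm) by a safety factor; the normal
  test excludes the far cortex of closed bone surfaces. The rule keeps a
  narrow band of bone just beyond the true cartilage edge; sampling
  regions placed at the 20/50/80% footprint quantiles stay > 2 mm inside
  the edge, so regional statistics are unaffected.
* **Region placement.** The region counts are fixed (18 humeral, 9
  glenoid) but there is no canonical placement rule beyond an evenly
  spread appearance. Centers are placed at the 20/50/80% quantiles of the footprint's
  anteroposterior and superoinferior coordinates (3×3 on the glenoid; on
  the humeral head, 2 superoinferior bands split at the median, each
  3×3 by the same rule within the band), then snapped to the nearest
  footprint vertex. Quantiles adapt deterministically to footprint shape;
  an explicit layout table can override the default. Regions may overlap
  (a note is emitted); vertices may contribute to several regions.
* **Anatomical frame.** Mediolateral axis = mean outward normal of the
  glenoid face; superoinferior = principal footprint axis orthogonalized
  against it, signed toward +z; anteroposterior completes the frame and
  always points anterior, so its sign follows laterality — the frame of
  a left shoulder is the mirror (left-handed) image of a right one,
  which is what anatomy does. Near-isotropic footprints (top
  eigenvalues within 1%) are refused as orientationally ambiguous.
* **Two compartmental summaries.** The primary definition is the mean of
  regional strains; the strain of compartment-mean thicknesses is also
  reported, labeled, because compartment-level thickness arithmetic
  (e.g. 1.3 mm → 1.1 mm ⇒ 15%) reflects the latter.
* **ANOVA conventions.** Regions sharing a factor level are averaged
  within subject before the ANOVA (three anterior glenoid regions → one
  anterior value per subject), giving a balanced one-way within-subject
  design. Uncorrected p values are primary; Greenhouse–Geisser-corrected
  values are emitted alongside, labeled. Tukey tests use the
  within-subject error term with the studentized range distribution.
* **Repeatability statistic.** From ≥ 2 repeated segmentations of the
  same anatomy the package reports both the SD across repetitions of the
  mean footprint thickness (`sd_mean_mm`) and the pooled per-site SD
  (`sd_pointwise_mm`). Under the phantom's independent-noise model the
  former is vanishingly small (a mean over thousands of sites), so the
  per-site SD is the statistic comparable to a ~0.04 mm per-measurement
  repeatability; with rater-level bias in real repeated segmentations
  the two converge. The conversion to an equivalent strain
  (`strain_equivalent`) divides by the pooled mean thickness.

## Numerical behaviour and known biases

* Nearest-*vertex* distance overestimates true (perpendicular) thickness
  by ≈ E[d²]/(2t), where d is the tangential offset to the nearest
  vertex; at 0.3 × 0.5 mm sampling this is ~0.014 mm on 1 mm cartilage.
  Because the bias grows as cartilage thins, it depresses measured
  strain by roughly 0.3–0.7 percentage points at 15–17% strain; together
  with residual registration error this is the dominant systematic in
  end-to-end recovery, well inside the ±1.5 pp acceptance band. A
  point-to-triangle refinement is available behind
  `thickness_config(method = "point_to_triangle")` for sensitivity
  analysis; the nearest-vertex definition stays the default because it
  is the convention these thickness maps are defined by.
* Degenerate inputs fail loudly and early: unknown tissue labels,
  non-uniform slice spacing, fewer than two contours per label,
  non-overlapping adjacent contours, empty cartilage meshes, empty
  footprints, unbalanced ANOVA tables, zero-variance correlates. ICP
  that merely fails to converge within its iteration cap returns
  `converged = FALSE` with its residual trace rather than throwing.
* Everything is deterministic given seeds: contour noise is the only
  random element, drawn under a fixed seed with the caller's RNG state
  restored; ICP subsampling uses a stride, never randomness. Cohort
  reruns are byte-identical.

## Problem sizes used in the shipped experiments

The default phantom yields ~40,000-vertex humeral bone and ~7,000-vertex
glenoid bone reconstructions. The packaged recovery experiments
(acceptance script and test suite) use 5 seeds per uniform-strain
condition, 8 phantom subjects for the regional-gradient cohort, and
1,000 replicates for the ANOVA type-I calibration; a single-compartment
subject runs in ~10–20 s, keeping the full suite within a few minutes on
one core. The analysis scripts under `analysis/` process an 8-subject,
two-compartment cohort in ~4 minutes.

## Limitations

Rigid registration only (no deformable or voxel-based alignment); no
continuous strain fields (regional means only); no quantitative MRI
(T2/T1ρ) or contact-force estimation; the humeral 18-region layout
(superior/inferior bands × anteroposterior thirds) is one defensible
arrangement among several and is configurable; equivalence with the
original commercial lofting pipeline is asserted only at the
thickness/strain level, not mesh-level identity.
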