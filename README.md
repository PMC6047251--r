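# cartstrain

Quantifying exercise-induced compressive strain in glenohumeral (shoulder)
articular cartilage from pre/post-exercise MRI segmentations.

## The problem

Articular cartilage is biphasic: joint loading squeezes interstitial fluid
out of the matrix and measurably thins the tissue, which recovers over tens
of minutes after unloading. Imaging a shoulder at high resolution
immediately before and after a loaded exercise bout (e.g. a series of
push-ups) therefore turns cartilage *strain* into a thickness-change
measurement. The catch is scale: glenohumeral cartilage is ~1.0 mm thick on
the humeral head and ~1.3 mm on the glenoid, so segmentation, 3D
reconstruction, inter-session registration and thickness mapping must all
hold up at a few hundredths of a millimetre.

`cartstrain` implements the full measurement chain, for researchers in
joint biomechanics and musculoskeletal imaging:

* **Reconstruction** — labeled segmentation contour stacks (0.5 mm axial
  slices, ~0.3 mm in-plane point density) are lofted into triangulated bone
  and cartilage surfaces (`reconstruct_surface`).
* **Registration** — each post-exercise bone surface is rigidly aligned to
  its pre-exercise counterpart with an area-weighted point-to-point
  iterative closest point algorithm (`icp_align`); bone does not deform,
  so it carries the unknown inter-session pose.
* **Thickness** — at every bone vertex, cartilage thickness is the distance
  to the nearest vertex of the articular cartilage surface
  (`compute_thickness_map`); registering the post cartilage into the pre
  frame makes the pre/post comparison site-specific.
* **Regional strain** — thickness is averaged within 2-mm-radius sampling
  regions (18 on the humeral head, 9 on the glenoid;
  `build_region_grid`), and strain in each region is

  ε = (t_pre − t_post) / t_pre,   positive in compression,

  with compartmental strain the mean of a surface's regional strains
  (`compute_strain_table`, `compartment_summary`).
* **Statistics** — one-way repeated-measures ANOVAs across anatomical
  thirds (anterior/central/posterior, superior/central/inferior), Tukey
  post hoc tests, and Pearson correlations against per-subject covariates
  (`rm_anova`, `tukey_posthoc`, `pearson_corr`); results as mean ± 95% CI.

Because raw study MRI is typically not shareable, the package includes a
**synthetic shoulder phantom** with exact ground truth
(`generate_phantom`, `slice_to_contours`): an aspherical humeral head with
tuberosity bumps, a pear-shaped glenoid socket, configurable thickness and
strain fields, an unknown rigid pose offset between sessions, and 0.04 mm
contour noise emulating segmentation repeatability. Every pipeline stage
is validated by parameter recovery against this ground truth; see the
methods vignette (`vignettes/cartilage-strain-methods.Rmd`) for the model,
design choices, and known biases.

## Worked example

One synthetic subject with a uniform 15% compressive strain imposed on the
glenoid cartilage and an unknown 5° / 3 mm pose change between sessions:

```r
library(cartstrain)

spec <- phantom_spec(
  glenoid_strain_field = field_constant(0.15),
  rigid_offset = random_rigid_offset(5 * pi / 180, 3, seed = 42),
  surfaces = c("glenoid_bone", "glenoid_cartilage"),
  subject = "demo")
ph <- generate_phantom(spec)

pre  <- slice_to_contours(ph$pre,  0.5, 0.3, 0.04, seed = 1,
                          subject = "demo", session = "pre")
post <- slice_to_contours(ph$post, 0.5, 0.3, 0.04, seed = 2,
                          subject = "demo", session = "post")
res <- run_subject(pre, post, run_config(compartments = "glenoid"))

print(res$registrations$glenoid)
#> registration_report: rms 0.1816 mm after 14 iterations (converged)

tab <- res$strain_table
print(data.frame(region = tab$region_id, ap = tab$ap_label,
                 si = tab$si_label, t_pre = round(tab$t_pre, 3),
                 t_post = round(tab$t_post, 3),
                 strain_pct = round(100 * tab$strain, 1)),
      row.names = FALSE)
#>  region        ap       si t_pre t_post strain_pct
#>       1 posterior inferior 1.304  1.116       14.4
#>       2   central inferior 1.290  1.106       14.3
#>       3  anterior inferior 1.419  1.216       14.3
#>       4 posterior  central 1.212  1.027       15.2
#>       5   central  central 1.182  1.016       14.1
#>       6  anterior  central 1.287  1.103       14.3
#>       7 posterior superior 1.197  1.011       15.6
#>       8   central superior 1.200  1.020       15.0
#>       9  anterior superior 1.293  1.106       14.5

sprintf("compartmental strain: %.1f%% (imposed 15%%)",
        100 * mean(tab$strain))
#> [1] "compartmental strain: 14.6% (imposed 15%)"
```

The regional means reflect the glenoid's baseline thickness pattern
(thinnest centrally at ~1.2 mm, thickest anteroinferiorly at ~1.4–1.5 mm),
and the imposed 15% compression is recovered to within a fraction of a
percentage point despite contour noise and the unknown pose offset.

## Cohort analysis workflow

`analysis/` contains a numbered workflow that simulates and analyses a
full 8-subject study cohort (uniform 17% humeral strain; glenoid strain
graded 19% anterior / 15% central / 12% posterior):

```sh
Rscript analysis/01_simulate.R              # phantom cohort -> contour stacks
Rscript analysis/02_reconstruct_register.R  # per-subject pipeline -> results/subjects/
Rscript analysis/03_cohort_strain.R         # strain tables + compartment summaries
Rscript analysis/04_stats.R                 # ANOVAs, Tukey, correlations
```

On this synthetic cohort the pipeline reports 16.4% ± 0.9% humeral and
15.0% ± 0.2% glenoid compartmental strain, detects the anteroposterior
glenoid gradient (anterior 18.7% vs posterior 11.7%, repeated-measures
ANOVA and Tukey p < .001) and finds no anteroposterior effect on the
humeral head — the qualitative pattern such a study design is built to
resolve. (Synthetic-cohort CIs are much narrower than in vivo ones;
between-subject variability here is purely technical.)

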