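#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Eight synthetic shoulder subjects (6 right, 2 left, matching the study's
# dominant-arm mix) with the deformation pattern the study reports:
# a uniform 17% compressive strain on the humeral head cartilage and an
# anteroposterior regional strain field on the glenoid (anterior 19%,
# central 15%, posterior 12%). Each subject gets an independent unknown
# 5 degree / 3 mm pose offset between sessions and independent 0.04 mm
# segmentation noise. Contour stacks (the pipeline's raw input) are written
# to scratch/stacks/ as JSON; subject metadata (including synthetic BMI and
# body weight covariates for the correlation stage) to
# results/cohort_manifest.csv.

library(cartstrain)

out_stacks <- "scratch/stacks"
dir.create(out_stacks, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

n_subjects <- 8
lateralities <- c(rep("right", 6), rep("left", 2))

glenoid_field <- field_regional(ap_regional_values(anterior = 0.19,
                                                   central = 0.15,
                                                   posterior = 0.12))
humeral_field <- field_constant(0.17)

set.seed(20180713)
covariates <- data.frame(
  subject = sprintf("subj%02d", seq_len(n_subjects)),
  bmi = round(runif(n_subjects, 20.0, 30.2), 1),      # study's BMI range
  weight = round(runif(n_subjects, 55, 95), 1))

manifest <- covariates
manifest$laterality <- lateralities

for (k in seq_len(n_subjects)) {
  id <- manifest$subject[k]
  spec <- phantom_spec(
    laterality = lateralities[k],
    humeral_strain_field = humeral_field,
    glenoid_strain_field = glenoid_field,
    rigid_offset = random_rigid_offset(5 * pi / 180, 3, 1000L + k),
    seed = k, subject = id)
  ph <- generate_phantom(spec)
  for (ses in c("pre", "post")) {
    st <- slice_to_contours(ph[[ses]], spec$contour_slice_spacing,
                            spec$in_plane_point_spacing, spec$noise_sd,
                            seed = 100L * k + match(ses, c("pre", "post")),
                            subject = id, session = ses,
                            laterality = lateralities[k])
    write_contour_stack(st, file.path(out_stacks,
                                      sprintf("%s_%s.json", id, ses)))
  }
  message("simulated ", id, " (", lateralities[k], ")")
}

write.csv(manifest, "results/cohort_manifest.csv", row.names = FALSE)
message("wrote ", nrow(manifest), " subjects to ", out_stacks)
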