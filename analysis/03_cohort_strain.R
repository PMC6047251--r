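#!/usr/bin/env Rscript
# Stage 3 — cohort strain summaries.
#
# Concatenates the per-subject regional strain tables, then reports what
# the study design asks of the data: compartmental compressive strain
# (mean +/- 95% CI across subjects, both as mean-of-regional-strains and as
# strain-of-mean-thicknesses), and regional strain along the
# anteroposterior and superoinferior axes of each surface. Writes
# results/strain_table.csv, results/compartment_summary.csv and
# results/regional_summary.csv.

library(cartstrain)

manifest <- read.csv("results/cohort_manifest.csv")
tabs <- lapply(manifest$subject, function(id) {
  read.csv(sprintf("results/subjects/%s/strain_regions.csv", id))
})
tab <- do.call(rbind, tabs)
write.csv(tab, "results/strain_table.csv", row.names = FALSE)

summ <- compartment_summary(tab)
write.csv(summ, "results/compartment_summary.csv", row.names = FALSE)
message("compartmental strain (mean +/- 95% CI):")
for (i in seq_len(nrow(summ))) {
  message(sprintf("  %-8s %4.1f%% +/- %.1f%%  (pre %.2f mm -> post %.2f mm)",
                  summ$compartment[i], 100 * summ$mean_strain[i],
                  100 * summ$ci_half_width[i], summ$t_pre_mean[i],
                  summ$t_post_mean[i]))
}

regional <- list()
for (cmp in unique(tab$compartment)) {
  for (ax in c("ap_label", "si_label", "band")) {
    if (all(is.na(tab[[ax]][tab$compartment == cmp]))) next
    rs <- regional_summary(tab, cmp, ax)
    rs$compartment <- cmp
    rs$axis <- ax
    regional[[paste(cmp, ax)]] <- rs
  }
}
regional <- do.call(rbind, regional)
write.csv(regional, "results/regional_summary.csv", row.names = FALSE)
message("regional summaries written to results/regional_summary.csv")
print(regional[, c("compartment", "axis", "level", "mean_strain",
                   "ci_half_width")], digits = 3)
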