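#!/usr/bin/env Rscript
# Stage 4 — the statistical layer.
#
# Repeated-measures ANOVAs on the regional strains (glenoid
# anteroposterior and superoinferior thirds; humeral anteroposterior
# thirds and superior/inferior bands), Tukey post hoc tests where an
# ANOVA is significant, a baseline site-specific thickness ANOVA per
# compartment, and Pearson correlations of compartment strain against the
# cohort's BMI and body-weight covariates. Writes results/stats.json and a
# readable results/stats.txt.

library(cartstrain)

tab <- read.csv("results/strain_table.csv")
covariates <- read.csv("results/cohort_manifest.csv")[, c("subject", "bmi",
                                                          "weight")]

lines <- character(0)
say <- function(...) {
  msg <- sprintf(...)
  message(msg)
  lines <<- c(lines, msg)
}

report <- list()
axes <- list(glenoid = c("ap_label", "si_label"),
             humeral = c("ap_label", "band"))
for (cmp in names(axes)) {
  for (ax in axes[[cmp]]) {
    lt <- strain_long_table(tab, cmp, ax, "strain")
    a <- rm_anova(lt)
    key <- paste(cmp, sub("_label", "", ax), sep = "_")
    report$anovas[[key]] <- a[c("F", "df_num", "df_den", "p", "p_gg",
                                "gg_epsilon")]
    say("%-16s F(%d,%d) = %6.2f, p = %.4f (GG p = %.4f)", key, a$df_num,
        a$df_den, a$F, a$p, a$p_gg)
    if (a$p < 0.05) {
      tk <- tukey_posthoc(lt)
      report$tukey[[key]] <- tk
      for (i in seq_len(nrow(tk))) {
        say("    Tukey %-9s vs %-9s diff %+.3f, p = %.4f", tk$level_1[i],
            tk$level_2[i], tk$diff[i], tk$p_adj[i])
      }
    }
  }
  # baseline site-specific thickness differences (region as within factor)
  lt0 <- strain_long_table(tab, cmp, "region_id", "t_pre")
  a0 <- rm_anova(lt0)
  report$anovas[[paste0(cmp, "_baseline_thickness")]] <-
    a0[c("F", "df_num", "df_den", "p")]
  say("%-16s baseline thickness: F(%d,%d) = %.2f, p = %.4f", cmp,
      a0$df_num, a0$df_den, a0$F, a0$p)
}

per_subj <- aggregate(strain ~ subject + compartment, tab, mean)
for (cmp in unique(per_subj$compartment)) {
  sc <- merge(per_subj[per_subj$compartment == cmp, ], covariates,
              by = "subject")
  for (cv in c("bmi", "weight")) {
    pc <- pearson_corr(sc[[cv]], sc$strain)
    report$correlations[[paste(cmp, cv, sep = "_")]] <- pc
    say("%-8s strain vs %-6s r = %+.3f, p = %.3f (n = %d)", cmp, cv, pc$r,
        pc$p, pc$n)
  }
}

jsonlite::write_json(report, "results/stats.json", auto_unbox = TRUE,
                     digits = NA, force = TRUE)
writeLines(lines, "results/stats.txt")
message("wrote results/stats.json and results/stats.txt")
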