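#' Regional and compartmental cartilage strain
#'
#' Compressive strain in each sampling region is the post-exercise decrease
#' in regional mean thickness normalized to the pre-exercise regional mean:
#' `strain = (t_pre - t_post) / t_pre` (positive = compression). The
#' compartmental strain of a subject is the mean strain across all sampling
#' regions of that articular surface; cohort summaries average compartment
#' strains across subjects with a t-distribution 95% CI. The
#' thickness-of-means variant (strain of the compartment-mean thicknesses)
#' is also reported, clearly labeled, since compartment-level thickness
#' arithmetic reflects that definition.
#'
#' @param pre_maps,post_maps named lists (by compartment) of thickness maps
#'   per subject: `pre_maps[[subject]][[compartment]]`.
#' @param grids `grids[[subject]][[compartment]]` region grids.
#' @param subjects character vector of subject ids.
#' @return object of class `strain_table`: data frame with one row per
#'   subject x region (`subject, compartment, region_id, ap_label, si_label,
#'   band, t_pre, t_post, strain`).
#' @export
compute_strain_table <- function(pre_maps, post_maps, grids, subjects) {
  rows <- list()
  for (s in subjects) {
    for (cmp in names(grids[[s]])) {
      grid <- grids[[s]][[cmp]]
      pre <- region_mean_thickness(pre_maps[[s]][[cmp]], grid)
      post <- region_mean_thickness(post_maps[[s]][[cmp]], grid)
      if (any(!is.na(pre$mean_thickness) & pre$mean_thickness <= 0)) {
        bad <- which(pre$mean_thickness <= 0)[1]
        stop("non-positive pre-exercise thickness in region ", bad,
             " (", cmp, ", subject ", s, ")")
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, compartment = cmp, region_id = grid$id,
        ap_label = grid$ap_label, si_label = grid$si_label,
        band = grid$band, t_pre = pre$mean_thickness,
        t_post = post$mean_thickness,
        strain = (pre$mean_thickness - post$mean_thickness) /
          pre$mean_thickness)
    }
  }
  structure(do.call(rbind, rows), class = c("strain_table", "data.frame"))
}

#' Compartment-level strain summary across subjects
#'
#' @param table a [compute_strain_table()] result (or plain data frame with
#'   the same columns).
#' @param conf confidence level of the CI.
#' @return data frame, one row per compartment: `mean_strain`,
#'   `ci_half_width` (both as fractions), `mean_strain_of_mean_thickness`,
#'   `t_pre_mean`, `t_post_mean` (mm), `n_subjects`.
#' @export
compartment_summary <- function(table, conf = 0.95) {
  out <- list()
  for (cmp in unique(table$compartment)) {
    tc <- table[table$compartment == cmp & !is.na(table$strain), ]
    per_subj <- stats::aggregate(strain ~ subject, tc, mean)
    tp <- stats::aggregate(t_pre ~ subject, tc, mean)
    tq <- stats::aggregate(t_post ~ subject, tc, mean)
    n <- nrow(per_subj)
    m <- mean(per_subj$strain)
    hw <- if (n > 1) {
      stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(per_subj$strain) /
        sqrt(n)
    } else NA_real_
    out[[cmp]] <- data.frame(
      compartment = cmp, mean_strain = m, ci_half_width = hw,
      mean_strain_of_mean_thickness =
        mean((tp$t_pre - tq$t_post) / tp$t_pre),
      t_pre_mean = mean(tp$t_pre), t_post_mean = mean(tq$t_post),
      n_subjects = n)
  }
  do.call(rbind, out)
}

#' Per-third regional strain summary along one anatomical axis
#'
#' Averages, within each subject, the regions sharing a factor level (e.g.
#' the three anterior glenoid regions), then summarizes across subjects.
#'
#' @param table a strain table.
#' @param compartment compartment to summarize.
#' @param axis `"ap_label"`, `"si_label"`, or `"band"`.
#' @param conf confidence level.
#' @return data frame per level: `mean_strain`, `ci_half_width`,
#'   `n_subjects`.
#' @export
regional_summary <- function(table, compartment, axis = "ap_label",
                             conf = 0.95) {
  tc <- table[table$compartment == compartment & !is.na(table$strain), ]
  lv <- unique(tc[[axis]])
  out <- list()
  for (l in lv) {
    per_subj <- stats::aggregate(
      strain ~ subject, tc[tc[[axis]] == l, ], mean)
    n <- nrow(per_subj)
    m <- mean(per_subj$strain)
    hw <- if (n > 1) {
      stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(per_subj$strain) /
        sqrt(n)
    } else NA_real_
    out[[l]] <- data.frame(level = l, mean_strain = m, ci_half_width = hw,
                           n_subjects = n)
  }
  do.call(rbind, out)
}

#' Long-format per-subject response table for repeated-measures ANOVA
#'
#' Builds the balanced subject x level table for one compartment and axis,
#' averaging regions that share a level within each subject.
#'
#' @param table a strain table.
#' @param compartment compartment.
#' @param axis grouping column (`"ap_label"`, `"si_label"`, `"band"`, or
#'   `"region_id"`).
#' @param response `"strain"`, `"t_pre"`, or `"t_post"`.
#' @return data frame `subject`, `level`, `value`.
#' @export
strain_long_table <- function(table, compartment, axis = "ap_label",
                              response = "strain") {
  tc <- table[table$compartment == compartment, ]
  tc$value <- tc[[response]]
  tc$level <- as.character(tc[[axis]])
  agg <- stats::aggregate(value ~ subject + level, tc, mean, na.action =
                            stats::na.omit)
  agg[order(agg$subject, agg$level), c("subject", "level", "value")]
}

#' Write a strain table as tidy CSV
#' @param table strain table.
#' @param path file path.
#' @export
write_strain_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
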