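#' Pipeline run configuration
#'
#' @param compartments compartments to process.
#' @param icp ICP settings, see [icp_config()].
#' @param thickness thickness-map settings, see [thickness_config()].
#' @param grid_layout optional explicit region layout override (see
#'   [build_region_grid()]).
#' @param write_meshes also write reconstructed meshes / thickness PLYs when
#'   an output directory is given.
#' @param out_dir optional output directory for per-subject artifacts.
#' @export
run_config <- function(compartments = c("humeral", "glenoid"),
                       icp = icp_config(),
                       thickness = thickness_config(),
                       grid_layout = NULL,
                       write_meshes = FALSE,
                       out_dir = NULL) {
  compartments <- match.arg(compartments, c("humeral", "glenoid"),
                            several.ok = TRUE)
  list(compartments = compartments, icp = icp, thickness = thickness,
       grid_layout = grid_layout, write_meshes = write_meshes,
       out_dir = out_dir)
}

#' Run the full strain pipeline for one subject
#'
#' Reconstructs all surfaces from the pre- and post-exercise contour
#' stacks, registers each post-exercise bone to its pre-exercise
#' counterpart with ICP (bone surfaces only), maps the aligned post
#' cartilage onto the pre-exercise bone vertices, builds the anatomical
#' sampling-region grids on the pre-exercise cartilage footprints, and
#' returns the per-region strain table. Deterministic given its inputs.
#'
#' @param pre,post `contour_stack`s of the same subject.
#' @param config see [run_config()].
#' @return list with `strain_table`, `registrations` (per compartment),
#'   `frame`, `maps` (`pre`/`post` thickness maps), `grids`.
#' @export
run_subject <- function(pre, post, config = run_config()) {
  if (!identical(pre$subject, post$subject)) {
    stop("pre/post stacks belong to different subjects (",
         pre$subject, " vs ", post$subject, ")")
  }
  subject <- pre$subject
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", what, "' failed for subject ", subject, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }

  frame_bone <- stage("reconstruct",
                      reconstruct_surface(pre, "glenoid_bone"))
  frame <- stage("anatomical_frame",
                 fit_anatomical_frame(frame_bone, pre$laterality))

  maps <- list(pre = list(), post = list())
  grids <- list()
  regs <- list()
  for (cmp in config$compartments) {
    bone_lab <- paste0(cmp, "_bone")
    cart_lab <- paste0(cmp, "_cartilage")
    pre_bone <- if (cmp == "glenoid") frame_bone else
      stage("reconstruct", reconstruct_surface(pre, bone_lab))
    pre_cart <- stage("reconstruct", reconstruct_surface(pre, cart_lab))
    post_bone <- stage("reconstruct", reconstruct_surface(post, bone_lab))
    post_cart <- stage("reconstruct", reconstruct_surface(post, cart_lab))

    reg <- stage("register", icp_align(post_bone, pre_bone, config$icp))
    regs[[cmp]] <- reg
    post_cart_aligned <- apply_transform(post_cart, reg$transform)

    map_pre <- stage("thickness",
                     compute_thickness_map(pre_bone, pre_cart,
                                           config$thickness))
    map_post <- stage("thickness",
                      compute_thickness_map(pre_bone, post_cart_aligned,
                                            config$thickness))
    shared <- map_pre$mask & map_post$mask
    map_pre$mask <- shared
    map_post$mask <- shared
    map_pre$thickness[!shared] <- NA
    map_post$thickness[!shared] <- NA
    maps$pre[[cmp]] <- map_pre
    maps$post[[cmp]] <- map_post

    grids[[cmp]] <- stage("regions", build_region_grid(
      pre_bone$vertices[shared, , drop = FALSE], frame, cmp,
      layout = config$grid_layout))
  }

  tab <- compute_strain_table(
    pre_maps = stats::setNames(list(maps$pre), subject),
    post_maps = stats::setNames(list(maps$post), subject),
    grids = stats::setNames(list(grids), subject),
    subjects = subject)

  if (!is.null(config$out_dir)) {
    write_subject_artifacts(subject, tab, regs, maps, grids, config)
  }
  list(strain_table = tab, registrations = regs, frame = frame,
       maps = maps, grids = grids)
}

write_subject_artifacts <- function(subject, tab, regs, maps, grids,
                                    config) {
  dir <- file.path(config$out_dir, subject)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_strain_table(tab, file.path(dir, "strain_regions.csv"))
  for (cmp in names(regs)) {
    write_transform(regs[[cmp]]$transform,
                    file.path(dir, paste0(cmp, "_registration.json")))
    utils::write.csv(as.data.frame(grids[[cmp]]),
                     file.path(dir, paste0(cmp, "_regions.csv")),
                     row.names = FALSE)
    if (isTRUE(config$write_meshes)) {
      for (ses in c("pre", "post")) {
        m <- maps[[ses]][[cmp]]
        th <- m$thickness
        th[is.na(th)] <- -1
        write_ply(m$bone, file.path(dir, paste0(cmp, "_", ses,
                                                "_thickness.ply")),
                  scalars = list(thickness_mm = th))
      }
    }
  }
  invisible(dir)
}

#' Run the pipeline over a cohort and compute the study statistics
#'
#' Runs [run_subject()] per subject (collecting per-subject failures
#' without aborting the cohort), concatenates the strain tables, and
#' produces the compartment summaries and the repeated-measures statistical
#' layer: regional strain ANOVAs along the anatomical axes (with Tukey post
#' hoc tests when significant), baseline site-specific thickness ANOVAs,
#' and Pearson correlations of compartment strain against per-subject
#' covariates.
#'
#' @param subjects list of `list(pre = , post = )` contour stacks.
#' @param config see [run_config()].
#' @param covariates optional data frame with column `subject` plus numeric
#'   covariate columns (e.g. `bmi`, `weight`).
#' @param alpha significance threshold for following up with Tukey tests.
#' @return list with `strain_table`, `compartment_summary`, `anovas`,
#'   `tukey`, `correlations`, `failures`, `results` (per-subject).
#' @export
run_cohort <- function(subjects, config = run_config(), covariates = NULL,
                       alpha = 0.05) {
  if (length(subjects) < 3) {
    stop(">= 3 subjects required for statistics")
  }
  results <- list()
  failures <- list()
  for (s in subjects) {
    id <- s$pre$subject
    res <- tryCatch(run_subject(s$pre, s$post, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      results[[id]] <- res
    }
  }
  if (length(results) < 3) {
    stop("fewer than 3 subjects completed; failures: ",
         paste(names(failures), failures, collapse = "; "))
  }
  tab <- do.call(rbind, lapply(results, function(r) r$strain_table))
  rownames(tab) <- NULL
  class(tab) <- c("strain_table", "data.frame")

  axes <- list(glenoid = c("ap_label", "si_label"),
               humeral = c("ap_label", "band"))
  anovas <- list()
  tukey <- list()
  for (cmp in intersect(config$compartments, unique(tab$compartment))) {
    for (ax in axes[[cmp]]) {
      key <- paste(cmp, sub("_label", "", ax), sep = "_")
      lt <- strain_long_table(tab, cmp, ax, "strain")
      anovas[[key]] <- rm_anova(lt)
      if (is.finite(anovas[[key]]$p) && anovas[[key]]$p < alpha) {
        tukey[[key]] <- tukey_posthoc(lt)
      }
    }
    # baseline site-specific thickness (region as within factor)
    lt0 <- strain_long_table(tab, cmp, "region_id", "t_pre")
    anovas[[paste0(cmp, "_baseline_thickness")]] <- rm_anova(lt0)
  }

  correlations <- list()
  if (!is.null(covariates)) {
    summ_subj <- stats::aggregate(strain ~ subject + compartment, tab, mean)
    for (cmp in unique(summ_subj$compartment)) {
      sc <- summ_subj[summ_subj$compartment == cmp, ]
      mrg <- merge(sc, covariates, by = "subject")
      for (cv in setdiff(names(covariates), "subject")) {
        correlations[[paste(cmp, cv, sep = "_")]] <-
          pearson_corr(mrg[[cv]], mrg$strain)
      }
    }
  }

  out <- list(strain_table = tab,
              compartment_summary = compartment_summary(tab),
              anovas = anovas, tukey = tukey, correlations = correlations,
              failures = failures, results = results)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_strain_table(tab, file.path(config$out_dir, "strain_table.csv"))
    utils::write.csv(out$compartment_summary,
                     file.path(config$out_dir, "compartment_summary.csv"),
                     row.names = FALSE)
    report <- list(
      anovas = lapply(anovas, function(a) a[c("F", "df_num", "df_den", "p",
                                              "p_gg", "gg_epsilon")]),
      tukey = tukey, correlations = correlations, failures = failures)
    jsonlite::write_json(report, file.path(config$out_dir, "stats.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  out
}

#' Generate a cohort of phantom subjects
#'
#' Convenience wrapper producing pre/post contour stacks for `n` phantoms
#' sharing one anatomy/deformation specification but independent noise
#' draws and rigid offsets (seeded per subject from `base_seed`).
#'
#' @param n number of subjects.
#' @param base_seed integer; subject k uses seeds derived from
#'   `base_seed + k`.
#' @param spec_fun function(seed) returning the subject's [phantom_spec()];
#'   defaults to the standard phantom with a 5 degree / 3 mm random session
#'   offset.
#' @param ... passed on to [phantom_spec()] by the default `spec_fun`.
#' @return list of `list(pre, post, truth)` per subject.
#' @export
simulate_cohort <- function(n, base_seed = 1L, spec_fun = NULL, ...) {
  spec_fun <- spec_fun %||% function(seed) {
    phantom_spec(rigid_offset = random_rigid_offset(5 * pi / 180, 3, seed),
                 seed = seed, subject = sprintf("phantom%02d", seed), ...)
  }
  lapply(seq_len(n), function(k) {
    seed <- base_seed + k - 1L
    spec <- spec_fun(seed)
    ph <- generate_phantom(spec)
    pre <- slice_to_contours(ph$pre, spec$contour_slice_spacing,
                             spec$in_plane_point_spacing, spec$noise_sd,
                             seed = seed * 2L + 1L, subject = spec$subject,
                             session = "pre", laterality = spec$laterality)
    post <- slice_to_contours(ph$post, spec$contour_slice_spacing,
                              spec$in_plane_point_spacing, spec$noise_sd,
                              seed = seed * 2L + 2L, subject = spec$subject,
                              session = "post",
                              laterality = spec$laterality)
    list(pre = pre, post = post, truth = ph$truth)
  })
}
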