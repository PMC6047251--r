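#' Fit the anatomical coordinate frame from the glenoid bone surface
#'
#' The mediolateral axis is the mean outward normal of the glenoid face
#' (the glenoid faces laterally); the superoinferior axis is the principal
#' axis of the glenoid footprint orthogonalized against it, signed toward
#' +z (superior); the anteroposterior axis completes the frame and always
#' points anterior, so its sign follows laterality (for right shoulders
#' `(ap, si, ml)` is right-handed; a left shoulder is its mirror image).
#'
#' @param glenoid_bone `surface_mesh` of the glenoid bone.
#' @param laterality `"right"` or `"left"`.
#' @return object of class `anatomical_frame`: `origin`, `axis_ap`,
#'   `axis_si`, `axis_ml` (unit vectors), `laterality`.
#' @export
fit_anatomical_frame <- function(glenoid_bone, laterality = "right") {
  laterality <- match.arg(laterality, c("right", "left"))
  v <- glenoid_bone$vertices
  if (nrow(v) == 0) stop("empty glenoid mesh")
  ml <- colMeans(vertex_normals(glenoid_bone))
  ml <- ml / sqrt(sum(ml^2))
  ev <- eigen(stats::cov(v), symmetric = TRUE)
  # principal in-plane axis: largest-eigenvalue direction after removing ml
  vecs <- ev$vectors
  vals <- ev$values
  in_plane <- apply(vecs, 2, function(u) u - sum(u * ml) * ml)
  norms <- sqrt(colSums(in_plane^2))
  cand <- which(norms > 0.5)
  if (length(cand) >= 2) {
    v1 <- vals[cand[1]]
    v2 <- vals[cand[2]]
    if (abs(v1 - v2) / max(v1, v2) < 0.01) {
      stop("ambiguous orientation: glenoid footprint is isotropic within 1%")
    }
  }
  si <- in_plane[, cand[1]] / norms[cand[1]]
  if (sum(si * c(0, 0, 1)) < 0) si <- -si
  ap <- c(si[2] * ml[3] - si[3] * ml[2],
          si[3] * ml[1] - si[1] * ml[3],
          si[1] * ml[2] - si[2] * ml[1])
  ap <- ap / sqrt(sum(ap^2))
  if (laterality == "left") ap <- -ap
  structure(list(origin = colMeans(v), axis_ap = ap, axis_si = si,
                 axis_ml = ml, laterality = laterality),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame (", x$laterality, ")\n")
  for (a in c("axis_ap", "axis_si", "axis_ml")) {
    cat(" ", a, ":", paste(format(x[[a]], digits = 3), collapse = " "), "\n")
  }
  invisible(x)
}

# Anatomical in-plane coordinates of points relative to a frame.
frame_coords <- function(points, frame, origin = NULL) {
  origin <- origin %||% frame$origin
  rel <- sweep(points, 2, origin)
  list(ap = as.numeric(rel %*% frame$axis_ap),
       si = as.numeric(rel %*% frame$axis_si))
}

#' Build the anatomical sampling-region grid on a cartilage footprint
#'
#' Places the study's 2-mm-radius sampling regions: 9 on the glenoid (a 3x3
#' grid at the 20/50/80% quantiles of the footprint's anteroposterior and
#' superoinferior coordinates) and 18 on the humeral head (2 superoinferior
#' bands split at the median, each a 3x3 grid by the same quantile rule
#' within the band). Region centers are projected onto the nearest footprint
#' vertex. An explicit `layout` (data frame of `ap_q`, `si_q`, optional
#' `band`, `ap_label`, `si_label` rows) may override the default placement.
#'
#' @param footprint n x 3 matrix of masked bone vertices (the cartilage
#'   footprint), mm.
#' @param frame an [fit_anatomical_frame()] result.
#' @param compartment `"glenoid"` or `"humeral"`.
#' @param radius sampling-region radius, mm.
#' @param layout optional explicit layout table (see above; quantiles in
#'   \[0, 1\]).
#' @return object of class `region_grid`: data frame with one row per
#'   region (`id`, `center_x/y/z`, `radius`, `ap_label`, `si_label`,
#'   `band`), plus the frame as an attribute.
#' @export
build_region_grid <- function(footprint, frame,
                              compartment = c("glenoid", "humeral"),
                              radius = 2, layout = NULL) {
  compartment <- match.arg(compartment)
  if (nrow(footprint) == 0) stop("empty cartilage footprint")
  ctr <- colMeans(footprint)
  co <- frame_coords(footprint, frame, origin = ctr)

  if (is.null(layout)) layout <- default_region_layout(compartment)
  qs <- c(anterior = NA, central = NA, posterior = NA)

  rows <- list()
  for (r in seq_len(nrow(layout))) {
    sel <- rep(TRUE, nrow(footprint))
    if (!is.null(layout$band) && !is.na(layout$band[r])) {
      split_si <- stats::median(co$si)
      sel <- if (layout$band[r] == "superior") co$si >= split_si else
        co$si < split_si
    }
    apq <- stats::quantile(co$ap[sel], layout$ap_q[r], names = FALSE)
    siq <- stats::quantile(co$si[sel], layout$si_q[r], names = FALSE)
    d2 <- (co$ap - apq)^2 + (co$si - siq)^2
    d2[!sel] <- Inf
    vi <- which.min(d2)
    rows[[r]] <- data.frame(
      id = r, center_x = footprint[vi, 1], center_y = footprint[vi, 2],
      center_z = footprint[vi, 3], radius = radius,
      ap_label = layout$ap_label[r], si_label = layout$si_label[r],
      band = if (!is.null(layout$band)) layout$band[r] else NA_character_)
  }
  grid <- do.call(rbind, rows)
  n_expect <- if (compartment == "glenoid") 9L else 18L
  if (is.null(attr(layout, "custom")) && nrow(grid) != n_expect) {
    stop("internal error: expected ", n_expect, " regions")
  }
  small <- min(stats::dist(grid[, c("center_x", "center_y", "center_z")]))
  if (small < 2 * radius) {
    message("note: sampling regions overlap (closest centers ",
            format(small, digits = 3), " mm apart)")
  }
  structure(grid, compartment = compartment, frame = frame,
            class = c("region_grid", "data.frame"))
}

default_region_layout <- function(compartment) {
  q <- c(0.2, 0.5, 0.8)
  ap_lab <- c("posterior", "central", "anterior")
  si_lab <- c("inferior", "central", "superior")
  if (compartment == "glenoid") {
    g <- expand.grid(ai = 1:3, si = 1:3)
    data.frame(ap_q = q[g$ai], si_q = q[g$si],
               ap_label = ap_lab[g$ai], si_label = si_lab[g$si],
               band = NA_character_)
  } else {
    g <- expand.grid(ai = 1:3, si = 1:3, band = c("inferior", "superior"))
    data.frame(ap_q = q[g$ai], si_q = q[g$si],
               ap_label = ap_lab[g$ai], si_label = si_lab[g$si],
               band = as.character(g$band))
  }
}

#' Mean thickness within each sampling region
#'
#' Averages the thickness map over the masked bone vertices within `radius`
#' (Euclidean) of each region center; vertices may contribute to several
#' overlapping regions. Regions containing no masked vertex are flagged
#' missing (NA).
#'
#' @param map a [compute_thickness_map()] result.
#' @param grid a [build_region_grid()] result.
#' @return data frame `id`, `mean_thickness`, `n_vertices`.
#' @export
region_mean_thickness <- function(map, grid) {
  pts <- map$bone$vertices[map$mask, , drop = FALSE]
  th <- map$thickness[map$mask]
  out <- data.frame(id = grid$id, mean_thickness = NA_real_, n_vertices = 0L)
  for (r in seq_len(nrow(grid))) {
    ctr <- c(grid$center_x[r], grid$center_y[r], grid$center_z[r])
    d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
      (pts[, 3] - ctr[3])^2
    sel <- d2 <= grid$radius[r]^2
    out$n_vertices[r] <- sum(sel)
    if (any(sel)) out$mean_thickness[r] <- mean(th[sel])
  }
  if (all(is.na(out$mean_thickness))) stop("all sampling regions are empty")
  out
}
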