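#' Segmented contour stacks
#'
#' A `contour_stack` holds one subject/session worth of segmentation
#' geometry: per axial slice (constant z, uniform spacing), ordered 2D point
#' lists labeled by tissue. This is the pipeline's raw input format,
#' emulating manual sub-pixel MRI segmentation, and the output of
#' [slice_to_contours()].
#'
#' @param slices list of `list(z, contours)`; each contour is
#'   `list(label, points, closed)` with `points` an n x 2 matrix (mm).
#' @param subject subject identifier.
#' @param session `"pre"` or `"post"`.
#' @param laterality `"left"` or `"right"`.
#' @param slice_spacing slice spacing, mm.
#' @return object of class `contour_stack` (slices sorted by z).
#' @export
contour_stack <- function(slices, subject = "subject", session = "pre",
                          laterality = "right", slice_spacing = 0.5) {
  session <- match.arg(session, c("pre", "post"))
  laterality <- match.arg(laterality, c("left", "right"))
  if (length(slices) == 0) stop("no slices produced")
  z <- vapply(slices, function(s) s$z, 0)
  slices <- slices[order(z)]
  z <- sort(z)
  if (any(diff(z) <= 0)) stop("slice z values must be strictly increasing")
  if (length(z) > 1) {
    dz <- diff(z)
    if (max(abs(dz - slice_spacing)) > 1e-6) {
      stop("non-uniform slice spacing (tolerance 1e-6 mm)")
    }
  }
  for (s in slices) {
    for (ct in s$contours) validate_contour(ct)
  }
  structure(list(subject = subject, session = session,
                 laterality = laterality, slice_spacing = slice_spacing,
                 slices = slices),
            class = "contour_stack")
}

validate_contour <- function(ct) {
  if (!ct$label %in% tissue_labels()) {
    stop("unknown label '", ct$label, "'; allowed labels: ",
         paste(tissue_labels(), collapse = ", "))
  }
  p <- ct$points
  min_pts <- if (isTRUE(ct$closed)) 3 else 2
  if (nrow(p) < min_pts) {
    stop("contour with label '", ct$label, "' has fewer than ", min_pts,
         " points")
  }
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg <= 1e-9)) {
    stop("consecutive duplicate points in contour '", ct$label, "'")
  }
  invisible(ct)
}

#' @export
print.contour_stack <- function(x, ...) {
  nc <- sum(vapply(x$slices, function(s) length(s$contours), 0L))
  np <- sum(vapply(x$slices, function(s) {
    sum(vapply(s$contours, function(ct) nrow(ct$points), 0L))
  }, 0L))
  cat("contour_stack", x$subject, x$session, x$laterality, "\n",
      " slices:", length(x$slices), " contours:", nc, " points:", np,
      " spacing:", x$slice_spacing, "mm\n")
  invisible(x)
}

#' Slice a scene of surfaces into a labeled contour stack
#'
#' Emulates the manual segmentation step: each surface is intersected with
#' parallel axial planes (z = const on a shared grid at half-spacing offsets),
#' each section resampled to an ordered polyline at `point_spacing`, and an
#' independent zero-mean Gaussian displacement of SD `noise_sd` is applied to
#' every point along the in-plane contour normal. Surfaces generated by
#' [generate_phantom()] carry exact star-shaped parametrizations and are
#' sectioned analytically; plain meshes are sectioned by triangle/plane
#' intersection.
#'
#' @param scene named list of `surface_mesh` objects (labels are taken from
#'   the meshes).
#' @param spacing slice spacing, mm (> 0).
#' @param point_spacing in-plane resampling distance, mm.
#' @param noise_sd segmentation noise SD, mm (0 disables noise and makes the
#'   output independent of `seed`).
#' @param seed integer seed for the noise (RNG state restored on exit).
#' @param subject,session,laterality stack metadata.
#' @return a `contour_stack`.
#' @export
slice_to_contours <- function(scene, spacing = 0.5, point_spacing = 0.3,
                              noise_sd = 0.04, seed = 1L,
                              subject = "subject", session = "pre",
                              laterality = "right") {
  stopifnot(spacing > 0, point_spacing > 0, noise_sd >= 0)
  if (inherits(scene, "surface_mesh")) scene <- list(scene)
  zr <- range(vapply(scene, function(m) range(m$vertices[, 3]), c(0, 0)))
  k <- seq(floor(zr[1] / spacing) - 1, ceiling(zr[2] / spacing) + 1)
  zs <- (k + 0.5) * spacing
  zs <- zs[zs > zr[1] - spacing & zs < zr[2] + spacing]

  raw <- list()  # per z: list of contours
  for (z0 in zs) raw[[as.character(z0)]] <- list()
  for (mi in seq_along(scene)) {
    mesh <- scene[[mi]]
    label <- mesh$label
    if (is.null(label)) stop("scene surfaces must carry tissue labels")
    rad <- attr(mesh, "radial")
    for (z0 in zs) {
      secs <- if (!is.null(rad)) radial_slice(rad, z0, point_spacing) else
        mesh_plane_sections(mesh, z0)
      for (sec in secs) {
        pts <- if (isTRUE(sec$resampled)) sec$points else
          resample_polyline(sec$points, point_spacing, sec$closed)
        if (is.null(pts)) next
        if (sec$closed) pts <- orient_ccw(pts)
        raw[[as.character(z0)]][[length(raw[[as.character(z0)]]) + 1]] <-
          list(label = label, points = pts, closed = sec$closed)
      }
    }
  }

  slices <- list()
  for (z0 in zs) {
    cts <- raw[[as.character(z0)]]
    if (length(cts) > 0) {
      slices[[length(slices) + 1]] <- list(z = z0, contours = cts)
    }
  }
  if (length(slices) == 0) stop("no slices produced")

  if (noise_sd > 0) {
    slices <- with_seed(seed, {
      lapply(slices, function(s) {
        s$contours <- lapply(s$contours, function(ct) {
          ct$points <- ct$points + noise_sd *
            stats::rnorm(nrow(ct$points)) * contour_normals(ct$points,
                                                            ct$closed)
          ct
        })
        s
      })
    })
  }
  contour_stack(slices, subject = subject, session = session,
                laterality = laterality, slice_spacing = spacing)
}

# In-plane unit normals (rotated tangents) of a 2D polyline.
contour_normals <- function(p, closed) {
  n <- nrow(p)
  if (closed) {
    nxt <- p[c(2:n, 1), , drop = FALSE]
    prv <- p[c(n, 1:(n - 1)), , drop = FALSE]
  } else {
    nxt <- p[c(2:n, n), , drop = FALSE]
    prv <- p[c(1, 1:(n - 1)), , drop = FALSE]
  }
  tg <- nxt - prv
  len <- sqrt(rowSums(tg^2))
  len[len == 0] <- 1
  cbind(tg[, 2], -tg[, 1]) / len
}

# Resample a polyline at uniform arc length close to `spacing`.
# Works for 2D or 3D point matrices. Returns NULL for degenerate input.
resample_polyline <- function(p, spacing, closed, n_out = NULL) {
  if (closed) p <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  L <- sum(seg)
  if (L < spacing) return(NULL)
  s <- c(0, cumsum(seg))
  if (closed) {
    n <- if (is.null(n_out)) max(8L, round(L / spacing)) else n_out
    at <- L * (seq_len(n) - 1) / n
  } else {
    n <- if (is.null(n_out)) max(2L, round(L / spacing) + 1) else n_out
    at <- L * (seq_len(n) - 1) / (n - 1)
  }
  out <- matrix(0, length(at), ncol(p))
  for (j in seq_len(ncol(p))) {
    out[, j] <- stats::approx(s, p[, j], xout = at, ties = "ordered")$y
  }
  out
}

polygon_area <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

orient_ccw <- function(p) {
  if (polygon_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# Triangle-mesh / plane sections: chained intersection polylines at z = z0.
mesh_plane_sections <- function(mesh, z0) {
  v <- mesh$vertices
  f <- mesh$faces
  dz <- v[, 3] - z0
  dz[dz == 0] <- 1e-9                     # avoid exact-vertex degeneracies
  s <- matrix(dz[f] > 0, ncol = 3)
  cross <- rowSums(s) %in% c(1L, 2L)
  if (!any(cross)) return(list())
  fc <- f[cross, , drop = FALSE]
  segs <- vector("list", nrow(fc))
  edge_pt <- function(i, j) {
    t <- dz[i] / (dz[i] - dz[j])
    v[i, 1:2] + t * (v[j, 1:2] - v[i, 1:2])
  }
  pa <- matrix(0, nrow(fc), 2)
  pb <- matrix(0, nrow(fc), 2)
  ka <- character(nrow(fc))
  kb <- character(nrow(fc))
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  for (r in seq_len(nrow(fc))) {
    tri <- fc[r, ]
    pos <- dz[tri] > 0
    lone <- tri[pos == (sum(pos) == 1)]
    others <- setdiff(tri, lone)
    pa[r, ] <- edge_pt(lone, others[1])
    pb[r, ] <- edge_pt(lone, others[2])
    ka[r] <- ekey(lone, others[1])
    kb[r] <- ekey(lone, others[2])
  }
  chain_segments(pa, pb, ka, kb)
}

# Chain segments (matched by shared mesh-edge keys) into polylines.
chain_segments <- function(pa, pb, ka, kb) {
  n <- nrow(pa)
  keys <- unique(c(ka, kb))
  a_id <- match(ka, keys)
  b_id <- match(kb, keys)
  # adjacency: segments touching each key
  touch <- vector("list", length(keys))
  for (r in seq_len(n)) {
    touch[[a_id[r]]] <- c(touch[[a_id[r]]], r)
    touch[[b_id[r]]] <- c(touch[[b_id[r]]], r)
  }
  used <- rep(FALSE, n)
  out <- list()
  deg <- vapply(touch, length, 0L)
  for (start in order(deg[a_id] + deg[b_id])) {
    if (used[start]) next
    # walk both directions from `start`
    path_keys <- c(a_id[start], b_id[start])
    used[start] <- TRUE
    repeat {
      tail_key <- path_keys[length(path_keys)]
      nxt <- setdiff(touch[[tail_key]][!used[touch[[tail_key]]]], integer(0))
      if (length(nxt) == 0) break
      r <- nxt[1]
      used[r] <- TRUE
      path_keys <- c(path_keys,
                     if (a_id[r] == tail_key) b_id[r] else a_id[r])
    }
    repeat {
      head_key <- path_keys[1]
      nxt <- touch[[head_key]][!used[touch[[head_key]]]]
      if (length(nxt) == 0) break
      r <- nxt[1]
      used[r] <- TRUE
      path_keys <- c(if (a_id[r] == head_key) b_id[r] else a_id[r],
                     path_keys)
    }
    closed <- path_keys[1] == path_keys[length(path_keys)]
    if (closed) path_keys <- path_keys[-length(path_keys)]
    key_pts <- matrix(0, length(keys), 2)
    key_pts[a_id, ] <- pa
    key_pts[b_id, ] <- pb
    pts <- key_pts[path_keys, , drop = FALSE]
    if (nrow(pts) >= 2) {
      out[[length(out) + 1]] <- list(points = pts, closed = closed)
    }
  }
  out
}

#' Read / write contour stacks as JSON
#'
#' The on-disk schema is
#' `{subject, session, laterality, slice_spacing_mm,
#'   slices: [{z_mm, contours: [{label, closed, points_mm: [[x, y], ...]}]}]}`.
#' Numeric values round-trip at full double precision; slices are returned
#' sorted by z regardless of file order.
#'
#' @param stack a `contour_stack`.
#' @param path file path.
#' @export
write_contour_stack <- function(stack, path) {
  obj <- list(
    subject = stack$subject, session = stack$session,
    laterality = stack$laterality, slice_spacing_mm = stack$slice_spacing,
    slices = lapply(stack$slices, function(s) {
      list(z_mm = s$z, contours = lapply(s$contours, function(ct) {
        list(label = ct$label, closed = isTRUE(ct$closed),
             points_mm = apply(unname(ct$points), 1, as.numeric,
                               simplify = FALSE))
      }))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_contour_stack
#' @export
read_contour_stack <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e)))
  need <- c("subject", "session", "laterality", "slice_spacing_mm", "slices")
  if (!all(need %in% names(obj))) {
    stop("malformed contour stack file: missing fields ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  }
  slices <- lapply(obj$slices, function(s) {
    list(z = s$z_mm, contours = lapply(s$contours, function(ct) {
      pts <- do.call(rbind, lapply(ct$points_mm, unlist))
      list(label = ct$label, points = pts, closed = isTRUE(ct$closed))
    }))
  })
  contour_stack(slices, subject = obj$subject, session = obj$session,
                laterality = obj$laterality,
                slice_spacing = obj$slice_spacing_mm)
}

# All contours of a label, as list of (z, points, closed), sorted by z.
stack_label_contours <- function(stack, label) {
  out <- list()
  for (s in stack$slices) {
    for (ct in s$contours) {
      if (ct$label == label) {
        out[[length(out) + 1]] <- list(z = s$z, points = ct$points,
                                       closed = ct$closed)
      }
    }
  }
  out
}
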