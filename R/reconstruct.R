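#' Reconstruct a triangulated surface from a labeled contour stack
#'
#' Implements the "contours to 3D surface model" step: the ordered 2D
#' contours of one tissue label are lifted to their slice planes and lofted
#' slice-to-slice into a triangle mesh. Adjacent contours keep their own
#' point counts; the strip between them is triangulated by a merge walk over
#' normalized arc-length parameters, with the cyclic phase of closed contours
#' aligned by FFT cross-correlation. Closed stacks are capped with centroid
#' fans (watertight result); open stacks (cartilage arcs) yield an open
#' sheet. Face orientation is normalized so vertex normals point out of the
#' anatomy: positive enclosed volume for closed surfaces, and for open
#' sheets toward (glenoid) or away from (humeral) the center of the
#' least-squares fitted sphere — the articular side in both cases.
#'
#' @param stack a `contour_stack`.
#' @param label tissue label to reconstruct, one of [tissue_labels()].
#' @return a `surface_mesh`.
#' @export
reconstruct_surface <- function(stack, label) {
  label <- match.arg(label, tissue_labels())
  cts <- stack_label_contours(stack, label)
  zs <- vapply(cts, function(ct) ct$z, 0)
  if (anyDuplicated(zs)) {
    stop("multiple '", label, "' contours on one slice are not supported")
  }
  if (length(cts) < 2) stop("insufficient contours for label '", label, "'")
  cts <- cts[order(zs)]
  closed <- vapply(cts, function(ct) isTRUE(ct$closed), TRUE)
  if (!all(closed) && any(closed)) {
    stop("mixed open/closed contour topology for label '", label, "'")
  }
  closed <- all(closed)

  rings <- lapply(cts, function(ct) {
    p <- ct$points
    if (closed) p <- orient_ccw(p)
    cbind(p, ct$z)
  })

  # adjacent-slice overlap check (projected bounding boxes, with a margin
  # for steeply inclined surfaces whose sections shift laterally per slice)
  marg <- max(2, 5 * stack$slice_spacing)
  for (k in seq_len(length(rings) - 1)) {
    a <- rings[[k]]; b <- rings[[k + 1]]
    if (min(a[, 1]) > max(b[, 1]) + marg || min(b[, 1]) > max(a[, 1]) + marg ||
        min(a[, 2]) > max(b[, 2]) + marg || min(b[, 2]) > max(a[, 2]) + marg) {
      stop("non-overlapping adjacent contours between slices z = ",
           format(cts[[k]]$z), " and z = ", format(cts[[k + 1]]$z))
    }
  }

  if (!closed) rings <- align_open_rings(rings)
  if (closed) rings <- align_closed_rings(rings)

  offs <- cumsum(c(0, vapply(rings, nrow, 0L)))
  verts <- do.call(rbind, rings)
  faces <- list()
  for (k in seq_len(length(rings) - 1)) {
    ia <- offs[k] + seq_len(nrow(rings[[k]]))
    ib <- offs[k + 1] + seq_len(nrow(rings[[k + 1]]))
    faces[[k]] <- loft_walk(ia, ib, closed)
  }
  if (closed) {
    apex1 <- colMeans(rings[[1]])
    apex2 <- colMeans(rings[[length(rings)]])
    verts <- rbind(verts, apex1, apex2)
    i1 <- nrow(verts) - 1L
    i2 <- nrow(verts)
    faces[[length(faces) + 1]] <-
      fan_cap(i1, offs[1] + seq_len(nrow(rings[[1]])))
    faces[[length(faces) + 1]] <-
      fan_cap(i2, offs[length(rings)] + seq_len(nrow(rings[[length(rings)]])),
              reverse = TRUE)
  }
  mesh <- surface_mesh(verts, do.call(rbind, faces), label, validate = FALSE)
  orient_mesh(mesh)
}

# Normalize global face orientation (see reconstruct_surface docs).
orient_mesh <- function(mesh) {
  boundary <- length(boundary_edges(mesh)) > 0
  if (!boundary) {
    if (mesh_volume(mesh) < 0) mesh <- flip_faces(mesh)
    return(mesh)
  }
  fit <- fit_sphere(mesh$vertices)
  vn <- vertex_normals(mesh)
  to_center <- sweep(-mesh$vertices, 2, fit$center, "+")
  score <- mean(rowSums(vn * to_center))
  toward <- !is.null(mesh$label) && startsWith(mesh$label, "glenoid")
  if ((toward && score < 0) || (!toward && score > 0)) mesh <- flip_faces(mesh)
  mesh
}

# Edges used by exactly one face.
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  names(tab)[tab == 1]
}

# Merge-walk triangulation between two index rings with arbitrary counts.
loft_walk <- function(ia, ib, closed) {
  na <- length(ia)
  nb <- length(ib)
  if (closed) {
    ia <- c(ia, ia[1])
    ib <- c(ib, ib[1])
  }
  steps_a <- length(ia) - 1L
  steps_b <- length(ib) - 1L
  tri <- matrix(0L, steps_a + steps_b, 3)
  i <- 1L; j <- 1L; r <- 0L
  while (i <= steps_a || j <= steps_b) {
    adv_a <- j > steps_b ||
      (i <= steps_a && i / steps_a <= j / steps_b)
    r <- r + 1L
    if (adv_a) {
      tri[r, ] <- c(ia[i], ib[j], ia[i + 1])
      i <- i + 1L
    } else {
      tri[r, ] <- c(ia[i], ib[j], ib[j + 1])
      j <- j + 1L
    }
  }
  tri
}

# Rotate each closed ring so its start point lines up with the previous
# ring's (FFT cross-correlation of arc-length-resampled rings).
align_closed_rings <- function(rings) {
  n_ref <- 256L
  for (k in seq_len(length(rings) - 1)) {
    a <- resample_polyline(rings[[k]], 1, TRUE, n_out = n_ref)
    b <- resample_polyline(rings[[k + 1]], 1, TRUE, n_out = n_ref)
    corr <- numeric(n_ref)
    for (col in 1:2) {
      fa <- stats::fft(a[, col])
      fb <- stats::fft(b[, col])
      corr <- corr + Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / n_ref
    }
    shift <- which.max(corr) - 1L          # b lagged by `shift` matches a
    nb <- nrow(rings[[k + 1]])
    j0 <- round(shift / n_ref * nb) %% nb
    if (j0 > 0) {
      idx <- c((j0 + 1):nb, 1:j0)
      rings[[k + 1]] <- rings[[k + 1]][idx, , drop = FALSE]
    }
  }
  rings
}

# Flip open rings so consecutive rings run the same direction.
align_open_rings <- function(rings) {
  for (k in seq_len(length(rings) - 1)) {
    a <- rings[[k]]
    b <- rings[[k + 1]]
    straight <- sum((a[1, 1:2] - b[1, 1:2])^2) +
      sum((a[nrow(a), 1:2] - b[nrow(b), 1:2])^2)
    crossed <- sum((a[1, 1:2] - b[nrow(b), 1:2])^2) +
      sum((a[nrow(a), 1:2] - b[1, 1:2])^2)
    if (crossed < straight) {
      rings[[k + 1]] <- b[rev(seq_len(nrow(b))), , drop = FALSE]
    }
  }
  rings
}
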