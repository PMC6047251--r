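#' Triangulated surface mesh
#'
#' The unit of registration and distance computation: a triangulated bone or
#' cartilage surface in mm. Vertices are an n x 3 matrix; faces an m x 3
#' integer matrix of 1-based vertex indices.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of vertex indices.
#' @param label tissue label, one of [tissue_labels()] (or NULL).
#' @param validate check mesh invariants (degenerate faces, unreferenced
#'   vertices, index range).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, label = NULL, validate = TRUE) {
  vertices <- unname(as.matrix(vertices))
  faces <- unname(matrix(as.integer(faces), ncol = 3))
  stopifnot(ncol(vertices) == 3)
  if (!is.null(label)) label <- match.arg(label, tissue_labels())
  m <- structure(list(vertices = vertices, faces = faces, label = label),
                 class = "surface_mesh")
  if (validate) validate_mesh(m)
  m
}

#' Allowed tissue labels
#' @export
tissue_labels <- function() {
  c("humeral_bone", "humeral_cartilage", "glenoid_bone", "glenoid_cartilage")
}

validate_mesh <- function(m) {
  if (nrow(m$vertices) == 0 || nrow(m$faces) == 0) {
    stop("empty mesh (no vertices or no faces)")
  }
  if (min(m$faces) < 1 || max(m$faces) > nrow(m$vertices)) {
    stop("face indices out of range")
  }
  a <- face_areas(m)
  if (any(a <= 1e-12)) stop("degenerate triangle (area <= 1e-12 mm^2)")
  if (!all(seq_len(nrow(m$vertices)) %in% m$faces)) {
    stop("unreferenced vertices present")
  }
  invisible(m)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh", if (!is.null(x$label)) paste0("<", x$label, ">") else "",
      "\n  vertices:", nrow(x$vertices), " faces:", nrow(x$faces),
      " area:", format(mesh_area(x), digits = 5), "mm^2\n")
  invisible(x)
}

face_cross <- function(m) {
  v <- m$vertices
  f <- m$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

face_areas <- function(m) {
  0.5 * sqrt(rowSums(face_cross(m)^2))
}

#' Total surface area, mm^2
#' @param m a `surface_mesh`.
#' @export
mesh_area <- function(m) sum(face_areas(m))

#' Signed enclosed volume (positive when faces are oriented outward), mm^3
#' @param m a `surface_mesh`.
#' @export
mesh_volume <- function(m) {
  v <- m$vertices
  f <- m$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Area-weighted per-vertex outward normals
#' @param m a `surface_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(m) {
  fc <- face_cross(m)  # 2*area-weighted face normals
  grp <- as.vector(m$faces)
  n <- rowsum(fc[rep(seq_len(nrow(fc)), 3), , drop = FALSE], grp,
              reorder = TRUE)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Per-vertex surface area weights (one third of incident face areas)
#'
#' Used to make surface integrals (centroids, covariances, ICP updates)
#' independent of vertex-density anisotropy, e.g. the in-plane vs
#' slice-direction density difference of contour-lofted meshes.
#'
#' @param m a `surface_mesh`.
#' @return numeric vector of areas, mm^2.
#' @export
vertex_areas <- function(m) {
  fa <- face_areas(m) / 3
  as.numeric(rowsum(rep(fa, 3), as.vector(m$faces),
                    reorder = TRUE)[, 1])
}

#' Flip face orientation
#' @param m a `surface_mesh`.
#' @export
flip_faces <- function(m) {
  m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  m
}

#' Apply a rigid transform to a mesh
#'
#' Vertices map as `x -> R x + t`; faces are unchanged, so pairwise vertex
#' distances are preserved exactly (up to floating point).
#'
#' @param mesh a `surface_mesh`.
#' @param t a `rigid_transform`.
#' @export
apply_transform <- function(mesh, t) {
  mesh$vertices <- transform_points(mesh$vertices, t)
  rad <- attr(mesh, "radial")
  if (!is.null(rad)) {
    rad$pose <- compose_transforms(t, rad$pose)
    attr(mesh, "radial") <- rad
  }
  mesh
}

#' Mirror a mesh in the plane y = 0 (laterality change)
#'
#' Face winding is reversed so outward normals stay outward.
#' @param mesh a `surface_mesh`.
#' @keywords internal
mirror_mesh_y <- function(mesh) {
  mesh$vertices[, 2] <- -mesh$vertices[, 2]
  mesh <- flip_faces(mesh)
  rad <- attr(mesh, "radial")
  if (!is.null(rad)) attr(mesh, "radial") <- mirror_radial(rad)
  mesh
}

# Triangulate the strip between two rings of equal point count.
# ring_a / ring_b: integer vertex indices in order; closed: wrap around.
# Returns m x 3 face matrix with consistent winding (a-ring first).
loft_strip <- function(ring_a, ring_b, closed) {
  n <- length(ring_a)
  stopifnot(length(ring_b) == n)
  i <- seq_len(if (closed) n else n - 1)
  j <- if (closed) c(seq_len(n)[-1], 1L) else i + 1L
  rbind(cbind(ring_a[i], ring_b[i], ring_b[j]),
        cbind(ring_a[i], ring_b[j], ring_a[j]))
}

# Fan from an apex vertex index to a closed ring of vertex indices.
# Winding matches loft_strip when the ring is traversed in the same order;
# global orientation is fixed afterwards by the caller.
fan_cap <- function(apex, ring, reverse = FALSE) {
  n <- length(ring)
  j <- c(seq_len(n)[-1], 1L)
  if (reverse) cbind(ring[j], ring, apex) else cbind(ring, ring[j], apex)
}

#' Least-squares sphere fit (algebraic)
#'
#' @param points n x 3 matrix.
#' @return list with `center` (length 3) and `radius`.
#' @keywords internal
fit_sphere <- function(points) {
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  coef <- qr.solve(A, b)
  center <- coef[1:3]
  radius <- sqrt(coef[4] + sum(center^2))
  list(center = as.numeric(center), radius = radius)
}

#' Merge duplicate vertices within a tolerance
#'
#' @param m a `surface_mesh`.
#' @param tol merge distance, mm.
#' @export
dedup_vertices <- function(m, tol = 1e-6) {
  key <- apply(round(m$vertices / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  keep <- m$vertices[first, , drop = FALSE]
  f <- matrix(map[m$faces], ncol = 3)
  good <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  surface_mesh(keep, f[good, , drop = FALSE], m$label, validate = FALSE)
}
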