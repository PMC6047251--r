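#' Rigid transforms
#'
#' A `rigid_transform` is a proper rigid-body motion in 3D: a rotation
#' `R` (3x3 orthonormal, det = +1) followed by a translation `t` (mm),
#' mapping a point `x` to `R x + t`. Used to express the unknown pose
#' difference between imaging sessions and the alignment recovered by ICP.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation, mm.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal (||R'R - I|| > 1e-9)")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation is not proper (|det(R) - 1| > 1e-9)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  cat("  rotation angle:", format(rotation_angle(x) * 180 / pi, digits = 4),
      "deg\n")
  cat("  translation:  ", paste(format(x$translation, digits = 4),
                                collapse = " "), "mm\n")
  invisible(x)
}

#' Rotation about an axis
#'
#' @param axis numeric length-3 rotation axis (normalized internally).
#' @param angle rotation angle, radians.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Angle of a rigid transform's rotation, radians
#' @param t a `rigid_transform`.
#' @export
rotation_angle <- function(t) {
  acos(pmin(1, pmax(-1, (sum(diag(t$rotation)) - 1) / 2)))
}

#' Apply a rigid transform to a matrix of points
#' @param points n x 3 matrix, mm.
#' @param t a `rigid_transform`.
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(points, t) {
  sweep(points %*% t(t$rotation), 2, t$translation, "+")
}

#' Compose two rigid transforms (apply `a` after `b`)
#' @param a,b `rigid_transform` objects.
#' @return `rigid_transform` equal to `x -> a(b(x))`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Convert to/from a 4x4 homogeneous matrix (row-major semantics)
#' @param t a `rigid_transform`.
#' @return 4x4 matrix with rotation in the top-left block and translation in
#'   the last column.
#' @export
transform_to_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' @rdname transform_to_matrix
#' @param m 4x4 homogeneous matrix.
#' @export
transform_from_matrix <- function(m) {
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Write / read a rigid transform as JSON (4x4 homogeneous, row-major)
#' @param t a `rigid_transform`.
#' @param path file path.
#' @export
write_transform <- function(t, path) {
  m <- transform_to_matrix(t)
  jsonlite::write_json(list(matrix = apply(m, 1, as.numeric, simplify = FALSE)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- do.call(rbind, lapply(obj$matrix, unlist))
  transform_from_matrix(m)
}

#' Seeded random small rigid offset
#'
#' Draws a rotation of exactly `angle` about a uniformly random axis and a
#' translation of exactly `distance` in a uniformly random direction.
#' Emulates the unknown inter-session pose difference of a repositioned
#' shoulder.
#'
#' @param angle rotation magnitude, radians.
#' @param distance translation magnitude, mm.
#' @param seed integer seed (RNG state is restored on exit).
#' @export
random_rigid_offset <- function(angle, distance, seed) {
  with_seed(seed, {
    ax <- stats::rnorm(3)
    dir <- stats::rnorm(3)
    rigid_transform(rotation_about_axis(ax, angle),
                    distance * dir / sqrt(sum(dir^2)))
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
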