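#' ICP configuration
#'
#' @param max_iterations iteration cap.
#' @param tolerance convergence threshold on the per-iteration change of the
#'   RMS nearest-point residual, mm.
#' @param max_match_points moving-vertex budget for matching; larger meshes
#'   are subsampled with a deterministic stride (never randomly).
#' @export
icp_config <- function(max_iterations = 100L, tolerance = 1e-5,
                       max_match_points = 20000L) {
  list(max_iterations = as.integer(max_iterations), tolerance = tolerance,
       max_match_points = as.integer(max_match_points))
}

#' Rigidly align one bone surface to another (iterative closest point)
#'
#' Point-to-point ICP: nearest-neighbour correspondences (kd-tree) between
#' the moving vertices and the fixed vertices, followed by a closed-form
#' least-squares rigid update (Kabsch/SVD), iterated until the RMS residual
#' change drops below `config$tolerance`. Initialization aligns centroids
#' and, when the vertex covariance is sufficiently anisotropic, principal
#' axes (sign combinations disambiguated by the resulting residual);
#' near-isotropic shapes start at the identity rotation. Used to map the
#' post-exercise bone into the pre-exercise frame so cartilage thickness can
#' be compared site-specifically.
#'
#' @param moving,fixed `surface_mesh` objects of the same bone from two
#'   sessions.
#' @param config see [icp_config()].
#' @return a `registration_report`: list with `transform` (mapping moving
#'   into the fixed frame), `rms_residual` (mm), `iterations`, `converged`,
#'   and `rms_trace` (per-iteration RMS, non-increasing).
#' @export
icp_align <- function(moving, fixed, config = icp_config()) {
  if (nrow(moving$vertices) == 0 || nrow(fixed$vertices) == 0) {
    stop("empty mesh passed to icp_align")
  }
  # area weights make the alignment a surface integral, immune to the
  # vertex-density anisotropy of contour-lofted meshes
  w_all <- vertex_areas(moving)
  keep <- subsample_idx(nrow(moving$vertices), config$max_match_points)
  mv <- moving$vertices[keep, , drop = FALSE]
  w <- w_all[keep]
  fx <- fixed$vertices

  tr <- icp_initialize(moving, fixed)
  rms_trace <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  iters <- 0L
  wrms <- function(d) sqrt(sum(w * d^2) / sum(w))
  for (it in seq_len(config$max_iterations)) {
    iters <- it
    cur <- transform_points(mv, tr)
    nn <- RANN::nn2(fx, cur, k = 1)
    match <- fx[nn$nn.idx[, 1], , drop = FALSE]
    rms <- wrms(nn$nn.dists[, 1])
    rms_trace <- c(rms_trace, rms)
    upd <- kabsch(cur, match, w)
    tr <- compose_transforms(upd, tr)
    if (is.finite(prev_rms) && abs(prev_rms - rms) < config$tolerance) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  final <- transform_points(mv, tr)
  rms_final <- wrms(RANN::nn2(fx, final, k = 1)$nn.dists[, 1])
  structure(list(transform = tr, rms_residual = rms_final,
                 iterations = iters, converged = converged,
                 rms_trace = rms_trace),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat("registration_report: rms", format(x$rms_residual, digits = 4),
      "mm after", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

subsample_idx <- function(n, max_n) {
  if (n <= max_n) return(seq_len(n))
  unique(round(seq(1, n, length.out = max_n)))
}

subsample_rows <- function(m, max_n) {
  m[subsample_idx(nrow(m), max_n), , drop = FALSE]
}

# Closed-form (weighted) least-squares rigid motion mapping p onto q
# (Kabsch/SVD).
kabsch <- function(p, q, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(p))
  sw <- sum(w)
  cp <- colSums(p * w) / sw
  cq <- colSums(q * w) / sw
  H <- crossprod(sweep(p, 2, cp) * w, sweep(q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(cq - R %*% cp))
}

# Centroid + principal-axes initialization. Candidate rotations are the
# identity (sessions share pose approximately) and, when the vertex
# covariance is anisotropic enough for axes to be meaningful, the four
# det-+1 sign combinations of the principal-axes alignment; the candidate
# with the smallest probe residual wins.
icp_initialize <- function(moving, fixed) {
  mv <- moving$vertices
  fx <- fixed$vertices
  wm <- vertex_areas(moving)
  wf <- vertex_areas(fixed)
  wcov <- function(x, w) {
    c0 <- colSums(x * w) / sum(w)
    xc <- sweep(x, 2, c0)
    list(center = c0, cov = crossprod(xc * w, xc) / sum(w))
  }
  sm <- wcov(mv, wm)
  sf <- wcov(fx, wf)
  cm <- sm$center
  cf <- sf$center
  em <- eigen(sm$cov, symmetric = TRUE)
  ef <- eigen(sf$cov, symmetric = TRUE)
  gaps <- function(e) min(abs(diff(e$values))) / max(e$values)
  if (gaps(em) < 0.01 || gaps(ef) < 0.01) {
    # axes not meaningful: centroid alignment only
    return(rigid_transform(diag(3), cf - cm))
  }
  # principal-axes alignment; the axes of the same anatomy are far more
  # reliable than the identity rotation, so only the four proper sign
  # combinations compete (disambiguated by probe residual)
  cands <- list()
  Vm <- em$vectors
  Vf <- ef$vectors
  if (det(Vm) < 0) Vm[, 3] <- -Vm[, 3]
  if (det(Vf) < 0) Vf[, 3] <- -Vf[, 3]
  for (s in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    R <- Vf %*% diag(s) %*% t(Vm)
    cands[[length(cands) + 1]] <-
      rigid_transform(R, as.numeric(cf - R %*% cm))
  }
  probe <- subsample_rows(mv, 500L)
  rmss <- vapply(cands, function(tr) {
    sqrt(mean(RANN::nn2(fx, transform_points(probe, tr), k = 1)$nn.dists^2))
  }, 0)
  cands[[which.min(rmss)]]
}
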