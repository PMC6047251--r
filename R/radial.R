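# Radial (star-shaped) analytic surfaces.
#
# Every phantom surface is star-shaped about a center c: points are
# p = pose(c + rho(d) * d) for unit directions d in a domain mask. This makes
# exact plane sections available (1D root solve per azimuth), which is what
# lets the contour simulator reach analytic accuracy where the contour noise
# model demands it. A radial spec is attached to generated meshes as the
# "radial" attribute and survives rigid transforms and mirroring.

radial_surface <- function(center, rho, domain = function(d) rep(TRUE, nrow(d)),
                           pose = rigid_transform()) {
  structure(list(center = as.numeric(center), rho = rho, domain = domain,
                 pose = pose), class = "radial_surface")
}

# Mirror the local shape in y = 0 (laterality). Folded into the closures so
# the result is again a plain radial surface.
mirror_radial <- function(rad) {
  M <- function(d) {
    d[, 2] <- -d[, 2]
    d
  }
  old_rho <- rad$rho
  old_dom <- rad$domain
  radial_surface(center = rad$center * c(1, -1, 1),
                 rho = function(d) old_rho(M(d)),
                 domain = function(d) old_dom(M(d)),
                 pose = rad$pose)
}

# Evaluate world-frame surface points for local unit directions d (n x 3).
radial_points <- function(rad, d) {
  p <- sweep(d * rad$rho(d), 2, rad$center, "+")
  transform_points(p, rad$pose)
}

# World-frame z-range of the surface (for slice planning), via dense sampling.
radial_zrange <- function(rad, n = 4000) {
  d <- fibonacci_sphere(n)
  keep <- rad$domain(d)
  if (!any(keep)) stop("radial surface has empty domain")
  range(radial_points(rad, d[keep, , drop = FALSE])[, 3])
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Section the surface with the world plane z = z0.
# Returns a list of contours: list(points = k x 2 matrix (world x, y),
# closed = logical), already resampled at `point_spacing` and lying on the
# exact surface. Solves rho(d(theta, phi)) * cos(theta) = h by bisection in
# theta for each azimuth phi about the plane normal pulled back to the local
# frame; rho * cos(theta) is monotone in theta for the shallow shapes
# generated here. A coarse azimuth grid locates the section; exact points
# are then re-solved at arc-length-uniform azimuths, so accuracy is set by
# the bisection (~1e-12 mm), not the grid.
radial_slice <- function(rad, z0, point_spacing = 0.3, n_phi = 720) {
  Q <- rad$pose$rotation
  tau <- rad$pose$translation
  m <- as.numeric(t(Q) %*% c(0, 0, 1))          # plane normal, local frame
  h <- z0 - tau[3] - sum(m * rad$center)
  # local orthonormal frame around m
  e1 <- if (abs(m[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * m) * m
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(m[2] * e1[3] - m[3] * e1[2],
          m[3] * e1[1] - m[1] * e1[3],
          m[1] * e1[2] - m[2] * e1[1])

  dir_at <- function(theta, phi) {
    st <- sin(theta)
    ct <- cos(theta)
    cbind(ct * m[1] + st * (cos(phi) * e1[1] + sin(phi) * e2[1]),
          ct * m[2] + st * (cos(phi) * e1[2] + sin(phi) * e2[2]),
          ct * m[3] + st * (cos(phi) * e1[3] + sin(phi) * e2[3]))
  }
  # exact section point(s) at azimuths `phi`; NA rows where no root
  solve_phi <- function(phi) {
    na_phi <- is.na(phi)
    phi[na_phi] <- 0
    lo <- rep(1e-9, length(phi))
    hi <- rep(pi - 1e-9, length(phi))
    g <- function(theta) rad$rho(dir_at(theta, phi)) * cos(theta) - h
    ok <- g(lo) > 0 & g(hi) < 0
    ok[is.na(ok) | na_phi] <- FALSE
    for (it in 1:52) {
      mid <- (lo + hi) / 2
      pos <- g(mid) > 0
      pos[is.na(pos)] <- TRUE
      lo[ok & pos] <- mid[ok & pos]
      hi[ok & !pos] <- mid[ok & !pos]
    }
    d <- dir_at((lo + hi) / 2, phi)
    d[!ok, ] <- NA
    d
  }

  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  d <- solve_phi(phi)
  ok <- !is.na(d[, 1])
  inside <- ok
  inside[ok] <- rad$domain(d[ok, , drop = FALSE])
  if (!any(inside)) return(list())

  full <- all(inside)
  runs <- if (full) list(seq_len(n_phi)) else find_runs(inside)

  out <- list()
  for (r in runs) {
    if (length(r) < 2 && !full) next
    phis <- phi[r]
    jump <- which(diff(phis) < 0)        # run wrapped past 2*pi
    if (length(jump)) {
      phis[(jump[1] + 1):length(phis)] <-
        phis[(jump[1] + 1):length(phis)] + 2 * pi
    }
    pw <- radial_points(rad, d[r, , drop = FALSE])[, 1:2, drop = FALSE]
    if (full) {
      phis <- c(phis, phis[1] + 2 * pi)
      pw <- rbind(pw, pw[1, ])
    }
    seg <- sqrt(rowSums((pw[-1, , drop = FALSE] -
                           pw[-nrow(pw), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    L <- s[length(s)]                    # exact end of the arc-length grid
    if (L < point_spacing) next
    if (full) {
      n <- max(8L, round(L / point_spacing))
      at <- L * (seq_len(n) - 1) / n
    } else {
      n <- max(2L, round(L / point_spacing) + 1)
      at <- L * (seq_len(n) - 1) / (n - 1)
    }
    phi_t <- stats::approx(s, phis, xout = at, ties = "ordered")$y
    dt <- solve_phi(phi_t %% (2 * pi))
    keep <- !is.na(dt[, 1])
    if (sum(keep) < 2) next
    pts <- radial_points(rad, dt[keep, , drop = FALSE])[, 1:2, drop = FALSE]
    out[[length(out) + 1]] <- list(points = pts, closed = full,
                                   resampled = TRUE)
  }
  out
}

# Runs of TRUE in a cyclic logical vector; returns list of index vectors.
find_runs <- function(present) {
  n <- length(present)
  if (!any(present)) return(list())
  if (all(present)) return(list(seq_len(n)))
  # rotate so position 1 is FALSE
  start <- which(!present)[1]
  ord <- c(start:n, if (start > 1) 1:(start - 1))
  p <- present[ord]
  r <- rle(p)
  ends <- cumsum(r$lengths)
  begins <- c(1, head(ends, -1) + 1)
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) out[[length(out) + 1]] <- ord[begins[k]:ends[k]]
  }
  out
}
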