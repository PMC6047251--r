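#' Synthetic shoulder phantom specification
#'
#' Parametric description of a synthetic glenohumeral joint with known
#' ground truth, standing in for segmented MRI of a study participant. The
#' humeral head is a spherical cap (articular cartilage over a 120 degree
#' cap facing medially); the humeral bone carries two smooth Gaussian
#' surface bumps away from the articular surface (greater/lesser tuberosity
#' analogues) so that its rigid pose is geometrically identifiable. The
#' glenoid is a shallow spherical-patch socket with an elliptical footprint.
#' Cartilage is applied along outward surface normals, so the articular
#' (outer) cartilage surface sits exactly one thickness field value above
#' the bone, and the post-exercise scene scales each thickness by
#' `(1 - strain)` before moving rigidly by `rigid_offset`.
#'
#' Defaults emulate the imaging study the pipeline targets: 0.5 mm slice
#' spacing, 0.3 mm in-plane point spacing, 0.04 mm segmentation noise,
#' ~1.0 mm humeral cartilage, and a glenoid thickness pattern rising from
#' 1.2 mm centrally to 1.5 mm at the anteroinferior periphery. Head and
#' socket dimensions are literature-typical and configurable.
#'
#' @param humeral_head_radius humeral head radius, mm.
#' @param glenoid_radius_of_curvature glenoid radius of curvature, mm.
#' @param glenoid_extent named lengths `c(si = , ap = )`, mm (full extents of
#'   the glenoid cartilage footprint).
#' @param laterality `"right"` or `"left"` (left mirrors the anteroposterior
#'   axis).
#' @param humeral_thickness_field,glenoid_thickness_field [field_spec][field_constant]
#'   thickness fields, mm.
#' @param strain_field compressive strain field (fraction in \[0, 1)),
#'   applied to both compartments unless a per-compartment override is given.
#' @param humeral_strain_field,glenoid_strain_field optional per-compartment
#'   strain fields.
#' @param rigid_offset `rigid_transform` applied to the post-exercise scene.
#' @param contour_slice_spacing,in_plane_point_spacing,noise_sd contour
#'   simulation defaults (mm), see [slice_to_contours()].
#' @param seed integer seed used when slicing with noise.
#' @param mesh_spacing target vertex spacing of generated surface meshes, mm.
#' @param humeral_cap_angle full opening angle of the humeral articular cap,
#'   radians.
#' @param surfaces subset of [tissue_labels()] to generate.
#' @param subject subject identifier.
#' @return validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(humeral_head_radius = 24,
                         glenoid_radius_of_curvature = 30,
                         glenoid_extent = c(si = 35, ap = 25),
                         laterality = "right",
                         humeral_thickness_field = field_constant(1.0),
                         glenoid_thickness_field = field_radial_glenoid(),
                         strain_field = field_constant(0),
                         humeral_strain_field = NULL,
                         glenoid_strain_field = NULL,
                         rigid_offset = rigid_transform(),
                         contour_slice_spacing = 0.5,
                         in_plane_point_spacing = 0.3,
                         noise_sd = 0.04,
                         seed = 1L,
                         mesh_spacing = 0.6,
                         humeral_cap_angle = 2 * pi / 3,
                         surfaces = tissue_labels(),
                         subject = "phantom") {
  spec <- list(humeral_head_radius = humeral_head_radius,
               glenoid_radius_of_curvature = glenoid_radius_of_curvature,
               glenoid_extent = glenoid_extent,
               laterality = match.arg(laterality, c("right", "left")),
               humeral_thickness_field = humeral_thickness_field,
               glenoid_thickness_field = glenoid_thickness_field,
               strain_field = strain_field,
               humeral_strain_field = humeral_strain_field %||% strain_field,
               glenoid_strain_field = glenoid_strain_field %||% strain_field,
               rigid_offset = rigid_offset,
               contour_slice_spacing = contour_slice_spacing,
               in_plane_point_spacing = in_plane_point_spacing,
               noise_sd = noise_sd,
               seed = as.integer(seed),
               mesh_spacing = mesh_spacing,
               humeral_cap_angle = humeral_cap_angle,
               surfaces = match.arg(surfaces, tissue_labels(),
                                    several.ok = TRUE),
               subject = subject)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_phantom_spec <- function(spec) {
  pos <- c("humeral_head_radius", "glenoid_radius_of_curvature",
           "contour_slice_spacing", "in_plane_point_spacing", "mesh_spacing",
           "humeral_cap_angle")
  for (f in pos) {
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1 || spec[[f]] <= 0) {
      stop("invalid phantom spec: field '", f, "' must be a positive number")
    }
  }
  if (!all(c("si", "ap") %in% names(spec$glenoid_extent)) ||
      any(spec$glenoid_extent[c("si", "ap")] <= 0)) {
    stop("invalid phantom spec: field 'glenoid_extent' needs positive ",
         "'si' and 'ap' entries")
  }
  if (spec$noise_sd < 0) {
    stop("invalid phantom spec: field 'noise_sd' must be >= 0")
  }
  for (f in c("humeral_thickness_field", "glenoid_thickness_field",
              "humeral_strain_field", "glenoid_strain_field")) {
    if (!is_field(spec[[f]])) {
      stop("invalid phantom spec: field '", f, "' must be a field_spec")
    }
  }
  if (!inherits(spec$rigid_offset, "rigid_transform")) {
    stop("invalid phantom spec: field 'rigid_offset' must be a ",
         "rigid_transform")
  }
  # strain range check over each compartment's footprint
  for (cmp in c("humeral", "glenoid")) {
    ctx <- phantom_field_ctx(spec, cmp)
    eps <- eval_field(spec[[paste0(cmp, "_strain_field")]],
                      ctx$samples$ap_n, ctx$samples$si_n, ctx)
    if (any(eps < 0 | eps >= 1)) {
      stop("invalid phantom spec: field '", cmp, "_strain_field' must lie ",
           "in [0, 1) over the footprint")
    }
  }
  spec
}

# Fixed anatomy of the canonical (right) phantom frame: +x lateral,
# +y anterior, +z superior; humeral center at the origin.
phantom_anatomy <- function(spec) {
  Rh <- spec$humeral_head_radius
  Rg <- spec$glenoid_radius_of_curvature
  cap_half <- spec$humeral_cap_angle / 2
  list(
    hc = c(0, 0, 0),
    Rh = Rh,
    # mild triaxial asphericity + two tuberosity bumps away from the
    # articular cap make the bone's rigid pose geometrically identifiable
    # (principal axes + unique flip disambiguation) for ICP
    semi_axes = Rh * c(1, 0.97, 0.94),
    cap_axis = c(-1, 0, 0),
    cap_half = cap_half,
    bumps = list(
      list(dir = vnorm(c(0.75, 0.35, 0.55)), amp = 3.0, sigma = 25 * pi / 180),
      list(dir = vnorm(c(0.55, 0.80, -0.20)), amp = 2.0, sigma = 20 * pi / 180)
    ),
    gc = c(Rg - (Rh + 2), 0, 0),
    Rg = Rg,
    ap_semi = unname(spec$glenoid_extent["ap"]) / 2,
    si_semi = unname(spec$glenoid_extent["si"]) / 2,
    bone_patch_scale = 1.18,
    # pear-shaped footprint (wider inferiorly), as in real glenoids; also
    # removes the 180-degree flip symmetry an elliptical dish would have
    pear = 0.2
  )
}

vnorm <- function(v) v / sqrt(sum(v^2))

# Normalized anatomical coordinates of unit directions, per compartment.
anat_coords <- function(an, cmp, d) {
  if (cmp == "humeral") {
    s <- sin(an$cap_half)
    list(ap_n = d[, 2] / s, si_n = d[, 3] / s)
  } else {
    list(ap_n = an$Rg * d[, 2] / an$ap_semi,
         si_n = an$Rg * d[, 3] / an$si_semi)
  }
}

# Frozen footprint-quantile context used by regional fields: area-weighted
# terciles of the normalized anatomical coordinates over the cartilage
# footprint (deterministic dense sampling).
phantom_field_ctx <- function(spec, cmp) {
  an <- phantom_anatomy(spec)
  if (cmp == "glenoid") {
    g <- as.matrix(expand.grid(a = seq(-1.3, 1.3, length.out = 181),
                               s = seq(-1, 1, length.out = 141)))
    keep <- (g[, 1] / (1 - an$pear * g[, 2]))^2 + g[, 2]^2 <= 1
    g <- g[keep, , drop = FALSE]
    ap_n <- g[, 1]
    si_n <- g[, 2]
  } else {
    ct <- seq(cos(an$cap_half), 1, length.out = 101)
    phi <- seq(0, 2 * pi, length.out = 181)[-181]
    g <- expand.grid(ct = ct, phi = phi)
    st <- sqrt(pmax(0, 1 - g$ct^2))
    s <- sin(an$cap_half)
    ap_n <- st * cos(g$phi) / s
    si_n <- st * sin(g$phi) / s
  }
  ctx <- list(
    compartment = cmp,
    ap_terciles = unname(stats::quantile(ap_n, c(1, 2) / 3)),
    si_terciles = unname(stats::quantile(si_n, c(1, 2) / 3)),
    si_split = unname(stats::median(si_n)),
    samples = list(ap_n = ap_n, si_n = si_n)
  )
  if (cmp == "humeral") {
    up <- si_n >= ctx$si_split
    ctx$band_si_terciles <- list(
      superior = unname(stats::quantile(si_n[up], c(1, 2) / 3)),
      inferior = unname(stats::quantile(si_n[!up], c(1, 2) / 3)))
  }
  ctx
}

# rho / domain closures for each surface of one session.
phantom_radials <- function(spec, session) {
  an <- phantom_anatomy(spec)
  ctxs <- list(humeral = phantom_field_ctx(spec, "humeral"),
               glenoid = phantom_field_ctx(spec, "glenoid"))
  scale_t <- function(cmp, d) {
    ac <- anat_coords(an, cmp, d)
    ctx <- ctxs[[cmp]]
    t <- eval_field(spec[[paste0(cmp, "_thickness_field")]],
                    ac$ap_n, ac$si_n, ctx)
    if (session == "post") {
      eps <- eval_field(spec[[paste0(cmp, "_strain_field")]],
                        ac$ap_n, ac$si_n, ctx)
      t <- t * (1 - eps)
    }
    t
  }
  hb_rho <- function(d) {
    r <- 1 / sqrt(d[, 1]^2 / an$semi_axes[1]^2 +
                    d[, 2]^2 / an$semi_axes[2]^2 +
                    d[, 3]^2 / an$semi_axes[3]^2)
    for (b in an$bumps) {
      ang <- acos(pmin(1, pmax(-1, d %*% b$dir)))
      r <- r + b$amp * exp(-ang^2 / (2 * b$sigma^2))
    }
    as.numeric(r)
  }
  cap_dom <- function(scale) {
    force(scale)
    function(d) {
      as.numeric(d %*% an$cap_axis) >= cos(an$cap_half * scale)
    }
  }
  gle_dom <- function(scale) {
    force(scale)
    function(d) {
      ac <- anat_coords(an, "glenoid", d)
      A <- ac$ap_n / scale
      S <- ac$si_n / scale
      d[, 1] < 0 & (A / (1 - an$pear * S))^2 + S^2 <= 1
    }
  }
  list(
    humeral_bone = radial_surface(an$hc, hb_rho),
    humeral_cartilage = radial_surface(
      an$hc, function(d) hb_rho(d) + scale_t("humeral", d), cap_dom(1)),
    glenoid_bone = radial_surface(
      an$gc, function(d) rep(an$Rg, nrow(d)), gle_dom(an$bone_patch_scale)),
    glenoid_cartilage = radial_surface(
      an$gc, function(d) an$Rg - scale_t("glenoid", d), gle_dom(1))
  )
}

#' Generate a synthetic shoulder phantom with ground truth
#'
#' Builds the pre- and post-exercise scenes (up to four labeled surface
#' meshes per session: humeral bone, humeral cartilage outer, glenoid bone,
#' glenoid cartilage outer) plus a ground-truth record. The post scene
#' equals the pre scene with each cartilage thickness scaled pointwise by
#' `(1 - strain)` and the whole scene moved rigidly by the spec's
#' `rigid_offset`. Every surface carries its exact parametrization, so
#' [slice_to_contours()] sections it analytically.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `pre`, `post` (named lists of `surface_mesh`)
#'   and `truth`: per-compartment data frames (`x, y, z, ap_n, si_n, t_pre,
#'   t_post, strain` at the pre-scene bone vertices under cartilage) and
#'   `true_rigid_offset`, the transform mapping the pre scene onto the post
#'   scene in world coordinates.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  an <- phantom_anatomy(spec)
  rads_pre <- phantom_radials(spec, "pre")
  rads_post <- phantom_radials(spec, "post")

  scenes <- list(pre = list(), post = list())
  for (lab in spec$surfaces) {
    for (ses in c("pre", "post")) {
      rad <- (if (ses == "pre") rads_pre else rads_post)[[lab]]
      mesh <- phantom_mesh(spec, an, lab, rad)
      scenes[[ses]][[lab]] <- mesh
    }
  }

  truth <- list()
  for (cmp in c("humeral", "glenoid")) {
    bone_lab <- paste0(cmp, "_bone")
    cart_lab <- paste0(cmp, "_cartilage")
    if (!(bone_lab %in% spec$surfaces && cart_lab %in% spec$surfaces)) next
    bone <- scenes$pre[[bone_lab]]
    center <- if (cmp == "humeral") an$hc else an$gc
    d <- sweep(bone$vertices, 2, center)
    d <- d / sqrt(rowSums(d^2))
    inside <- rads_pre[[cart_lab]]$domain(d)
    d <- d[inside, , drop = FALSE]
    ac <- anat_coords(an, cmp, d)
    ctx <- phantom_field_ctx(spec, cmp)
    t_pre <- eval_field(spec[[paste0(cmp, "_thickness_field")]],
                        ac$ap_n, ac$si_n, ctx)
    eps <- eval_field(spec[[paste0(cmp, "_strain_field")]],
                      ac$ap_n, ac$si_n, ctx)
    truth[[cmp]] <- data.frame(
      vertex = which(inside),
      x = bone$vertices[inside, 1], y = bone$vertices[inside, 2],
      z = bone$vertices[inside, 3],
      ap_n = ac$ap_n, si_n = ac$si_n,
      t_pre = t_pre, t_post = t_pre * (1 - eps), strain = eps)
  }

  offset <- spec$rigid_offset
  if (spec$laterality == "left") {
    scenes$pre <- lapply(scenes$pre, mirror_mesh_y)
    scenes$post <- lapply(scenes$post, mirror_mesh_y)
    for (cmp in names(truth)) {
      truth[[cmp]]$y <- -truth[[cmp]]$y
    }
    M <- diag(c(1, -1, 1))
    offset <- rigid_transform(M %*% offset$rotation %*% M,
                              as.numeric(M %*% offset$translation))
  }
  scenes$post <- lapply(scenes$post, apply_transform, t = offset)

  truth$true_rigid_offset <- offset
  truth$spec <- spec
  list(pre = scenes$pre, post = scenes$post, truth = truth)
}

# Structured ring mesh for one phantom surface, radial spec attached.
phantom_mesh <- function(spec, an, lab, rad) {
  h <- spec$mesh_spacing
  if (lab == "humeral_bone") {
    rings <- polar_rings(rad, pole = c(0, 0, 1), theta_max = pi, h = h,
                         radius = an$Rh)
    mesh <- rings_to_mesh(rings$rings, apexes = rings$apexes, lab)
  } else if (lab == "humeral_cartilage") {
    rings <- polar_rings(rad, pole = an$cap_axis, theta_max = an$cap_half,
                         h = h, radius = an$Rh + 1)
    mesh <- rings_to_mesh(rings$rings, apexes = rings$apexes[1], lab)
  } else {
    scale <- if (lab == "glenoid_bone") an$bone_patch_scale else 1
    rings <- glenoid_rings(rad, an, scale, h)
    mesh <- rings_to_mesh(rings$rings, apexes = rings$apexes[1], lab)
  }
  attr(mesh, "radial") <- rad
  orient_mesh(mesh)
}

polar_rings <- function(rad, pole, theta_max, h, radius) {
  e1 <- if (abs(pole[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- vnorm(e1 - sum(e1 * pole) * pole)
  e2 <- c(pole[2] * e1[3] - pole[3] * e1[2],
          pole[3] * e1[1] - pole[1] * e1[3],
          pole[1] * e1[2] - pole[2] * e1[1])
  full <- abs(theta_max - pi) < 1e-9
  n_th <- max(3L, ceiling(theta_max * radius / h))
  thetas <- seq(0, theta_max, length.out = n_th + 1)
  inner <- thetas[-1]
  if (full) inner <- inner[-length(inner)] else
    inner[length(inner)] <- theta_max - 1e-9
  rings <- lapply(inner, function(th) {
    n <- max(8L, round(2 * pi * radius * sin(th) / h))
    phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    d <- cos(th) * matrix(pole, n, 3, byrow = TRUE) +
      sin(th) * (cos(phi) %o% e1 + sin(phi) %o% e2)
    d <- d / sqrt(rowSums(d^2))
    radial_points(rad, d)
  })
  apexes <- list(as.numeric(radial_points(rad, matrix(pole, 1))))
  if (full) apexes[[2]] <- as.numeric(radial_points(rad, matrix(-pole, 1)))
  list(rings = rings, apexes = apexes)
}

glenoid_rings <- function(rad, an, scale, h) {
  a <- an$ap_semi * scale
  b <- an$si_semi * scale
  n_r <- max(3L, ceiling(max(a, b) / h))
  rhos <- seq(0, 1, length.out = n_r + 1)[-1]
  rings <- lapply(rhos, function(r) {
    per <- pi * (3 * (a * r + b * r) -
                 sqrt((3 * a * r + b * r) * (a * r + 3 * b * r)))
    n <- max(8L, round(per / h))
    psi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    S <- r * sin(psi)
    A <- r * cos(psi) * (1 - an$pear * S)
    u <- a * A
    w <- b * S
    x <- -sqrt(pmax(0, an$Rg^2 - u^2 - w^2))
    d <- cbind(x, u, w) / an$Rg
    radial_points(rad, d)
  })
  apex <- as.numeric(radial_points(rad, matrix(c(-1, 0, 0), 1)))
  list(rings = rings, apexes = list(apex))
}

rings_to_mesh <- function(rings, apexes, label) {
  offs <- cumsum(c(0, vapply(rings, nrow, 0L)))
  verts <- do.call(rbind, rings)
  faces <- list()
  for (k in seq_len(length(rings) - 1)) {
    ia <- offs[k] + seq_len(nrow(rings[[k]]))
    ib <- offs[k + 1] + seq_len(nrow(rings[[k + 1]]))
    faces[[k]] <- loft_walk(ia, ib, TRUE)
  }
  if (length(apexes) >= 1 && !is.null(apexes[[1]])) {
    verts <- rbind(verts, apexes[[1]])
    faces[[length(faces) + 1]] <-
      fan_cap(nrow(verts), offs[1] + seq_len(nrow(rings[[1]])))
  }
  if (length(apexes) >= 2) {
    verts <- rbind(verts, apexes[[2]])
    faces[[length(faces) + 1]] <-
      fan_cap(nrow(verts), offs[length(rings)] +
                seq_len(nrow(rings[[length(rings)]])), reverse = TRUE)
  }
  surface_mesh(unname(verts), do.call(rbind, faces), label, validate = FALSE)
}

#' Evaluate the phantom's ground-truth fields at arbitrary surface points
#'
#' Maps pre-exercise-scene points (e.g. vertices of a reconstructed bone
#' surface) to the phantom's anatomical coordinates and evaluates the true
#' thickness and strain fields there. Points outside the cartilage
#' footprint get `inside = FALSE` and NA fields.
#'
#' @param spec the [phantom_spec()] that generated the scene.
#' @param points n x 3 matrix of pre-scene points, mm.
#' @param compartment `"humeral"` or `"glenoid"`.
#' @return data frame `ap_n`, `si_n`, `inside`, `t_pre`, `t_post`, `strain`.
#' @export
phantom_truth_at <- function(spec, points,
                             compartment = c("glenoid", "humeral")) {
  compartment <- match.arg(compartment)
  an <- phantom_anatomy(spec)
  points <- as.matrix(points)
  if (spec$laterality == "left") points[, 2] <- -points[, 2]
  center <- if (compartment == "humeral") an$hc else an$gc
  d <- sweep(points, 2, center)
  d <- d / sqrt(rowSums(d^2))
  rads <- phantom_radials(spec, "pre")
  inside <- rads[[paste0(compartment, "_cartilage")]]$domain(d)
  ac <- anat_coords(an, compartment, d)
  ctx <- phantom_field_ctx(spec, compartment)
  t_pre <- eval_field(spec[[paste0(compartment, "_thickness_field")]],
                      ac$ap_n, ac$si_n, ctx)
  eps <- eval_field(spec[[paste0(compartment, "_strain_field")]],
                    ac$ap_n, ac$si_n, ctx)
  t_pre[!inside] <- NA
  eps[!inside] <- NA
  data.frame(ap_n = ac$ap_n, si_n = ac$si_n, inside = inside,
             t_pre = t_pre, t_post = t_pre * (1 - eps), strain = eps)
}

#' Analytic sphere surface (testing aid)
#'
#' A closed sphere mesh carrying its exact radial parametrization, so
#' [slice_to_contours()] sections it analytically.
#'
#' @param radius sphere radius, mm.
#' @param center length-3 center, mm.
#' @param spacing target vertex spacing, mm.
#' @param label optional tissue label.
#' @export
sphere_surface <- function(radius, center = c(0, 0, 0), spacing = 0.6,
                           label = NULL) {
  rad <- radial_surface(center, function(d) rep(radius, nrow(d)))
  rings <- polar_rings(rad, pole = c(0, 0, 1), theta_max = pi, h = spacing,
                       radius = radius)
  mesh <- rings_to_mesh(rings$rings, apexes = rings$apexes, label)
  attr(mesh, "radial") <- rad
  if (mesh_volume(mesh) < 0) mesh <- flip_faces(mesh)
  mesh
}
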