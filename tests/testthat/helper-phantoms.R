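# Shared fixtures, built once per test run and cached. All geometry is
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small analytic sphere scene used by contour/reconstruction tests
sphere10 <- function() {
  cached("sphere10", sphere_surface(10, spacing = 0.5, label = "humeral_bone"))
}

sphere10_stack <- function() {
  cached("sphere10_stack",
         slice_to_contours(list(sphere10()), spacing = 0.5,
                           point_spacing = 0.3, noise_sd = 0, seed = 1))
}

# default glenoid-only phantom (no deformation, identity offset)
glenoid_phantom <- function() {
  cached("glenoid_phantom", generate_phantom(
    phantom_spec(surfaces = c("glenoid_bone", "glenoid_cartilage"))))
}

# default humeral-only phantom
humeral_phantom <- function() {
  cached("humeral_phantom", generate_phantom(
    phantom_spec(surfaces = c("humeral_bone", "humeral_cartilage"))))
}

# noiseless pre-scene stack of the default glenoid phantom
glenoid_stack0 <- function() {
  cached("glenoid_stack0",
         slice_to_contours(glenoid_phantom()$pre, 0.5, 0.3, 0, seed = 1))
}

glenoid_bone_mesh <- function() {
  cached("glenoid_bone_mesh",
         reconstruct_surface(glenoid_stack0(), "glenoid_bone"))
}

# simulate one subject and run the pipeline for one compartment;
# strain fields keyed by compartment
run_phantom_subject <- function(seed, compartment,
                                strain_field = field_constant(0),
                                offset = random_rigid_offset(5 * pi / 180, 3,
                                                             seed + 9000L),
                                noise_sd = 0.04) {
  surfaces <- if (compartment == "glenoid") {
    c("glenoid_bone", "glenoid_cartilage")
  } else {
    c("humeral_bone", "humeral_cartilage", "glenoid_bone")
  }
  spec <- phantom_spec(
    humeral_strain_field = if (compartment == "humeral") strain_field,
    glenoid_strain_field = if (compartment == "glenoid") strain_field,
    rigid_offset = offset, surfaces = surfaces, noise_sd = noise_sd,
    seed = seed, subject = sprintf("s%03d", seed))
  ph <- generate_phantom(spec)
  pre <- slice_to_contours(ph$pre, spec$contour_slice_spacing,
                           spec$in_plane_point_spacing, noise_sd,
                           seed = 2L * seed + 1L,
                           subject = spec$subject, session = "pre")
  post <- slice_to_contours(ph$post, spec$contour_slice_spacing,
                            spec$in_plane_point_spacing, noise_sd,
                            seed = 2L * seed + 2L,
                            subject = spec$subject, session = "post")
  res <- run_subject(pre, post, run_config(compartments = compartment))
  res$truth <- ph$truth
  res
}

# brute-force point-to-surface distance oracle, independent of the package
# implementation: min distance to a dense barycentric sampling of every face
brute_point_mesh_distance <- function(p, mesh, n = 12) {
  v <- mesh$vertices
  f <- mesh$faces
  g <- expand.grid(a = seq(0, 1, length.out = n), b = seq(0, 1,
                                                          length.out = n))
  g <- g[g$a + g$b <= 1, ]
  best <- Inf
  for (fi in seq_len(nrow(f))) {
    a <- v[f[fi, 1], ]
    b <- v[f[fi, 2], ]
    cc <- v[f[fi, 3], ]
    pts <- outer(1 - g$a - g$b, a) + outer(g$a, b) + outer(g$b, cc)
    best <- min(best, sqrt(min(rowSums(sweep(pts, 2, p)^2))))
  }
  best
}

expect_transform_close <- function(a, b, rot_tol, trans_tol) {
  comp <- compose_transforms(a, invert_transform(b))
  expect_lt(rotation_angle(comp), rot_tol)
  expect_lt(sqrt(sum(comp$translation^2)), trans_tol)
}
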