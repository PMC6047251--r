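test_that("concentric spheres give the analytic 1 mm thickness", {
  bone <- sphere_surface(20, spacing = 0.6, label = "humeral_bone")
  cart <- sphere_surface(21, spacing = 0.4, label = "humeral_cartilage")
  map <- compute_thickness_map(bone, cart)
  expect_true(all(map$mask))
  expect_lt(max(abs(map$thickness - 1)), 0.05)
})

test_that("a cartilage surface coincident with the bone has zero thickness", {
  bone <- sphere_surface(15, spacing = 1, label = "humeral_bone")
  cart <- bone
  cart$label <- "humeral_cartilage"
  map <- compute_thickness_map(bone, cart)
  expect_lt(max(map$thickness[map$mask]), 1e-12)
})

test_that("the phantom glenoid thickness field is recovered per vertex", {
  bone <- glenoid_bone_mesh()
  cart <- reconstruct_surface(glenoid_stack0(), "glenoid_cartilage")
  map <- compute_thickness_map(bone, cart)
  spec <- phantom_spec(surfaces = c("glenoid_bone", "glenoid_cartilage"))
  tr <- phantom_truth_at(spec, bone$vertices, "glenoid")
  # compare where cartilage truly covers the bone, away from the patch edge
  core <- tr$inside & (tr$ap_n^2 + tr$si_n^2) < 0.9^2 & map$mask
  expect_gt(sum(core), 2000)
  expect_lt(max(abs(map$thickness[core] - tr$t_pre[core])), 0.08)
})

test_that("thickness maps are invariant under a common rigid transform", {
  bone <- glenoid_bone_mesh()
  cart <- reconstruct_surface(glenoid_stack0(), "glenoid_cartilage")
  map0 <- compute_thickness_map(bone, cart)
  tt <- rigid_transform(rotation_about_axis(c(1, 2, -1), 0.8), c(5, -3, 2))
  map1 <- compute_thickness_map(apply_transform(bone, tt),
                                apply_transform(cart, tt))
  expect_identical(map0$mask, map1$mask)
  expect_lt(max(abs(map0$thickness - map1$thickness), na.rm = TRUE), 1e-9)
})

test_that("footprint masking excludes uncovered and far-side bone", {
  # closed humeral bone vs its articular cap cartilage: the lateral half
  # of the bone must be masked out by the normal test
  ph <- humeral_phantom()
  map <- compute_thickness_map(ph$pre$humeral_bone,
                               ph$pre$humeral_cartilage)
  v <- ph$pre$humeral_bone$vertices
  expect_true(any(map$mask))
  expect_false(any(map$mask & v[, 1] > 15))  # far (lateral) cortex excluded
  d <- v / sqrt(rowSums(v^2))
  deep <- d[, 1] < -cos(30 * pi / 180)      # well inside the articular cap
  # 0.6 mm generator mesh spacing bounds the nearest-vertex overshoot
  expect_lt(max(abs(map$thickness[deep & map$mask] - 1)), 0.08)
})

test_that("nearest-vertex and point-to-triangle thickness agree within an edge length", {
  bone <- glenoid_bone_mesh()
  cart <- reconstruct_surface(glenoid_stack0(), "glenoid_cartilage")
  nv <- compute_thickness_map(bone, cart)
  pt <- compute_thickness_map(bone, cart,
                              thickness_config(method = "point_to_triangle"))
  edge <- 2 * 0.5  # generous bound on the cartilage mesh edge length, mm
  both <- nv$mask & pt$mask
  expect_lt(max(abs(nv$thickness[both] - pt$thickness[both])), edge)
  expect_true(all(pt$thickness[both] <= nv$thickness[both] + 1e-9))
  # point-to-triangle agrees with an independent brute-force oracle
  idx <- which(both)[c(10, 500, 1500)]
  for (i in idx) {
    oracle <- brute_point_mesh_distance(bone$vertices[i, ], cart)
    expect_equal(unname(pt$thickness[i]), oracle, tolerance = 0.01)
  }
})

test_that("degenerate thickness inputs raise errors", {
  bone <- sphere_surface(10, spacing = 1, label = "humeral_bone")
  empty <- bone
  empty$vertices <- bone$vertices[0, , drop = FALSE]
  expect_error(compute_thickness_map(bone, empty), "empty cartilage")
  far <- sphere_surface(10, center = c(100, 0, 0), spacing = 1,
                        label = "humeral_cartilage")
  expect_error(compute_thickness_map(bone, far), "no cartilage footprint")
})

test_that("repeatability of identical segmentations is exactly zero", {
  st <- glenoid_stack0()
  rep <- compute_repeatability(list(st, st, st), "glenoid")
  expect_equal(rep$sd_mean_mm, 0)
  expect_equal(rep$sd_pointwise_mm, 0)
  expect_equal(rep$strain_equivalent_mean_pct, 0)
})

test_that("repeated noisy segmentations land in the expected SD band", {
  ph <- glenoid_phantom()
  stacks <- lapply(1:4, function(k) {
    slice_to_contours(ph$pre, 0.5, 0.3, 0.04, seed = 500 + k)
  })
  rep <- compute_repeatability(stacks, "glenoid")
  # sampling band for a per-site SD estimated from n = 4 at 0.04 mm noise
  expect_gt(rep$sd_pointwise_mm, 0.01)
  expect_lt(rep$sd_pointwise_mm, 0.08)
  # the mean-thickness SD is far smaller: averaging over thousands of sites
  expect_lt(rep$sd_mean_mm, rep$sd_pointwise_mm)
  expect_error(compute_repeatability(stacks[1], "glenoid"), "at least 2")
})

test_that("a 0.04 mm SD on 1.15 mm cartilage is a 3.5% strain equivalent", {
  expect_equal(round(strain_equivalent(0.04, mean(c(1.0, 1.3))), 1), 3.5)
})
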