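test_that("self-alignment returns the identity with negligible residual", {
  m <- glenoid_phantom()$pre$glenoid_bone
  rep <- icp_align(m, m)
  expect_true(rep$converged)
  expect_lt(rep$rms_residual, 1e-6)
  expect_lt(rotation_angle(rep$transform), 1e-6)
  expect_lt(max(abs(rep$transform$translation)), 1e-6)
})

test_that("a known rigid offset of the humeral bone is recovered exactly without noise", {
  hb <- humeral_phantom()$pre$humeral_bone
  tt <- rigid_transform(rotation_about_axis(c(0, 0, 1), 5 * pi / 180),
                        c(2, 1, 0.5))
  rep <- icp_align(apply_transform(hb, tt), hb)
  # recovered transform composed with the applied one is the identity
  comp <- compose_transforms(rep$transform, tt)
  expect_lt(rotation_angle(comp), 1e-3)
  expect_lt(sqrt(sum(comp$translation^2)), 1e-3)
})

test_that("recovery under 0.04 mm vertex noise stays within 0.2 deg / 0.05 mm", {
  hb <- humeral_phantom()$pre$humeral_bone
  tt <- rigid_transform(rotation_about_axis(c(1, -1, 2), 5 * pi / 180),
                        c(2, 1, 0.5))
  mv <- apply_transform(hb, tt)
  set.seed(1234)
  mv$vertices <- mv$vertices +
    matrix(stats::rnorm(length(mv$vertices), 0, 0.04), ncol = 3)
  rep <- icp_align(mv, hb)
  comp <- compose_transforms(rep$transform, tt)
  expect_lt(rotation_angle(comp), 0.2 * pi / 180)
  expect_lt(sqrt(sum(comp$translation^2)), 0.05)
})

test_that("the rms trace is non-increasing and reported per iteration", {
  gb <- glenoid_phantom()$pre$glenoid_bone
  tt <- rigid_transform(rotation_about_axis(c(1, 0, 0), 8 * pi / 180),
                        c(3, -2, 1))
  rep <- icp_align(apply_transform(gb, tt), gb)
  expect_length(rep$rms_trace, rep$iterations)
  expect_true(all(diff(rep$rms_trace) <= 1e-9))
})

test_that("forward and reverse alignments are mutually inverse", {
  gb <- glenoid_phantom()$pre$glenoid_bone
  tt <- rigid_transform(rotation_about_axis(c(0, 1, 1), 6 * pi / 180),
                        c(1, 2, -1))
  moved <- apply_transform(gb, tt)
  fwd <- icp_align(moved, gb)$transform
  rev <- icp_align(gb, moved)$transform
  comp <- compose_transforms(fwd, rev)
  expect_lt(rotation_angle(comp), 1e-3)
  expect_lt(sqrt(sum(comp$translation^2)), 1e-3)
})

test_that("initial misalignments up to 15 deg / 10 mm are inside the basin", {
  for (mesh in list(glenoid_phantom()$pre$glenoid_bone,
                    humeral_phantom()$pre$humeral_bone)) {
    tt <- rigid_transform(rotation_about_axis(c(2, 1, -1), 15 * pi / 180),
                          c(7, -5, 4))
    rep <- icp_align(apply_transform(mesh, tt), mesh)
    expect_lt(rep$rms_residual, 1e-6)  # noiseless: well below 2x noise floor
  }
})

test_that("icp reports rather than throws when it cannot converge", {
  gb <- glenoid_phantom()$pre$glenoid_bone
  tt <- rigid_transform(rotation_about_axis(c(0, 0, 1), 10 * pi / 180),
                        c(2, 0, 0))
  rep <- icp_align(apply_transform(gb, tt), gb,
                   icp_config(max_iterations = 2, tolerance = 1e-16))
  expect_false(rep$converged)
  expect_equal(rep$iterations, 2L)
})

test_that("empty meshes are rejected", {
  gb <- glenoid_phantom()$pre$glenoid_bone
  empty <- gb
  empty$vertices <- gb$vertices[0, , drop = FALSE]
  expect_error(icp_align(empty, gb), "empty")
})

test_that("apply_transform moves vertices rigidly and exactly", {
  m <- sphere_surface(5, spacing = 1)
  expect_equal(apply_transform(m, rigid_transform())$vertices, m$vertices)
  shifted <- apply_transform(m, rigid_transform(diag(3), c(1, 0, 0)))
  expect_equal(colMeans(shifted$vertices) - colMeans(m$vertices),
               c(1, 0, 0), tolerance = 1e-12)
  t1 <- rigid_transform(rotation_about_axis(c(1, 2, 3), 0.7), c(1, -1, 2))
  t2 <- rigid_transform(rotation_about_axis(c(3, -1, 0), -0.4), c(0, 2, 1))
  seq2 <- apply_transform(apply_transform(m, t1), t2)
  once <- apply_transform(m, compose_transforms(t2, t1))
  expect_lt(max(abs(seq2$vertices - once$vertices)), 1e-9)
  # pairwise distances preserved
  idx <- seq(1, nrow(m$vertices), by = 37)
  d0 <- stats::dist(m$vertices[idx, ])
  d1 <- stats::dist(once$vertices[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})
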