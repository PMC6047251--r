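test_that("slicing a 10 mm sphere gives analytic circular sections", {
  st <- sphere10_stack()
  n <- length(st$slices)
  expect_gte(n, 39)
  expect_lte(n, 41)
  for (sl in st$slices) {
    expect_length(sl$contours, 1)
    ct <- sl$contours[[1]]
    expect_true(ct$closed)
    r_true <- sqrt(100 - sl$z^2)
    r_obs <- sqrt(rowSums(ct$points^2))
    expect_lt(max(abs(r_obs - r_true)), 1e-6)
  }
})

test_that("slicing is deterministic: noise off ignores the seed, fixed seed reproduces", {
  s <- sphere10()
  a <- slice_to_contours(list(s), 0.5, 0.3, 0, seed = 1)
  b <- slice_to_contours(list(s), 0.5, 0.3, 0, seed = 999)
  expect_identical(a, b)
  c1 <- slice_to_contours(list(s), 0.5, 0.3, 0.04, seed = 7)
  c2 <- slice_to_contours(list(s), 0.5, 0.3, 0.04, seed = 7)
  expect_identical(c1, c2)
  c3 <- slice_to_contours(list(s), 0.5, 0.3, 0.04, seed = 8)
  expect_false(identical(c1, c3))
})

test_that("contour noise has the requested SD along the normal", {
  st <- slice_to_contours(list(sphere10()), 0.5, 0.3, 0.04, seed = 11)
  res <- unlist(lapply(st$slices, function(sl) {
    p <- sl$contours[[1]]$points
    sqrt(rowSums(p^2)) - sqrt(100 - sl$z^2)
  }))
  expect_gt(length(res), 4000)
  expect_lt(abs(stats::sd(res) - 0.04) / 0.04, 0.10)
  expect_lt(abs(mean(res)), 0.005)
})

test_that("slice spacing beyond the object extent is an error", {
  expect_error(slice_to_contours(list(sphere10()), spacing = 50,
                                 point_spacing = 0.3, noise_sd = 0),
               "no slices produced")
})

test_that("contour stacks round-trip through JSON at full precision", {
  st <- slice_to_contours(list(sphere_surface(5, spacing = 1,
                                              label = "glenoid_bone")),
                          1, 0.6, 0.04, seed = 3, subject = "s1",
                          session = "post", laterality = "left")
  f <- withr::local_tempfile(fileext = ".json")
  write_contour_stack(st, f)
  back <- read_contour_stack(f)
  expect_equal(back$subject, "s1")
  expect_equal(back$session, "post")
  expect_equal(back$laterality, "left")
  expect_equal(back$slice_spacing, st$slice_spacing)
  expect_equal(length(back$slices), length(st$slices))
  for (k in seq_along(st$slices)) {
    expect_equal(back$slices[[k]]$z, st$slices[[k]]$z, tolerance = 1e-12)
    expect_equal(back$slices[[k]]$contours[[1]]$points,
                 st$slices[[k]]$contours[[1]]$points, tolerance = 1e-12)
  }
})

test_that("slices are sorted by z regardless of file order", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  mk <- function(z) list(z = z, contours = list(
    list(label = "humeral_bone", points = sq, closed = TRUE)))
  st <- contour_stack(list(mk(1), mk(0), mk(0.5)), slice_spacing = 0.5)
  expect_equal(vapply(st$slices, function(s) s$z, 0), c(0, 0.5, 1))
})

test_that("stack validation rejects bad labels, spacing, and degenerate contours", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  mk <- function(z, label = "humeral_bone", pts = sq) {
    list(z = z, contours = list(list(label = label, points = pts,
                                     closed = TRUE)))
  }
  err <- expect_error(contour_stack(list(mk(0, label = "femur"))),
                      "femur")
  expect_match(conditionMessage(err), "glenoid_cartilage")
  expect_error(contour_stack(list(mk(0), mk(0.5), mk(1.2)),
                             slice_spacing = 0.5), "spacing")
  expect_error(contour_stack(list(mk(0, pts = sq[c(1, 1, 2, 3), ]))),
               "duplicate")
  expect_error(contour_stack(list(mk(0, pts = sq[1:2, ]))), "fewer than")
})

test_that("plain triangle meshes can be sliced without a parametrization", {
  s <- sphere_surface(8, spacing = 0.4, label = "humeral_bone")
  attr(s, "radial") <- NULL
  st <- slice_to_contours(list(s), 1, 0.4, 0, seed = 1)
  expect_gt(length(st$slices), 12)
  mid <- st$slices[[round(length(st$slices) / 2)]]
  r_obs <- sqrt(rowSums(mid$contours[[1]]$points^2))
  r_true <- sqrt(64 - mid$z^2)
  # accuracy limited by the mesh chord error, not the slicer
  expect_lt(max(abs(r_obs - r_true)), 0.01)
})
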