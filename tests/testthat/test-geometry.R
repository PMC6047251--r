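test_that("a noiseless sliced sphere reconstructs to the analytic sphere", {
  m <- reconstruct_surface(sphere10_stack(), "humeral_bone")
  d <- abs(sqrt(rowSums(m$vertices^2)) - 10)
  expect_lt(max(d), 0.3)
  expect_lt(abs(mesh_area(m) - 4 * pi * 100) / (4 * pi * 100), 0.03)
  expect_gt(mesh_volume(m), 0)                 # outward orientation
  expect_length(cartstrain:::boundary_edges(m), 0)  # watertight
})

test_that("two parallel squares loft to a prism shell", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)) * 4
  mk <- function(z) list(z = z, contours = list(
    list(label = "humeral_bone", points = sq, closed = TRUE)))
  st <- contour_stack(list(mk(0), mk(1)), slice_spacing = 1)
  m <- reconstruct_surface(st, "humeral_bone")
  expect_gte(nrow(m$vertices), 8)
  expect_equal(range(m$vertices[, 3]), c(0, 1))
  expect_gt(mesh_volume(m), 0)
})

test_that("phantom glenoid bone reconstructs onto the generating sphere patch", {
  m <- glenoid_bone_mesh()
  gc <- c(4, 0, 0)  # generator's center of curvature (defaults)
  d <- abs(sqrt(rowSums(sweep(m$vertices, 2, gc)^2)) - 30)
  expect_lt(max(d), 0.3)
  expect_gte(nrow(m$vertices), 3000)
})

test_that("reconstruction validates its inputs", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  mk <- function(z, pts = sq) list(z = z, contours = list(
    list(label = "humeral_bone", points = pts, closed = TRUE)))
  one <- contour_stack(list(mk(0)), slice_spacing = 1)
  expect_error(reconstruct_surface(one, "humeral_bone"), "insufficient")
  expect_error(reconstruct_surface(one, "glenoid_bone"), "insufficient")
  far <- contour_stack(list(mk(0), mk(1, pts = sq + 50)), slice_spacing = 1)
  err <- expect_error(reconstruct_surface(far, "humeral_bone"),
                      "non-overlapping")
  expect_match(conditionMessage(err), "z = 0")
})

test_that("reconstruction error decreases with finer sampling", {
  s <- sphere10()
  err_at <- function(spacing, pts) {
    st <- slice_to_contours(list(s), spacing, pts, 0, seed = 1)
    m <- reconstruct_surface(st, "humeral_bone")
    mean(abs(sqrt(rowSums(m$vertices^2)) - 10))
  }
  coarse <- err_at(1.0, 0.6)
  fine <- err_at(0.5, 0.3)
  expect_lt(fine, coarse)
})

test_that("reconstruction commutes with in-plane rigid motions", {
  st <- sphere10_stack()
  ang <- 0.5
  R <- rotation_about_axis(c(0, 0, 1), ang)
  tt <- rigid_transform(R, c(3, -2, 0))
  move_stack <- function(stack) {
    stack$slices <- lapply(stack$slices, function(sl) {
      sl$contours <- lapply(sl$contours, function(ct) {
        ct$points <- sweep(ct$points %*% t(R[1:2, 1:2]), 2, c(3, -2), "+")
        ct
      })
      sl
    })
    stack
  }
  m1 <- apply_transform(reconstruct_surface(st, "humeral_bone"), tt)
  m2 <- reconstruct_surface(move_stack(st), "humeral_bone")
  expect_lt(max(abs(m1$vertices - m2$vertices)), 1e-6)
})

test_that("round trip: noiseless slicing then reconstruction stays on the source surface", {
  cart <- reconstruct_surface(glenoid_stack0(), "glenoid_cartilage")
  # radial residual against the analytic cartilage surface rho = Rg - t
  spec <- phantom_spec(surfaces = c("glenoid_bone", "glenoid_cartilage"))
  tr <- phantom_truth_at(spec, cart$vertices, "glenoid")
  rho <- sqrt(rowSums(sweep(cart$vertices, 2, c(4, 0, 0))^2))
  resid <- abs(rho - (30 - tr$t_pre))[tr$inside]
  expect_gt(sum(tr$inside), 2000)
  expect_lt(max(resid), 0.3)  # < in-plane point spacing
})

test_that("meshes round-trip through PLY, OBJ and STL", {
  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(0, 0, 1)),
                      rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  for (ext in c("ply", "obj", "stl")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(tet, f)
    back <- read_mesh(f)
    # same vertex set (STL reorders via dedup)
    d <- RANN::nn2(back$vertices, tet$vertices, k = 1)$nn.dists
    expect_lt(max(d), 1e-6)
    expect_equal(nrow(back$vertices), 4)
    expect_equal(abs(mesh_volume(back)), abs(mesh_volume(tet)),
                 tolerance = 1e-9)
  }
  expect_error(write_mesh(tet, tempfile(fileext = ".vtk")), "ply, obj, stl")
  expect_error(read_mesh(tempfile(fileext = ".xyz")), "ply, obj, stl")
})

test_that("PLY preserves per-vertex scalar channels in ascii and binary", {
  m <- sphere_surface(3, spacing = 1)
  th <- seq_len(nrow(m$vertices)) * 0.01
  for (bin in c(FALSE, TRUE)) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_mesh(m, f, scalars = list(thickness_mm = th), binary = bin)
    back <- read_mesh(f)
    expect_equal(attr(back, "scalars")$thickness_mm, th, tolerance = 1e-7)
    expect_equal(back$vertices, m$vertices, tolerance = 1e-7)
    expect_equal(back$faces, m$faces)
  }
})

test_that("binary STL round-trips vertex positions within merge tolerance", {
  m <- sphere_surface(3, spacing = 1.2)
  f <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, f, binary = TRUE)
  back <- read_mesh(f)
  d <- RANN::nn2(back$vertices, m$vertices, k = 1)$nn.dists
  expect_lt(max(d), 1e-5)  # float32 storage
})
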