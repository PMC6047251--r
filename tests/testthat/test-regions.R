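# shared noiseless glenoid footprint + frame for the grid tests
glenoid_setup <- function() {
  cached("glenoid_setup", {
    bone <- glenoid_bone_mesh()
    cart <- reconstruct_surface(glenoid_stack0(), "glenoid_cartilage")
    map <- compute_thickness_map(bone, cart)
    frame <- fit_anatomical_frame(bone, "right")
    list(bone = bone, cart = cart, map = map, frame = frame,
         footprint = bone$vertices[map$mask, , drop = FALSE])
  })
}

humeral_setup <- function() {
  cached("humeral_setup", {
    ph <- humeral_phantom()
    map <- compute_thickness_map(ph$pre$humeral_bone,
                                 ph$pre$humeral_cartilage)
    frame <- fit_anatomical_frame(glenoid_phantom()$pre$glenoid_bone,
                                  "right")
    list(map = map, frame = frame,
         footprint = ph$pre$humeral_bone$vertices[map$mask, , drop = FALSE])
  })
}

test_that("the glenoid grid has exactly 9 regions of 2 mm radius", {
  s <- glenoid_setup()
  grid <- build_region_grid(s$footprint, s$frame, "glenoid")
  expect_equal(nrow(grid), 9L)
  expect_true(all(grid$radius == 2))
  counts <- table(grid$ap_label)
  expect_setequal(names(counts), c("anterior", "central", "posterior"))
  expect_true(all(counts == 3))
  # anterior regions really lie anterior (canonical frame: +y)
  ant <- grid$center_y[grid$ap_label == "anterior"]
  post <- grid$center_y[grid$ap_label == "posterior"]
  expect_true(all(ant > 0) && all(post < 0))
  sup <- grid$center_z[grid$si_label == "superior"]
  inf <- grid$center_z[grid$si_label == "inferior"]
  expect_true(all(sup > 0) && all(inf < 0))
  # centers lie on footprint vertices
  d <- RANN::nn2(s$footprint,
                 as.matrix(grid[, c("center_x", "center_y", "center_z")]),
                 k = 1)$nn.dists
  expect_lt(max(d), 1e-9)
})

test_that("the humeral grid has exactly 18 regions in two bands", {
  s <- humeral_setup()
  grid <- build_region_grid(s$footprint, s$frame, "humeral")
  expect_equal(nrow(grid), 18L)
  expect_true(all(table(grid$band) == 9))
  expect_setequal(names(table(grid$band)), c("inferior", "superior"))
  sup <- grid$center_z[grid$band == "superior"]
  inf <- grid$center_z[grid$band == "inferior"]
  expect_gt(min(sup), max(inf) - 1e-9)
})

test_that("region centers transform rigidly with the inputs", {
  s <- glenoid_setup()
  grid <- build_region_grid(s$footprint, s$frame, "glenoid")
  tt <- rigid_transform(rotation_about_axis(c(1, -2, 2), 0.5), c(4, 1, -2))
  moved_frame <- s$frame
  moved_frame$origin <- as.numeric(transform_points(rbind(s$frame$origin),
                                                    tt))
  for (a in c("axis_ap", "axis_si", "axis_ml")) {
    moved_frame[[a]] <- as.numeric(tt$rotation %*% s$frame[[a]])
  }
  grid2 <- build_region_grid(transform_points(s$footprint, tt),
                             moved_frame, "glenoid")
  c1 <- transform_points(as.matrix(grid[, c("center_x", "center_y",
                                            "center_z")]), tt)
  c2 <- as.matrix(grid2[, c("center_x", "center_y", "center_z")])
  expect_lt(max(abs(c1 - c2)), 1e-6)
})

test_that("region means average the thickness map correctly", {
  s <- glenoid_setup()
  grid <- build_region_grid(s$footprint, s$frame, "glenoid")
  # uniform map: every region mean is exactly the constant
  umap <- s$map
  umap$thickness[umap$mask] <- 1.0
  rm <- region_mean_thickness(umap, grid)
  expect_equal(rm$mean_thickness, rep(1, 9))
  expect_true(all(rm$n_vertices > 20))

  # step map: region mean is the vertex-weighted average of the two sides
  co <- sweep(s$bone$vertices, 2, colMeans(s$footprint))
  ap <- as.numeric(co %*% s$frame$axis_ap)
  ctr <- as.numeric(grid[5, c("center_x", "center_y", "center_z")])
  ap0 <- sum((ctr - colMeans(s$footprint)) * s$frame$axis_ap)
  smap <- s$map
  smap$thickness[smap$mask] <- ifelse(ap[smap$mask] >= ap0, 1.4, 1.0)
  rs <- region_mean_thickness(smap, grid)
  in_reg <- s$map$mask &
    rowSums(sweep(s$bone$vertices, 2, ctr)^2) <= 4
  w <- mean(ap[in_reg] >= ap0)
  expect_equal(rs$mean_thickness[5], 1.4 * w + 1.0 * (1 - w),
               tolerance = 1e-12)
})

test_that("central glenoid region recovers the 1.2 mm center thickness", {
  s <- glenoid_setup()
  grid <- build_region_grid(s$footprint, s$frame, "glenoid")
  rm <- region_mean_thickness(s$map, grid)
  central <- rm$mean_thickness[grid$ap_label == "central" &
                                 grid$si_label == "central"]
  expect_lt(abs(central - 1.2), 0.08)
})

test_that("an explicit layout table overrides the default placement", {
  s <- glenoid_setup()
  layout <- data.frame(ap_q = c(0.5, 0.9), si_q = c(0.5, 0.1),
                       ap_label = c("central", "anterior"),
                       si_label = c("central", "inferior"))
  attr(layout, "custom") <- TRUE
  grid <- build_region_grid(s$footprint, s$frame, "glenoid",
                            layout = layout)
  expect_equal(nrow(grid), 2L)
  expect_gt(grid$center_y[2], grid$center_y[1])
  expect_lt(grid$center_z[2], grid$center_z[1])
})

test_that("empty footprints and empty regions raise errors", {
  s <- glenoid_setup()
  expect_error(build_region_grid(s$footprint[0, , drop = FALSE], s$frame,
                                 "glenoid"), "empty")
  grid <- build_region_grid(s$footprint, s$frame, "glenoid")
  far_map <- s$map
  far_map$bone$vertices <- far_map$bone$vertices + 1000
  expect_error(region_mean_thickness(far_map, grid), "empty")
})

test_that("the anatomical frame requires anisotropy and a non-empty mesh", {
  s <- glenoid_setup()
  round_spec <- phantom_spec(glenoid_extent = c(si = 30, ap = 29.8),
                             surfaces = c("glenoid_bone"),
                             mesh_spacing = 1.2)
  # nearly circular footprint: principal axes are ambiguous
  ph <- generate_phantom(round_spec)
  expect_error(fit_anatomical_frame(ph$pre$glenoid_bone, "right"),
               "ambiguous")
  empty <- s$bone
  empty$vertices <- empty$vertices[0, , drop = FALSE]
  expect_error(fit_anatomical_frame(empty, "right"), "empty")
})
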