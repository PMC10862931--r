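test_that("centroid of a centred sphere is the grid centre", {
  ph <- sphere_fine()
  cen <- mask_centroid(ph$sac)
  expect_lt(max(abs(cen - ph$truth$centre)), max(ph$sac$spacing) / 2)
})

test_that("centroid matches single-voxel and brute-force cases", {
  a <- array(0L, c(8, 9, 5))
  a[3, 7, 2] <- 1L
  m <- mask_volume(a, c(0.5, 0.5, 2.5), origin = c(10, 0, -5))
  expect_equal(mask_centroid(m),
               c(10 + 2 * 0.5, 0 + 6 * 0.5, -5 + 1 * 2.5))

  # asymmetric two-blob mask vs an explicit voxel-list mean
  set.seed(4)
  b <- array(0L, c(12, 12, 8))
  b[2:4, 2:3, 1:2] <- 1L
  b[9:11, 8:11, 6:8] <- 1L
  mb <- mask_volume(b, c(1.5, 1, 2))
  idx <- which(b == 1L, arr.ind = TRUE)
  oracle <- colMeans((idx - 1) %*% diag(c(1.5, 1, 2)))
  expect_equal(unname(mask_centroid(mb)), unname(oracle))

  expect_error(mask_centroid(mask_volume(array(0L, c(3, 3, 3)), c(1, 1, 1))),
               "empty")
})

test_that("principal axes recover known ellipsoid diameters", {
  ax <- principal_axes(ellipsoid_coarse()$sac)
  tol <- 2 * max(c(1, 1, 2.5))  # 2 voxels at the coarsest spacing
  expect_equal(unname(ax$lengths), c(120, 90, 60), tolerance = tol / 60)
  expect_lt(abs(ax$lengths[["major"]] - 120), tol)
  expect_lt(abs(ax$lengths[["intermediate"]] - 90), tol)
  expect_lt(abs(ax$lengths[["minor"]] - 60), tol)
  expect_gte(ax$aspect_major_minor, ax$aspect_major_intermediate)
  expect_true(all(abs(crossprod(ax$directions) - diag(3)) < 1e-8))
})

test_that("principal-axis lengths are invariant under rotation", {
  a0 <- principal_axes(ellipsoid_coarse()$sac)$lengths
  a1 <- principal_axes(ellipsoid_coarse(rot_z(30))$sac)$lengths
  expect_lt(max(abs(a0 - a1)), 2 * 2.5)
})

test_that("a sphere has three equal axes", {
  ax <- principal_axes(sphere_fine()$sac)
  expect_lt(diff(range(ax$lengths)), 2 * 2.5)
  expect_equal(ax$aspect_major_minor, 1, tolerance = 0.07)
})

test_that("degenerate masks are rejected for principal axes", {
  a <- array(0L, c(10, 4, 4)); a[2:9, 2, 2] <- 1L  # collinear
  expect_error(principal_axes(mask_volume(a, c(1, 1, 1))), "collinear")
})

test_that("axial slabs split foreground slices with extras to the bottom", {
  m40 <- box_mask(c(10, 10, 44), c(1, 1, 1), c(2, 9), c(2, 9), c(3, 42))
  s40 <- partition_axial_slabs(m40)
  expect_equal(attr(s40, "slab_sizes"), rep(10L, 4))

  m10 <- box_mask(c(10, 10, 14), c(1, 1, 1), c(2, 9), c(2, 9), c(3, 12))
  s10 <- partition_axial_slabs(m10)
  expect_equal(attr(s10, "slab_sizes"), c(3L, 3L, 2L, 2L))
  # PQ1 is the lowermost slab
  expect_equal(unique(as.vector(s10$data[2:9, 2:9, 3:5])), 1L)
  expect_equal(unique(as.vector(s10$data[2:9, 2:9, 11:12])), 4L)

  # partition property: labels tile the foreground exactly
  expect_identical(s10$data != 0L, m10$data != 0L)
  expect_equal(sum(s10$data > 0), sum(m10$data))

  expect_error(partition_axial_slabs(
    box_mask(c(5, 5, 5), c(1, 1, 1), c(1, 5), c(1, 5), c(2, 3))), "slices")
})

test_that("slab labels mirror under a z-flip (PQ1 <-> PQ4)", {
  ph <- ellipsoid_coarse()
  s <- partition_axial_slabs(ph$sac)
  flipped <- mask_volume(ph$sac$data[, , dim(ph$sac$data)[3]:1],
                         ph$sac$spacing)
  sf <- partition_axial_slabs(flipped)
  relabelled <- sf$data[, , dim(sf$data)[3]:1]
  relabelled[relabelled > 0] <- 5L - relabelled[relabelled > 0]
  expect_identical(relabelled, s$data)
})

test_that("shells of a solid sphere match analytic band volumes", {
  R <- 40; h <- 2
  m <- solid_sphere_mask(R, h)
  sh <- partition_shells(m)
  counts <- vapply(1:4, function(k) sum(sh$data == k), numeric(1))
  # SH1 outermost .. SH4 innermost; boundaries at depths D/4, D/2, 3D/4
  D <- attr(sh, "max_depth_mm")
  r_edges <- R - D / 4 * (0:4)
  analytic <- 4 / 3 * pi * (r_edges[1:4]^3 - pmax(r_edges[2:5], 0)^3)
  expect_equal(counts * h^3, analytic, tolerance = 0.05)
  # partition property, exact
  expect_identical(sh$data != 0L, m$data != 0L)
  expect_error(partition_shells(mask_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})

test_that("shell volumes converge under grid refinement", {
  v <- lapply(c(2, 1), function(h) {
    sh <- partition_shells(solid_sphere_mask(40, h))
    vapply(1:4, function(k) sum(sh$data == k), numeric(1)) * h^3
  })
  expect_lt(max(abs(v[[2]] - v[[1]]) / v[[1]]), 0.02)
})

test_that("the exterior distance respects anisotropic spacing", {
  a <- array(0L, c(9, 9, 9)); a[5, 5, 5] <- 1L
  d <- exterior_distance(mask_volume(a, c(0.5, 0.5, 2.5)))
  expect_equal(d[5, 5, 5], 0.5)  # nearest background is one in-plane step
  expect_equal(d[5, 5, 4], 0)
  b <- array(1L, c(9, 9, 9))
  b[1, , ] <- 0L
  db <- exterior_distance(mask_volume(b, c(0.5, 0.5, 2.5)))
  expect_equal(db[9, 5, 5], 8 * 0.5)
})
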