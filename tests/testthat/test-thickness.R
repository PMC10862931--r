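test_that("the default sweep produces 64,800 rays", {
  ph <- sphere_fine()
  fld <- fixture("sphere_field", function()
    measure_thickness_field(ph$eat, ph$sac))
  expect_equal(dim(fld$values), c(360, 180))
  expect_equal(length(fld$values), 64800)
})

test_that("a constant 6 mm spherical shell is recovered within a voxel diagonal", {
  ph <- sphere_fine()
  fld <- fixture("sphere_field", function()
    measure_thickness_field(ph$eat, ph$sac))
  vox_diag <- sqrt(sum(c(0.5, 0.5, 2.5)^2))
  expect_true(all(abs(fld$values - 6) <= vox_diag))
  expect_lt(abs(mean(fld$values) - 6), max(ph$sac$spacing))
})

test_that("an empty EAT mask gives an all-zero field", {
  ph <- sphere_fine()
  none <- mask_volume(array(0L, dim(ph$sac$data)), ph$sac$spacing)
  fld <- measure_thickness_field(none, ph$sac)
  expect_true(all(fld$values == 0))
})

test_that("EAT voxels outside the sac are clipped with a warning", {
  sac <- box_mask(c(20, 20, 10), c(1, 1, 1), c(5, 15), c(5, 15), c(3, 8))
  eat <- box_mask(c(20, 20, 10), c(1, 1, 1), c(5, 18), c(5, 15), c(3, 8))
  expect_warning(measure_thickness_field(eat, sac), "clipped")
})

test_that("halving the ray sampling step barely changes the field", {
  ph <- sphere_fine()
  f1 <- fixture("sphere_field", function()
    measure_thickness_field(ph$eat, ph$sac))
  f2 <- measure_thickness_field(ph$eat, ph$sac, ray_step = f1$ray_step / 2)
  expect_lt(max(abs(f2$values - f1$values)), sqrt(sum(c(0.5, 0.5, 2.5)^2)))
})

test_that("thickening the shell strictly increases the field mean", {
  ph6 <- sphere_fine()
  ph8 <- make_shell_phantom(phantom_spec(
    shape = c(176, 176, 40), spacing = c(0.5, 0.5, 2.5),
    semi_axes = c(40, 40, 40), thickness = 8, seed = 7))
  f6 <- fixture("sphere_field", function()
    measure_thickness_field(ph6$eat, ph6$sac))
  f8 <- measure_thickness_field(ph8$eat, ph8$sac)
  expect_gt(mean(f8$values), mean(f6$values))
})

test_that("rotating the phantom moves the field mean by under 2 percent", {
  # ellipsoid with an off-axis rotation: voxelisation changes, geometry not
  f0 <- measure_thickness_field(ellipsoid_coarse()$eat,
                                ellipsoid_coarse()$sac)
  phr <- make_shell_phantom(phantom_spec(
    shape = c(134, 134, 56), spacing = c(1, 1, 2.5),
    semi_axes = c(60, 45, 30), thickness = 5, seed = 3,
    rotation = rot_z(30)))
  fr <- measure_thickness_field(phr$eat, phr$sac)
  expect_lt(abs(mean(fr$values) - mean(f0$values)) / mean(f0$values), 0.02)
})

test_that("summaries follow the fixed-bin and zero-variance conventions", {
  const_field <- structure(list(values = matrix(5, 360, 180),
                                origin = c(0, 0, 0), step_deg = 1,
                                ray_step = 0.125),
                           class = "thickness_field")
  s <- summarize_thickness(const_field)
  expect_equal(s$mean, 5); expect_equal(s$max, 5); expect_equal(s$median, 5)
  expect_equal(s$std, 0)
  expect_equal(s$skewness, 0)   # zero-variance convention
  expect_equal(s$kurtosis, 0)

  half <- matrix(c(rep(0, 32400), rep(10, 32400)), 360, 180)
  s2 <- summarize_thickness(structure(list(values = half, origin = c(0, 0, 0),
                                           step_deg = 1, ray_step = 0.125),
                                      class = "thickness_field"))
  expect_equal(unname(s2$bin_fractions), c(0.5, 0.5, 0, 0))
  expect_equal(sum(s2$bin_counts), 64800)

  over <- matrix(c(rep(35, 100), rep(2, 64700)), 360, 180)
  s3 <- summarize_thickness(structure(list(values = over, origin = c(0, 0, 0),
                                           step_deg = 1, ray_step = 0.125),
                                      class = "thickness_field"))
  expect_equal(unname(s3$bin_counts[["TB_24_32"]]), 100)
  expect_equal(s3$n_over_32, 100)
})

test_that("summary moments match an independent one-pass oracle", {
  set.seed(8)
  x <- rlnorm(64800, meanlog = 1.5, sdlog = 0.6)
  fld <- structure(list(values = matrix(x, 360, 180), origin = c(0, 0, 0),
                        step_deg = 1, ray_step = 0.125),
                   class = "thickness_field")
  s <- summarize_thickness(fld)
  n <- length(x); mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  expect_equal(s$mean, mu)
  expect_equal(s$std, sqrt(m2))
  expect_equal(s$skewness, m3 / m2^1.5)
  expect_equal(s$kurtosis, m4 / m2^2 - 3)
  expect_equal(s$median, median(x))
  expect_equal(sum(s$bin_counts), n)
})
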