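test_that("line integrals match analytic chord lengths", {
  mu <- phantom_materials()[["water"]]
  g <- scan_geometry(detector_spec(65, 49, 2), c(0, 90, 180, 270))
  v <- make_cube_phantom(30, 48, 1.5)
  p0 <- drr_oracle(v, g, 0)
  # central ray crosses the full 30 mm water slab
  expect_equal(p0$pixels[33, 25], 30 * mu, tolerance = 0.01 * 30 * mu)
  # empty volume -> all-zero projection
  empty <- voxel_volume(array(0, c(16, 16, 16)), 3)
  expect_equal(max(abs(drr_oracle(empty, g, 0)$pixels)), 0)
  expect_equal(max(abs(drr_fast(empty, g)$images)), 0)
  # opposing views are horizontal mirrors of each other
  p180 <- drr_oracle(v, g, 180)
  expect_max_abs(p180$pixels[rev(seq_len(65)), ] - p0$pixels,
                 0.01 * max(p0$pixels))
})

test_that("oracle and fast engines agree on phantom/angle combinations", {
  g <- geom_tiny()
  combos <- list(list(vol = cube_tiny(), angle_i = 75),
                 list(vol = cube_tiny(), angle_i = 20),
                 list(vol = pelvis_tiny(), angle_i = 75),
                 list(vol = pelvis_tiny(), angle_i = 130))
  for (cb in combos) {
    ang <- g$angles_deg[cb$angle_i]
    sub <- scan_geometry(g$detector, ang,
                         sad_mm = g$source_axis_distance_mm,
                         sdd_mm = g$source_detector_distance_mm)
    po <- drr_oracle(cb$vol, sub, ang)
    pf <- drr_fast(cb$vol, sub)
    expect_max_abs(pf$images[, , 1] - po$pixels, 1e-3 * max(po$pixels))
    expect_gte(correlation_coefficient(po$pixels, pf$images[, , 1]), 0.99)
  }
})

test_that("projection is linear and monotone in the attenuation", {
  g <- geom_tiny()
  sub <- select_arc(g, 0, 3)
  v <- cube_tiny()
  p1 <- drr_fast(v, sub)
  v2 <- voxel_volume(2 * v$values, v$voxel_mm, v$origin_mm)
  expect_equal(drr_fast(v2, sub)$images, 2 * p1$images, tolerance = 1e-12)
  # adding attenuation anywhere never decreases any line integral
  extra <- v$values
  extra[10:15, 10:15, 30:35] <- extra[10:15, 10:15, 30:35] + 0.05
  p3 <- drr_fast(voxel_volume(extra, v$voxel_mm, v$origin_mm), sub)
  expect_true(all(p3$images >= p1$images - 1e-12))
})

test_that("magnification at the isocenter plane is SDD/SAD", {
  g <- scan_geometry(detector_spec(65, 49, 2), 0)
  a <- array(0, c(33, 33, 33))
  a[24, 20, 17] <- 1          # point at (7, 3, 0) mm on the isocenter plane
  pt <- voxel_volume(a, 1)
  img <- drr_fast(pt, g)$images[, , 1]
  cu <- sum(row(img) * img) / sum(img)
  cv <- sum(col(img) * img) / sum(img)
  mag <- 1500 / 1000
  expect_equal((cu - 33) * 2, 7 * mag, tolerance = 2)   # +/- 1 pixel (2 mm)
  expect_equal((cv - 25) * 2, 3 * mag, tolerance = 2)
})

test_that("intensity conversion and round trip", {
  g <- scan_geometry(detector_spec(8, 6, 1), 0)
  q <- matrix(seq(0, log(2), length.out = 48), 8, 6)
  p <- projection_image(q, 0, g)
  it <- to_intensity(p, I0 = 1)
  expect_equal(it$domain, "intensity")
  expect_equal(it$pixels[1, 1], 1)              # zero line integral -> I0
  expect_equal(it$pixels[8, 6], 0.5)            # ln 2 -> 0.5
  back <- to_line_integral(it, I0 = 1)
  expect_equal(back$pixels, q, tolerance = 1e-15)
  expect_error(to_intensity(it), "line-integral")
  expect_error(to_intensity(p, I0 = 0), "I0")
})

test_that("projection-set I/O and arc subsetting round trip", {
  g <- geom_tiny()
  ps <- drr_fast(cube_tiny(), select_arc(g, 0, 5))
  dir <- withr::local_tempdir()
  write_projection_set(ps, dir)
  r <- read_projection_set(dir)
  expect_equal(r$geom$angles_deg, ps$geom$angles_deg)
  expect_equal(r$domain, "line_integral")
  expect_max_abs(r$images - ps$images, 1e-6 * max(ps$images))
  sub <- subset_arc(ps, 0, 2)
  expect_equal(sub$geom$angles_deg,
               ps$geom$angles_deg[circular_distance(ps$geom$angles_deg, 0) <= 1 + 1e-9])
  expect_error(subset_arc(ps, 90, 2), "no views")
})
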