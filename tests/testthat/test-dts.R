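test_that("preprocessing: log conversion, DC kill, linearity", {
  g <- scan_geometry(detector_spec(64, 48, 2), 0)
  flood <- projection_image(matrix(1, 64, 48), 0, g, domain = "intensity")
  f <- preprocess_projection(flood, I0 = 1)
  expect_max_abs(f$pixels, 1e-12)
  # constant row: the ramp filter removes DC essentially exactly
  expect_max_abs(ramp_filter_rows(matrix(3.7, 64, 48), 1), 1e-6 * 3.7)
  # full preprocessing additionally cosine-weights the rows, which leaves a
  # small non-constant residual; it stays far below the image scale
  const <- projection_image(matrix(3.7, 64, 48), 0, g, domain = "line_integral")
  fc <- preprocess_projection(const)
  expect_max_abs(fc$pixels, 1e-3 * 3.7)
  # linearity for line-integral inputs
  q <- matrix(abs(sin(seq_len(64 * 48) / 7)), 64, 48)
  p <- projection_image(q, 0, g)
  f1 <- preprocess_projection(p)
  f2 <- preprocess_projection(projection_image(2.5 * q, 0, g))
  expect_max_abs(f2$pixels - 2.5 * f1$pixels, 1e-12 * max(abs(f1$pixels)))
  # intensity domain input validation
  bad <- projection_image(matrix(0.5, 64, 48), 0, g, domain = "intensity")
  bad$pixels[5, 5] <- 0
  expect_error(preprocess_projection(bad), "1 non-positive")
})

test_that("reconstruction contracts: empty input, zeros, mismatch", {
  g <- select_arc(geom_tiny(), 0, 10)
  spec <- dts_volume_spec("coronal", 1, 2, c(32, 32), 8)
  zero <- projection_set(array(0, c(64, 48, length(g$angles_deg))), g)
  out <- reconstruct_dts(zero, spec)
  expect_equal(max(abs(out$values)), 0)
  expect_equal(dim(out$values), c(32L, 32L, 8L))
  # detector mismatch
  g2 <- scan_geometry(detector_spec(32, 24, 4), g$angles_deg)
  expect_error(projection_set(array(0, c(64, 48, 3)), g2), "match")
  # sagittal spec fed a coronal arc warns about the orientation
  spec_sag <- dts_volume_spec("sagittal", 1, 2, c(32, 32), 8)
  expect_warning(reconstruct_dts(zero, spec_sag), "sagittal DTS from an arc")
})

test_that("reconstruction is linear in the projections", {
  g <- select_arc(geom_tiny(), 0, 10)
  n <- length(g$angles_deg)
  set.seed(7)
  a1 <- array(abs(rnorm(64 * 48 * n)), c(64, 48, n))
  a2 <- array(abs(rnorm(64 * 48 * n)), c(64, 48, n))
  spec <- dts_volume_spec("coronal", 1, 2, c(32, 32), 8)
  r1 <- reconstruct_dts(projection_set(a1, g), spec)
  r2 <- reconstruct_dts(projection_set(a2, g), spec)
  r12 <- reconstruct_dts(projection_set(a1 + a2, g), spec)
  scale <- max(abs(r12$values))
  expect_max_abs(r12$values - (r1$values + r2$values), 1e-6 * scale)
})

test_that("oracle and fast reconstruction engines agree", {
  ps <- drr_fast(pelvis_tiny(), select_arc(geom_tiny(), 0, 20))
  spec <- dts_volume_spec("coronal", 1, 2, c(48, 48), 12)
  rf <- reconstruct_dts(ps, spec, engine = "fast")
  ro <- reconstruct_dts(ps, spec, engine = "oracle")
  expect_gte(correlation_coefficient(ro$values, rf$values), 0.99)
  expect_max_abs(rf$values - ro$values, 1e-6 * max(abs(ro$values)))
})

test_that("coronal DTS localizes the cube in-plane to sub-voxel accuracy", {
  d40 <- memo("cube_dts_cor40", function()
    reconstruct_dts(subset_arc(cube_pset(), 0, 40), spec_cor_wide()))
  img <- focal_image(d40)
  # in-plane lengths on the focal plane within 0.5 mm of the true 50 mm
  for (o in c(-8, 0, 8)) {
    expect_equal(measure_edge_length(img, 1, o), 50, tolerance = 0.5)
    expect_equal(measure_edge_length(img, 2, o), 50, tolerance = 0.5)
  }
  # in-plane centroid of the (clamped) focal image within 0.5 mm of center
  pos <- pmax(img, 0)
  cu <- sum(row(img) * pos) / sum(pos)
  cv <- sum(col(img) * pos) / sum(pos)
  expect_equal((cu - (200 + 1) / 2) * 0.5, 0, tolerance = 0.5)
  expect_equal((cv - (160 + 1) / 2) * 0.5, 0, tolerance = 0.5)
})

test_that("wider arcs do not worsen the mean in-plane cube length error", {
  errs <- vapply(c(20, 80), function(arc) {
    d <- reconstruct_dts(subset_arc(cube_pset(), 0, arc), spec_cor_wide())
    img <- focal_image(d)
    m <- c(vapply(c(-8, 0, 8), function(o) measure_edge_length(img, 1, o), 1),
           vapply(c(-8, 0, 8), function(o) measure_edge_length(img, 2, o), 1))
    mean(abs(m - 50))
  }, numeric(1))
  expect_lte(errs[2], errs[1] + 0.05)
})

test_that("DTS of a shifted phantom shifts by the applied amount", {
  d0 <- memo("cube_dts_cor40", function()
    reconstruct_dts(subset_arc(cube_pset(), 0, 40), spec_cor_wide()))
  shifted <- shift_volume(cube_small(), c(3, 0, 0))
  ps <- project_arcs(shifted, geom_small(), 40, centers_deg = 0)
  d3 <- reconstruct_dts(subset_arc(ps, 0, 40), spec_cor_wide())
  r <- register_translation_2d(d0, d3, search_mm = 6)
  expect_equal(r$shift_mm[1], 3, tolerance = 0.5)
  expect_equal(r$shift_mm[2], 0, tolerance = 0.5)
})

test_that("half-fan stitching: identity, union, cross-fade midline", {
  v <- cube_tiny()
  same <- stitch_halffan(v, v, axis = 1, blend_mm = 10)
  expect_equal(same$values, v$values, tolerance = 1e-12)
  a <- voxel_volume(array(2, c(8, 8, 8)), 2)
  b <- voxel_volume(array(6, c(8, 8, 8)), 2)
  hard <- stitch_halffan(a, b, axis = 1, blend_mm = 0)
  xs <- (seq_len(8) - 4.5) * 2
  expect_equal(hard$values[xs < 0, 1, 1], rep(2, sum(xs < 0)))
  expect_equal(hard$values[xs > 0, 1, 1], rep(6, sum(xs > 0)))
  soft <- stitch_halffan(a, b, axis = 1, blend_mm = 18)
  mid <- approx(xs, soft$values[, 4, 4], xout = 0)$y
  expect_equal(mid, 4, tolerance = 1e-9)   # cross-fade weight 0.5 at midline
  expect_error(stitch_halffan(a, cube_tiny()), "share one grid")
})

test_that("focal_image and dts_slice respect the orientation layout", {
  g <- select_arc(geom_tiny(), 270, 10)
  ps <- drr_fast(pelvis_tiny(), g)
  spec <- dts_volume_spec("sagittal", 1, 2, c(40, 36), 10)
  d <- reconstruct_dts(ps, spec)
  expect_equal(dim(d$values), c(10L, 40L, 36L))  # stacked along LAT
  sl <- dts_slice(d, 5)
  expect_equal(dim(sl), c(40L, 36L))             # LNG x VRT plane
  fi <- focal_image(d, 4)
  expect_equal(dim(fi), dim(sl))
  expect_error(dts_slice(d, 11), "out of range")
})
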