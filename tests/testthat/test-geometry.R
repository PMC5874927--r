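test_that("full-fan geometry: spacing convention and angle grid", {
  g <- make_full_fan_geometry(20, 200, 375)
  expect_equal(g$angular_spacing_deg, 200 / 375)
  expect_equal(round(g$angular_spacing_deg, 2), 0.53)
  expect_length(g$angles_deg, 375)
  # bin-centered, decreasing (counterclockwise) grid
  expect_equal(g$angles_deg[1], 20 - 0.5 * 200 / 375)
  expect_lt(g$angles_deg[375], -179)
  expect_true(all(diff(g$angles_deg) < 0))

  g90 <- make_full_fan_geometry(0, 90, 90)
  expect_equal(g90$angular_spacing_deg, 1.0)
  expect_equal(utils::tail(g90$angles_deg, 1), -89.5)
  expect_equal(make_full_fan_geometry(0, 90, 90, direction = "cw")$angles_deg[90],
               89.5)

  g1 <- make_full_fan_geometry(0, 1, 1)
  expect_length(g1$angles_deg, 1)
  expect_equal(g1$angular_spacing_deg, 1.0)
  expect_equal(g1$angles_deg, -0.5)  # single view at the arc midpoint

  expect_error(make_full_fan_geometry(0, -10, 5), "range_deg")
  expect_error(make_full_fan_geometry(0, 10, 0), "positive count")
})

test_that("select_arc reproduces the protocol view counts and is idempotent", {
  g <- make_full_fan_geometry(20, 200, 375)
  a20 <- select_arc(g, 0, 20)
  expect_length(a20$angles_deg, 37)
  a40 <- select_arc(g, 0, 40)
  # brute-force enumeration of the closed circular window
  expect_length(a40$angles_deg, sum(circular_distance(g$angles_deg, 0) <= 20))
  expect_length(a40$angles_deg, 75)
  # wrap handling: 270 and -90 are the same center
  expect_equal(select_arc(g, 270, 40)$angles_deg,
               select_arc(g, -90, 40)$angles_deg)
  # superset window returns everything
  expect_equal(select_arc(g, 0, 720)$angles_deg, g$angles_deg)
  # idempotence
  twice <- select_arc(select_arc(g, 0, 40), 0, 40)
  expect_equal(twice$angles_deg, a40$angles_deg)
  expect_error(select_arc(g, 90, 2), "no angles within")
})

test_that("projection savings arithmetic", {
  expect_equal(projection_savings(75, 375), 80)
  expect_equal(projection_savings(375, 375), 0)
  expect_equal(projection_savings(0, 375), 100)
  expect_error(projection_savings(400, 375), "exceed")
  expect_error(projection_savings(10, 0), "n_full")
})

test_that("source_and_ray follows the gantry convention", {
  det <- detector_spec(65, 49, 2)  # odd grid: central pixel is exact
  g <- scan_geometry(det, c(0, 90, 180, 270, 360))
  r0 <- source_and_ray(g, 0, 33, 25)
  expect_equal(r0$direction, c(0, 0, -1))
  expect_equal(r0$origin, c(0, 0, 1000))
  r270 <- source_and_ray(g, 270, 33, 25)
  expect_equal(abs(r270$direction), c(1, 0, 0))
  # theta and theta + 360 give identical rays
  r360 <- source_and_ray(g, 360, 12, 40)
  r0b <- source_and_ray(g, 0, 12, 40)
  expect_equal(r360$origin, r0b$origin, tolerance = 1e-12)
  expect_equal(r360$direction, r0b$direction, tolerance = 1e-12)
  # central rays at theta and theta + 180 are anti-parallel
  r180 <- source_and_ray(g, 180, 33, 25)
  expect_equal(r180$direction, -r0$direction, tolerance = 1e-12)
  # corner pixel: unit norm, and the ray passes through the pixel center
  rc <- source_and_ray(g, 90, 1, 1)
  expect_equal(sum(rc$direction^2), 1)
  fr <- gantry_frame(g, 90)
  pc <- fr$det_center + (1 - 33) * 2 * fr$eu + (1 - 25) * 2 * fr$ev
  w <- pc - rc$origin
  cosang <- sum(w * rc$direction) / sqrt(sum(w^2))
  expect_equal(cosang, 1, tolerance = 1e-12)
  expect_error(source_and_ray(g, 0, 0, 1), "outside")
  expect_error(source_and_ray(g, 0, 66, 1), "outside")
})

test_that("geometry config round-trips through JSON", {
  cfg <- list(sad_mm = 1000, sdd_mm = 1500,
              detector = list(nu = 64, nv = 48, pixel_mm = 3),
              scan = list(start_deg = 20, range_deg = 200, n_projections = 75),
              arcs = list(list(center_deg = 0, arc_deg = 40),
                          list(center_deg = 270, arc_deg = 40)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  g <- read_geometry_config(path)
  expect_s3_class(g, "scan_geometry")
  expect_length(g$angles_deg, 75)
  expect_equal(g$detector$pixel_mm, 3)
  expect_equal(nrow(attr(g, "arcs")), 2)
})

test_that("scan_geometry validates its invariants", {
  det <- detector_spec(8, 8, 1)
  expect_error(scan_geometry(det, c(0, 1, 0.5)), "monotone")
  expect_error(scan_geometry(det, 0, sad_mm = 2000, sdd_mm = 1500), "sdd_mm")
  expect_error(detector_spec(8, 8, -1), "pixel")
})
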