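make_blob_image <- function(n = 96, px = 0.5, cx = 0, cy = 0) {
  x <- (seq_len(n) - (n + 1) / 2) * px
  m <- outer(x, x, function(a, b)
    exp(-((a - cx)^2 + (b - cy)^2) / 40) + 0.4 * exp(-((a - cx - 8)^2 + (b - cy + 5)^2) / 12))
  attr(m, "pixel_mm") <- c(px, px)
  m
}

test_that("self-registration is exact and integer shifts are recovered exactly", {
  img <- make_blob_image()
  r <- register_translation_2d(img, img, search_mm = 5)
  expect_equal(r$shift_mm, c(0, 0))
  expect_equal(r$ncc_peak, 1.0)
  # moving = fixed translated by an integer pixel count: exact at the
  # integer NCC stage (content moved by +4 px in u, -3 px in v)
  shifted <- matrix(0, 96, 96)
  shifted[5:96, 1:93] <- img[1:92, 4:96]
  attr(shifted, "pixel_mm") <- c(0.5, 0.5)
  r2 <- register_translation_2d(img, shifted, search_mm = 5)
  # the integer NCC peak sits exactly at the known lag ...
  peak <- which(r2$ncc$values == max(r2$ncc$values), arr.ind = TRUE)
  expect_equal(r2$ncc$du[peak[1]], 4 * 0.5)
  expect_equal(r2$ncc$dv[peak[2]], -3 * 0.5)
  # ... and parabolic refinement stays within a small fraction of a pixel
  expect_equal(r2$shift_mm, c(4 * 0.5, -3 * 0.5), tolerance = 0.1)
})

test_that("registration antisymmetry and error handling", {
  a <- make_blob_image()
  b <- make_blob_image(cx = 1.7, cy = -2.3)
  rab <- register_translation_2d(a, b, search_mm = 6)
  rba <- register_translation_2d(b, a, search_mm = 6)
  expect_max_abs(rab$shift_mm + rba$shift_mm, 0.1)
  flat <- matrix(1, 32, 32); attr(flat, "pixel_mm") <- c(1, 1)
  expect_error(register_translation_2d(flat, flat), "no structure")
  expect_error(register_translation_2d(a, b, search_mm = 1000), "search radius")
})

test_that("two-session bookkeeping: LNG averaging and session errors", {
  s <- shift_result(lat_mm = 1, lng_coronal_mm = 2.9, lng_sagittal_mm = 3.1,
                    vrt_mm = -0.5)
  expect_equal(s$lng_mm, 3.0)
  a <- make_blob_image()
  flat <- matrix(0, 96, 96); attr(flat, "pixel_mm") <- c(0.5, 0.5)
  expect_error(two_session_registration(a, a, flat, flat),
               "sagittal registration session failed")
  expect_error(two_session_registration(flat, flat, a, a),
               "coronal registration session failed")
})

test_that("self-registration of reconstructed DTS is at the noise floor", {
  dts <- memo("pelvis_dts_reg", function() {
    ps <- project_arcs(pelvis_small(), geom_small(), 40)
    list(cor = reconstruct_dts(subset_arc(ps, 0, 40), spec_cor_reg()),
         sag = reconstruct_dts(subset_arc(ps, 270, 40), spec_sag_reg()))
  })
  r <- two_session_registration(dts$cor, dts$cor, dts$sag, dts$sag)
  expect_max_abs(c(r$lat_mm, r$lng_mm, r$vrt_mm), 0.1)
  expect_equal(unname(r$ncc_peak), c(1, 1))
})

test_that("known 3 mm shifts are recovered within 0.5 mm on the pelvis", {
  dts <- memo("pelvis_dts_reg", function() {
    ps <- project_arcs(pelvis_small(), geom_small(), 40)
    list(cor = reconstruct_dts(subset_arc(ps, 0, 40), spec_cor_reg()),
         sag = reconstruct_dts(subset_arc(ps, 270, 40), spec_sag_reg()))
  })
  shifted <- shift_volume(pelvis_small(), c(3, 3, 3))
  psr <- project_arcs(shifted, geom_small(), 40)
  rcor <- reconstruct_dts(subset_arc(psr, 0, 40), spec_cor_reg())
  rsag <- reconstruct_dts(subset_arc(psr, 270, 40), spec_sag_reg())
  r <- two_session_registration(dts$cor, rcor, dts$sag, rsag)
  expect_equal(r$lat_mm, 3, tolerance = 0.5)
  expect_equal(r$lng_mm, 3, tolerance = 0.5)
  expect_equal(r$vrt_mm, 3, tolerance = 0.5)
})
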