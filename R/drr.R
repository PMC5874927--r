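#' Digitally reconstructed radiograph: brute-force reference engine
#'
#' Computes one DRR by casting, for every detector pixel, the ray from the
#' source through the pixel center and summing trilinearly interpolated
#' attenuation at fixed steps along it (step <= min(voxel)/2, integral scaled
#' by the step length in mm). Pure-R per-ray loop: this is the slow, auditable
#' reference the vectorized engine is checked against.
#'
#' @param vol A [voxel_volume()].
#' @param geom A [scan_geometry()].
#' @param angle_deg Gantry angle (must be one of `geom$angles_deg` up to
#'   floating tolerance, or any angle if `strict = FALSE`).
#' @param step_mm Sampling step; default `min(voxel_mm) / 2`.
#' @param strict Require `angle_deg` to belong to the geometry.
#' @return A [projection_image()] in the line-integral domain.
#' @seealso [drr_fast()]
#' @export
drr_oracle <- function(vol, geom, angle_deg, step_mm = NULL, strict = TRUE) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(geom, "scan_geometry"))
  if (strict && min(abs(geom$angles_deg - angle_deg)) > 1e-9)
    stop("angle_deg is not one of the geometry's angles")
  if (is.null(step_mm)) step_mm <- min(vol$voxel_mm) / 2
  det <- geom$detector
  fr <- gantry_frame(geom, angle_deg)
  a <- vol$values; d <- dim(a)
  org <- vol$origin_mm; vox <- vol$voxel_mm
  lo <- org - vox / 2
  hi <- org + (d - 1) * vox + vox / 2
  u <- (seq_len(det$nu) - (det$nu + 1) / 2) * det$pixel_mm
  v <- (seq_len(det$nv) - (det$nv + 1) / 2) * det$pixel_mm
  out <- matrix(0, det$nu, det$nv)
  nxy <- d[1] * d[2]
  src <- fr$source
  for (iv in seq_len(det$nv)) {
    for (iu in seq_len(det$nu)) {
      p <- fr$det_center + u[iu] * fr$eu + v[iv] * fr$ev
      dir <- p - src
      dn <- sqrt(sum(dir^2))
      if (dn == 0) stop("degenerate ray")
      dir <- dir / dn
      # slab intersection with the outer voxel box
      t0 <- -Inf; t1 <- Inf; miss <- FALSE
      for (ax in 1:3) {
        if (dir[ax] == 0) {
          if (src[ax] < lo[ax] || src[ax] > hi[ax]) { miss <- TRUE; break }
        } else {
          ta <- (lo[ax] - src[ax]) / dir[ax]
          tb <- (hi[ax] - src[ax]) / dir[ax]
          t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
        }
      }
      if (miss || t1 <= t0) next
      ns <- ceiling((t1 - t0) / step_mm)
      dt <- (t1 - t0) / ns
      t <- t0 + (seq_len(ns) - 0.5) * dt
      gx <- (src[1] + t * dir[1] - org[1]) / vox[1]
      gy <- (src[2] + t * dir[2] - org[2]) / vox[2]
      gz <- (src[3] + t * dir[3] - org[3]) / vox[3]
      ok <- gx >= 0 & gx <= d[1] - 1 & gy >= 0 & gy <= d[2] - 1 &
            gz >= 0 & gz <= d[3] - 1
      if (!any(ok)) next
      gx <- gx[ok]; gy <- gy[ok]; gz <- gz[ok]
      i0 <- pmin(floor(gx), d[1] - 2); fx <- gx - i0
      j0 <- pmin(floor(gy), d[2] - 2); fy <- gy - j0
      k0 <- pmin(floor(gz), d[3] - 2); fz <- gz - k0
      base <- 1 + i0 + j0 * d[1] + k0 * nxy
      s <- a[base]       * (1 - fx) * (1 - fy) * (1 - fz) +
           a[base + 1]   * fx       * (1 - fy) * (1 - fz) +
           a[base + d[1]]     * (1 - fx) * fy * (1 - fz) +
           a[base + d[1] + 1] * fx       * fy * (1 - fz) +
           a[base + nxy]      * (1 - fx) * (1 - fy) * fz +
           a[base + nxy + 1]  * fx       * (1 - fy) * fz +
           a[base + nxy + d[1]]     * (1 - fx) * fy * fz +
           a[base + nxy + d[1] + 1] * fx       * fy * fz
      out[iu, iv] <- sum(s) * dt
    }
  }
  projection_image(out, angle_deg, geom, domain = "line_integral")
}

#' Digitally reconstructed radiographs: fast vectorized engine
#'
#' Same mathematical contract as [drr_oracle()] (identical ray convention,
#' fixed-step trilinear sampling), but batched over all pixels and angles in
#' compiled code. Deterministic: repeated runs are bit-identical.
#'
#' @param vol A [voxel_volume()].
#' @param geom A [scan_geometry()]; one DRR is produced per geometry angle.
#' @param step_mm Sampling step; default `min(voxel_mm) / 2`.
#' @return A [projection_set()] in the line-integral domain.
#' @export
drr_fast <- function(vol, geom, step_mm = NULL) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(geom, "scan_geometry"))
  if (is.null(step_mm)) step_mm <- min(vol$voxel_mm) / 2
  det <- geom$detector
  ang <- geom$angles_deg
  frames <- lapply(ang, function(a) gantry_frame(geom, a))
  src <- t(vapply(frames, `[[`, numeric(3), "source"))
  d0 <- t(vapply(frames, `[[`, numeric(3), "d0"))
  eu <- t(vapply(frames, `[[`, numeric(3), "eu"))
  ev <- t(vapply(frames, `[[`, numeric(3), "ev"))
  imgs <- cpp_drr(vol$values, dim(vol$values), vol$voxel_mm, vol$origin_mm,
                  src, d0, eu, ev, det$nu, det$nv, det$pixel_mm,
                  geom$source_detector_distance_mm, step_mm)
  projection_set(array(imgs, c(det$nu, det$nv, length(ang))), geom,
                 domain = "line_integral")
}
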