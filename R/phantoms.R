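#' Reference attenuation coefficients
#'
#' Nominal linear attenuation (mm^-1) of the phantom materials at a diagnostic
#' kV effective energy (~60-80 keV). Only the relative contrast matters for
#' the geometric and registration validation metrics.
#' @export
phantom_materials <- function() {
  c(air = 0, soft = 0.018, water = 0.02, bone = 0.048)
}

#' Digital water-equivalent cube phantom
#'
#' Axis-aligned cube of uniform water attenuation centered on the isocenter in
#' an air background. Edge voxels are weighted by the fraction of the voxel
#' the cube occupies along each axis, so the 50 percent edge crossing sits at
#' the true face position: the phantom for sub-millimeter edge-length checks.
#'
#' @param edge_mm Cube edge length in mm (>= 0; 0 gives an empty volume).
#' @param dims Grid dimensions (length 1 or 3).
#' @param voxel_mm Voxel sizes in mm (length 1 or 3).
#' @param mu_water Water attenuation in mm^-1.
#' @return A [voxel_volume()].
#' @export
make_cube_phantom <- function(edge_mm = 50, dims = c(128L, 128L, 128L),
                              voxel_mm = 1, mu_water = phantom_materials()[["water"]]) {
  dims <- rep_len(as.integer(dims), 3L)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (!is.finite(edge_mm) || edge_mm < 0) stop("edge_mm must be >= 0")
  if (any(edge_mm > dims * voxel_mm))
    stop("cube does not fit inside the grid")
  # per-axis coverage fraction of [-e/2, e/2] in each voxel
  cov1 <- function(n, h) {
    x <- (seq_len(n) - (n + 1) / 2) * h     # voxel centers, grid centered at 0
    lo <- pmax(x - h / 2, -edge_mm / 2)
    hi <- pmin(x + h / 2, edge_mm / 2)
    pmax(hi - lo, 0) / h
  }
  wx <- cov1(dims[1], voxel_mm[1])
  wy <- cov1(dims[2], voxel_mm[2])
  wz <- cov1(dims[3], voxel_mm[3])
  vals <- mu_water * outer(outer(wx, wy), wz)
  voxel_volume(vals, voxel_mm)
}

#' Digital pelvis-like phantom
#'
#' Deterministic stand-in for a physical pelvis phantom: an elliptical
#' soft-tissue body (cylinder along LNG) containing two lateral bone cylinders
#' ("hips"), a posterior midline bone column ("sacrum"), and an anterior
#' midline air cavity. Mirror-symmetric about the sagittal midplane. The bone
#' structures provide the high-contrast content that DTS registration keys on;
#' no anthropomorphic texture is attempted. All structure positions/sizes are
#' in mm and scale to the default 128 mm desk-scale grid.
#'
#' @param dims Grid dimensions (length 1 or 3).
#' @param voxel_mm Voxel sizes in mm (length 1 or 3).
#' @param body_semi_mm Body ellipse semi-axes (LAT, VRT) in mm.
#' @param body_len_frac Fraction of the LNG extent occupied by the body.
#' @param mu Named attenuation vector as from [phantom_materials()].
#' @return A [voxel_volume()].
#' @export
make_pelvis_phantom <- function(dims = c(128L, 128L, 128L), voxel_mm = 1,
                                body_semi_mm = c(52, 38),
                                body_len_frac = 0.85,
                                mu = phantom_materials()) {
  dims <- rep_len(as.integer(dims), 3L)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  ext <- dims * voxel_mm
  if (any(2 * body_semi_mm > ext[c(1, 3)]))
    stop("body ellipse does not fit inside the grid")
  a <- body_semi_mm[1]; c0 <- body_semi_mm[2]
  hips_r <- 0.22 * a; hips_x <- 0.55 * a; hips_z <- -0.05 * c0
  sac_r <- 0.18 * a; sac_z <- -0.55 * c0
  air_r <- 0.12 * a; air_z <- -0.15 * c0
  if (hips_x + hips_r > a || abs(sac_z) + sac_r > c0)
    stop("bone structures exceed the body outline")
  x <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * voxel_mm[1]
  y <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * voxel_mm[2]
  z <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * voxel_mm[3]
  half_len <- body_len_frac * ext[2] / 2
  in_y <- abs(y) <= half_len
  X <- matrix(x, dims[1], dims[3])
  Z <- matrix(z, dims[1], dims[3], byrow = TRUE)
  body <- (X / a)^2 + (Z / c0)^2 <= 1
  circ <- function(cx, cz, r) ((X - cx)^2 + (Z - cz)^2) <= r^2
  sl <- matrix(mu[["air"]], dims[1], dims[3])
  sl[body] <- mu[["soft"]]
  sl[circ(-hips_x, hips_z, hips_r)] <- mu[["bone"]]
  sl[circ(hips_x, hips_z, hips_r)] <- mu[["bone"]]
  sl[circ(0, sac_z, sac_r)] <- mu[["bone"]]
  sl[circ(0, air_z, air_r)] <- mu[["air"]]
  vals <- array(0, dims)
  # iliac "wings": widen the hip bones over the superior half to break
  # LNG translation ambiguity (adds structure along the longitudinal axis)
  sl_wing <- sl
  sl_wing[circ(-hips_x, hips_z + 0.35 * c0, 0.6 * hips_r)] <- mu[["bone"]]
  sl_wing[circ(hips_x, hips_z + 0.35 * c0, 0.6 * hips_r)] <- mu[["bone"]]
  wing_y <- in_y & (y > 0.25 * half_len)
  for (j in seq_len(dims[2])) {
    if (!in_y[j]) next
    vals[, j, ] <- if (wing_y[j]) sl_wing else sl
  }
  voxel_volume(vals, voxel_mm)
}
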