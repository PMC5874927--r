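#' Voxel volume
#'
#' A 3D grid of linear attenuation values (mm^-1) in patient axes. Array
#' dimension 1 runs along LAT (x), dimension 2 along LNG (y), dimension 3
#' along VRT (z). `origin_mm` is the position of the center of voxel
#' `[1, 1, 1]`; by default the grid is centered on the isocenter.
#'
#' @param values Numeric 3D array of attenuation coefficients (>= 0, finite).
#' @param voxel_mm Per-axis voxel sizes in mm (length 1 or 3).
#' @param origin_mm Center of voxel `[1,1,1]` in mm (length 3), or `NULL` to
#'   center the grid on the isocenter.
#' @param nonneg Enforce the attenuation invariant `values >= 0`. Reconstructed
#'   (filtered back-projection) volumes set this to `FALSE`: ramp filtering
#'   legitimately produces negative ringing.
#' @return Object of class `voxel_volume`: list with `values`, `voxel_mm`,
#'   `origin_mm`.
#' @export
voxel_volume <- function(values, voxel_mm = 1, origin_mm = NULL, nonneg = TRUE) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("voxel_mm must be positive and finite")
  if (anyNA(values) || any(!is.finite(values))) stop("attenuation values must be finite")
  if (nonneg && any(values < 0)) stop("attenuation values must be >= 0")
  d <- dim(values)
  if (is.null(origin_mm)) origin_mm <- -(d - 1) / 2 * voxel_mm
  structure(list(values = values, voxel_mm = voxel_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %dx%dx%d voxels @ (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, range [%.4g, %.4g] mm^-1\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# voxel-center coordinates along one axis (1 = LAT, 2 = LNG, 3 = VRT)
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin_mm[axis] + (seq_len(n) - 1) * vol$voxel_mm[axis]
}

#' Attenuation-weighted centroid of a volume
#' @param vol A [voxel_volume()].
#' @return Length-3 centroid (LAT, LNG, VRT) in mm.
#' @export
volume_centroid <- function(vol) {
  v <- vol$values
  tot <- sum(v)
  if (tot <= 0) stop("volume has no attenuation; centroid undefined")
  cx <- sum(rowSums(v, dims = 1L) * axis_coords(vol, 1L))
  cy <- sum(rowSums(aperm(v, c(2L, 1L, 3L)), dims = 1L) * axis_coords(vol, 2L))
  cz <- sum(colSums(v, dims = 2L) * axis_coords(vol, 3L))
  c(cx, cy, cz) / tot
}

#' Translate a volume by a sub-voxel rigid shift
#'
#' Moves the volume content by `shift_mm` along (LAT, LNG, VRT) with trilinear
#' interpolation; voxels shifted in from outside the field are filled with the
#' background value 0. This is the digital analogue of shifting the planning
#' CT by a known couch displacement before rebuilding reference DTS.
#'
#' @param vol A [voxel_volume()].
#' @param shift_mm Length-3 shift in mm (content moves by +shift).
#' @return A shifted [voxel_volume()] on the same grid. If more than 1 percent
#'   of the total attenuation leaves the field a warning is issued.
#' @export
shift_volume <- function(vol, shift_mm) {
  shift_mm <- rep_len(as.numeric(shift_mm), 3L)
  if (all(shift_mm == 0)) return(vol)
  d <- dim(vol$values)
  # sample the input at x - shift: continuous 0-based source indices
  gx <- (seq_len(d[1]) - 1) - shift_mm[1] / vol$voxel_mm[1]
  gy <- (seq_len(d[2]) - 1) - shift_mm[2] / vol$voxel_mm[2]
  gz <- (seq_len(d[3]) - 1) - shift_mm[3] / vol$voxel_mm[3]
  out <- interp_trilinear_grid(vol$values, gx, gy, gz)
  tot_in <- sum(vol$values)
  if (tot_in > 0 && (tot_in - sum(out)) / tot_in > 0.01)
    warning("shift_volume: more than 1% of total attenuation left the field")
  voxel_volume(out, vol$voxel_mm, vol$origin_mm)
}

# trilinear resample of a 3D array on the tensor grid gx x gy x gz
# (0-based continuous indices); outside -> 0
interp_trilinear_grid <- function(a, gx, gy, gz) {
  d <- dim(a)
  cl <- function(g, n) pmin(pmax(g, 0), n - 1)
  okx <- gx >= 0 & gx <= d[1] - 1
  oky <- gy >= 0 & gy <= d[2] - 1
  okz <- gz >= 0 & gz <= d[3] - 1
  gx <- cl(gx, d[1]); gy <- cl(gy, d[2]); gz <- cl(gz, d[3])
  i0 <- pmin(floor(gx), d[1] - 2); fx <- gx - i0
  j0 <- pmin(floor(gy), d[2] - 2); fy <- gy - j0
  k0 <- pmin(floor(gz), d[3] - 2); fz <- gz - k0
  if (d[1] < 2L) { i0 <- rep(0, length(gx)); fx <- rep(0, length(gx)) }
  if (d[2] < 2L) { j0 <- rep(0, length(gy)); fy <- rep(0, length(gy)) }
  if (d[3] < 2L) { k0 <- rep(0, length(gz)); fz <- rep(0, length(gz)) }
  out <- array(0, d)
  # slice-by-slice along z to bound memory
  nx <- d[1]; ny <- d[2]
  I0 <- matrix(i0 + 1L, nx, ny); J0 <- matrix(j0 + 1L, nx, ny, byrow = TRUE)
  FX <- matrix(fx, nx, ny); FY <- matrix(fy, nx, ny, byrow = TRUE)
  OK2 <- outer(okx, oky, `&`)
  for (k in seq_len(d[3])) {
    if (!okz[k]) next
    kk <- k0[k] + 1L; fzk <- fz[k]
    s0 <- a[, , kk]; s1 <- if (d[3] >= 2L) a[, , kk + 1L] else s0
    idx00 <- cbind(as.vector(I0), as.vector(J0))
    v000 <- matrix(s0[idx00], nx, ny)
    v100 <- matrix(s0[idx00 + rep(c(1L, 0L), each = nx * ny)], nx, ny)
    v010 <- matrix(s0[idx00 + rep(c(0L, 1L), each = nx * ny)], nx, ny)
    v110 <- matrix(s0[idx00 + rep(c(1L, 1L), each = nx * ny)], nx, ny)
    v001 <- matrix(s1[idx00], nx, ny)
    v101 <- matrix(s1[idx00 + rep(c(1L, 0L), each = nx * ny)], nx, ny)
    v011 <- matrix(s1[idx00 + rep(c(0L, 1L), each = nx * ny)], nx, ny)
    v111 <- matrix(s1[idx00 + rep(c(1L, 1L), each = nx * ny)], nx, ny)
    c00 <- v000 * (1 - FX) + v100 * FX
    c10 <- v010 * (1 - FX) + v110 * FX
    c01 <- v001 * (1 - FX) + v101 * FX
    c11 <- v011 * (1 - FX) + v111 * FX
    sl <- (c00 * (1 - FY) + c10 * FY) * (1 - fzk) +
          (c01 * (1 - FY) + c11 * FY) * fzk
    sl[!OK2] <- 0
    out[, , k] <- sl
  }
  out
}

#' Write / read a volume as raw float32 + JSON metadata
#'
#' `write_volume()` stores `<base>.raw` (little-endian float32, column-major
#' in (LAT, LNG, VRT) order) and `<base>.json` (dims, voxel sizes, origin).
#' `read_volume()` reverses it.
#'
#' @param vol A [voxel_volume()].
#' @param base Path without extension.
#' @return `write_volume()` the base path invisibly; `read_volume()` a
#'   [voxel_volume()].
#' @export
write_volume <- function(vol, base) {
  meta <- list(format = "dtsalign-volume-v1", dims = dim(vol$values),
               voxel_mm = vol$voxel_mm, origin_mm = vol$origin_mm,
               dtype = "float32", byte_order = "little")
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$values), con, size = 4L, endian = "little")
  invisible(base)
}

#' @rdname write_volume
#' @export
read_volume <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "dtsalign-volume-v1"))
    stop("not a dtsalign volume: ", base)
  n <- prod(meta$dims)
  con <- file(paste0(base, ".raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  # reconstructed (filtered back-projection) stacks carry negative ringing
  voxel_volume(array(v, meta$dims), meta$voxel_mm, meta$origin_mm,
               nonneg = FALSE)
}
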