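#' Ramp filter specification
#'
#' Row-wise ramp filtering for FDK-style back-projection. `window = "hamming"`
#' (default) apodizes the ramp with a Hamming window at the detector Nyquist
#' frequency, trading a little resolution for noise suppression; `"ram-lak"`
#' is the bare band-limited ramp.
#'
#' @param window `"hamming"` or `"ram-lak"`.
#' @return Object of class `ramp_filter`.
#' @export
ramp_filter <- function(window = c("hamming", "ram-lak")) {
  structure(list(window = match.arg(window)), class = "ramp_filter")
}

# frequency response of the ramp on an N-point FFT grid, sample spacing d (mm)
ramp_response <- function(N, d, window) {
  k <- 0:(N - 1)
  f <- pmin(k, N - k) / (N * d)           # cycles/mm, symmetric
  H <- f
  if (window == "hamming") {
    fn <- 1 / (2 * d)
    H <- H * (0.54 + 0.46 * cos(pi * f / fn))
  }
  H                                        # H[1] = 0: DC is removed exactly
}

#' Pre-weight and ramp-filter a projection
#'
#' Prepares one view for FDK back-projection: (1) logarithm conversion
#' `q = ln(I0 / I)` if the view is in the intensity domain (line-integral
#' views skip this step); (2) cosine pre-weighting
#' `SAD / sqrt(SAD^2 + u^2 + v^2)` with `(u, v)` the physical pixel
#' coordinates rescaled to the isocenter plane; (3) ramp filtering of every
#' detector row by FFT, padded to the next power of two >= 2*nu. Padding is by
#' edge replication rather than zeros so that the filter's exact DC kill is
#' preserved for rows that do not decay to zero at the detector border (a
#' constant row filters to exactly zero).
#'
#' @param p A [projection_image()] or [projection_set()].
#' @param I0 Flood intensity for the log conversion.
#' @param filter A [ramp_filter()].
#' @return Same class as `p`, tagged as filtered (`domain` `"filtered"` is
#'   carried in the `filtered` attribute); pixel dims unchanged.
#' @export
preprocess_projection <- function(p, I0 = 1.0, filter = ramp_filter()) {
  stopifnot(inherits(filter, "ramp_filter"))
  if (inherits(p, "projection_set")) {
    g <- p$geom
    q <- if (p$domain == "intensity") {
      if (any(p$images <= 0)) {
        nbad <- sum(p$images <= 0)
        stop(sprintf("%d non-positive intensity pixel(s); cannot log-convert", nbad))
      }
      log(I0 / p$images)
    } else p$images
    out <- q
    for (i in seq_len(dim(q)[3]))
      out[, , i] <- filter_one(q[, , i], g, filter)
    res <- structure(list(images = out, geom = g, domain = "line_integral"),
                     class = "projection_set")
    attr(res, "filtered") <- TRUE
    return(res)
  }
  stopifnot(inherits(p, "projection_image"))
  g <- p$geom
  q <- if (p$domain == "intensity") {
    if (any(p$pixels <= 0)) {
      nbad <- sum(p$pixels <= 0)
      stop(sprintf("%d non-positive intensity pixel(s); cannot log-convert", nbad))
    }
    log(I0 / p$pixels)
  } else p$pixels
  out <- filter_one(q, g, filter)
  res <- list(pixels = out, angle_deg = p$angle_deg, geom = g,
              domain = "line_integral")
  class(res) <- "projection_image"
  attr(res, "filtered") <- TRUE
  res
}

# cosine pre-weight + row-wise ramp filtering of one nu x nv view
filter_one <- function(q, geom, filter) {
  det <- geom$detector
  sad <- geom$source_axis_distance_mm
  mag <- sad / geom$source_detector_distance_mm
  u <- (seq_len(det$nu) - (det$nu + 1) / 2) * det$pixel_mm * mag
  v <- (seq_len(det$nv) - (det$nv + 1) / 2) * det$pixel_mm * mag
  w <- sad / sqrt(sad^2 + outer(u^2, v^2, `+`))
  ramp_filter_rows(q * w, det$pixel_mm * mag, filter$window)
}

#' Ramp-filter the rows of a detector image
#'
#' FFT implementation of the 1D ramp: each row (first matrix dimension, the
#' detector u axis) is padded to the next power of two >= twice its length by
#' edge replication, multiplied by the (optionally Hamming-windowed) `|f|`
#' response in the frequency domain, and cropped back. The DC bin weight is
#' exactly zero, so a constant row filters to zero at machine precision.
#'
#' @param q `nu x nv` matrix (rows along u).
#' @param spacing_mm Row sample spacing in mm (at the isocenter scale for FDK
#'   use).
#' @param window `"hamming"` or `"ram-lak"`.
#' @return Filtered matrix of the same dimensions.
#' @export
ramp_filter_rows <- function(q, spacing_mm, window = "hamming") {
  nu <- nrow(q); nv <- ncol(q)
  N <- 2^ceiling(log2(2 * nu))
  H <- ramp_response(N, spacing_mm, window)
  P <- matrix(0, N, nv)
  P[seq_len(nu), ] <- q
  pad <- N - nu
  pr <- pad %/% 2
  if (pr > 0)
    P[nu + seq_len(pr), ] <- matrix(q[nu, ], pr, nv, byrow = TRUE)
  pl <- pad - pr
  if (pl > 0)
    P[nu + pr + seq_len(pl), ] <- matrix(q[1, ], pl, nv, byrow = TRUE)
  Fq <- stats::mvfft(P) * H
  out <- Re(stats::mvfft(Fq, inverse = TRUE)) / N
  out[seq_len(nu), , drop = FALSE]
}

#' DTS volume specification
#'
#' Orientation and grid of a reconstructed DTS plane stack. Coronal planes
#' are LAT x LNG, stacked along VRT with the slice thickness as the VRT
#' voxel size; sagittal planes are LNG x VRT, stacked along LAT. In-plane
#' pixels default to the 0.5 mm nominal DTS grid.
#'
#' @param orientation `"coronal"` or `"sagittal"`.
#' @param pixel_mm In-plane pixel sizes (length 1 or 2), mm.
#' @param slice_mm Slice thickness (stacking-axis voxel size), mm.
#' @param n_inplane In-plane dimensions (length 1 or 2).
#' @param n_slices Number of DTS planes.
#' @param offset_mm Slab center offset along the stacking axis, mm.
#' @return Object of class `dts_spec`.
#' @export
dts_volume_spec <- function(orientation = c("coronal", "sagittal"),
                            pixel_mm = 0.5, slice_mm = 1.0,
                            n_inplane = c(128L, 128L), n_slices = 64L,
                            offset_mm = 0) {
  orientation <- match.arg(orientation)
  pixel_mm <- rep_len(as.numeric(pixel_mm), 2L)
  n_inplane <- rep_len(as.integer(n_inplane), 2L)
  if (any(pixel_mm <= 0) || slice_mm <= 0) stop("pixel/slice sizes must be > 0")
  if (any(n_inplane < 1L) || n_slices < 1L) stop("grid dims must be >= 1")
  structure(list(orientation = orientation, pixel_mm = pixel_mm,
                 slice_mm = slice_mm, n_inplane = n_inplane,
                 n_slices = as.integer(n_slices), offset_mm = offset_mm),
            class = "dts_spec")
}

# patient-axis grid (dims, voxel, origin) of a DTS spec
dts_grid <- function(spec) {
  if (spec$orientation == "coronal") {
    dims <- c(spec$n_inplane[1], spec$n_inplane[2], spec$n_slices)
    vox <- c(spec$pixel_mm[1], spec$pixel_mm[2], spec$slice_mm)
    off <- c(0, 0, spec$offset_mm)
  } else {
    dims <- c(spec$n_slices, spec$n_inplane[1], spec$n_inplane[2])
    vox <- c(spec$slice_mm, spec$pixel_mm[1], spec$pixel_mm[2])
    off <- c(spec$offset_mm, 0, 0)
  }
  list(dims = as.integer(dims), voxel_mm = vox,
       origin_mm = -(dims - 1) / 2 * vox + off)
}

# index of the stacking (depth) axis in patient coordinates
dts_stack_axis <- function(spec) if (spec$orientation == "coronal") 3L else 1L

#' Reconstruct a DTS plane stack from a narrow-arc projection set
#'
#' FDK-style filtered back-projection restricted to a narrow arc: every view
#' is log-converted (if needed), cosine pre-weighted and ramp-filtered
#' ([preprocess_projection()]), then back-projected onto the DTS grid with
#' the distance weight `SAD^2 / U^2` and the angular step as integration
#' weight. Coronal stacks expect an arc centered near gantry 0 degrees,
#' sagittal stacks near 270 degrees; a mismatch only triggers a warning since
#' off-center slabs are legitimate.
#'
#' @param pset A [projection_set()] (intensity or line-integral domain).
#' @param spec A [dts_volume_spec()].
#' @param engine `"fast"` (compiled, batched) or `"oracle"` (pure R,
#'   plane-by-plane reference implementation).
#' @param I0 Flood intensity for the log conversion.
#' @param filter A [ramp_filter()].
#' @return A [voxel_volume()] (values may be negative: filtered
#'   back-projection output) with attributes `orientation` and `dts_spec`.
#' @export
reconstruct_dts <- function(pset, spec, engine = c("fast", "oracle"),
                            I0 = 1.0, filter = ramp_filter()) {
  engine <- match.arg(engine)
  stopifnot(inherits(pset, "projection_set"), inherits(spec, "dts_spec"))
  if (n_angles(pset$geom) < 1L) stop("empty projection set")
  center <- if (spec$orientation == "coronal") 0 else 270
  mid <- pset$geom$angles_deg[ceiling(n_angles(pset$geom) / 2)]
  if (circular_distance(mid, center) > 45)
    warning(sprintf("%s DTS from an arc centered at %.1f deg (expected near %d deg)",
                    spec$orientation, wrap_angle(mid), center))
  filt <- preprocess_projection(pset, I0 = I0, filter = filter)
  g <- pset$geom
  grid <- dts_grid(spec)
  frames <- lapply(g$angles_deg, function(a) gantry_frame(g, a))
  src <- t(vapply(frames, `[[`, numeric(3), "source"))
  d0 <- t(vapply(frames, `[[`, numeric(3), "d0"))
  eu <- t(vapply(frames, `[[`, numeric(3), "eu"))
  ev <- t(vapply(frames, `[[`, numeric(3), "ev"))
  dbeta <- g$angular_spacing_deg * pi / 180
  det <- g$detector
  if (engine == "fast") {
    vals <- cpp_backproject(filt$images, det$nu, det$nv, src, d0, eu, ev,
                            g$source_axis_distance_mm,
                            g$source_detector_distance_mm, det$pixel_mm,
                            dbeta, grid$dims, grid$voxel_mm, grid$origin_mm)
    vals <- array(vals, grid$dims)
  } else {
    vals <- backproject_oracle(filt$images, g, grid, dbeta)
  }
  out <- voxel_volume(vals, grid$voxel_mm, grid$origin_mm, nonneg = FALSE)
  attr(out, "orientation") <- spec$orientation
  attr(out, "dts_spec") <- spec
  out
}

# pure-R reference back-projection: loops over views and z-planes, vectorized
# only within a plane
backproject_oracle <- function(filt, geom, grid, dbeta) {
  det <- geom$detector
  sad <- geom$source_axis_distance_mm
  sdd <- geom$source_detector_distance_mm
  pix <- det$pixel_mm
  d <- grid$dims
  x <- grid$origin_mm[1] + (seq_len(d[1]) - 1) * grid$voxel_mm[1]
  y <- grid$origin_mm[2] + (seq_len(d[2]) - 1) * grid$voxel_mm[2]
  z <- grid$origin_mm[3] + (seq_len(d[3]) - 1) * grid$voxel_mm[3]
  X <- matrix(x, d[1], d[2])
  Y <- matrix(y, d[1], d[2], byrow = TRUE)
  out <- array(0, d)
  for (n in seq_len(n_angles(geom))) {
    fr <- gantry_frame(geom, geom$angles_deg[n])
    fp <- filt[, , n]
    S <- fr$source; A <- fr$d0; E <- fr$eu; V <- fr$ev
    w0 <- X - S[1]; w1 <- Y - S[2]
    for (k in seq_len(d[3])) {
      w2 <- z[k] - S[3]
      U <- w0 * A[1] + w1 * A[2] + w2 * A[3]
      m <- sdd / U
      pu <- (w0 * E[1] + w1 * E[2] + w2 * E[3]) * m / pix + (det$nu + 1) / 2
      pv <- (w0 * V[1] + w1 * V[2] + w2 * V[3]) * m / pix + (det$nv + 1) / 2
      ok <- U > 1e-6 & pu >= 1 & pu <= det$nu & pv >= 1 & pv <= det$nv
      if (!any(ok)) next
      puk <- pu[ok]; pvk <- pv[ok]
      i0 <- pmin(floor(puk), det$nu - 1); fu <- puk - i0
      j0 <- pmin(floor(pvk), det$nv - 1); fv <- pvk - j0
      base <- i0 + (j0 - 1) * det$nu
      val <- fp[base] * (1 - fu) * (1 - fv) +
             fp[base + 1] * fu * (1 - fv) +
             fp[base + det$nu] * (1 - fu) * fv +
             fp[base + det$nu + 1] * fu * fv
      sl <- matrix(0, d[1], d[2])
      sl[ok] <- val * (sad^2 / U[ok]^2) * dbeta
      out[, , k] <- out[, , k] + sl
    }
  }
  out
}

#' Extract one DTS plane
#' @param vol A DTS [voxel_volume()] from [reconstruct_dts()].
#' @param i Plane index along the stacking axis.
#' @return In-plane matrix (coronal: LAT x LNG; sagittal: LNG x VRT) with a
#'   `pixel_mm` attribute.
#' @export
dts_slice <- function(vol, i) {
  spec <- attr(vol, "dts_spec")
  if (is.null(spec)) stop("not a DTS volume (missing dts_spec attribute)")
  if (i < 1 || i > spec$n_slices) stop("plane index out of range")
  m <- if (spec$orientation == "coronal") vol$values[, , i]
       else matrix(vol$values[i, , ], dim(vol$values)[2], dim(vol$values)[3])
  attr(m, "pixel_mm") <- spec$pixel_mm
  m
}

#' Average the central DTS planes into a focal image
#'
#' Structures are sharpest near the focal plane at the slab center; averaging
#' a thin central slab is the 2D image the translational registration runs on.
#'
#' @param vol A DTS [voxel_volume()].
#' @param n_focal_slices Number of central planes to average.
#' @return In-plane matrix with a `pixel_mm` attribute.
#' @export
focal_image <- function(vol, n_focal_slices = 5L) {
  spec <- attr(vol, "dts_spec")
  if (is.null(spec)) stop("not a DTS volume (missing dts_spec attribute)")
  n <- spec$n_slices
  k <- min(as.integer(n_focal_slices), n)
  mid <- (n + 1) / 2
  idx <- seq.int(ceiling(mid - k / 2), length.out = k)
  acc <- 0
  for (i in idx) acc <- acc + dts_slice(vol, i)
  m <- acc / k
  attr(m, "pixel_mm") <- spec$pixel_mm
  m
}

#' Stitch two half-fan DTS volumes
#'
#' Half-fan acquisitions image one lateral half of the patient per arc; the
#' two reconstructions are merged by taking each input in its exclusive
#' lateral region and cross-fading linearly across the overlap band.
#'
#' @param vol_a,vol_b DTS [voxel_volume()]s on identical grids; `vol_a` is
#'   valid on the negative side of the blend axis, `vol_b` on the positive.
#' @param axis Patient axis (1 = LAT, 2 = LNG, 3 = VRT) of the blend.
#' @param boundary_mm Center of the overlap band along `axis`, mm.
#' @param blend_mm Width of the linear cross-fade band, mm (0 = hard union).
#' @return A [voxel_volume()] on the shared grid.
#' @export
stitch_halffan <- function(vol_a, vol_b, axis = 1L, boundary_mm = 0,
                           blend_mm = 20) {
  if (!identical(dim(vol_a$values), dim(vol_b$values)) ||
      !isTRUE(all.equal(vol_a$voxel_mm, vol_b$voxel_mm)) ||
      !isTRUE(all.equal(vol_a$origin_mm, vol_b$origin_mm)))
    stop("volumes must share one grid")
  xs <- axis_coords(vol_a, axis)
  h <- blend_mm / 2
  wa <- if (h > 0) pmin(pmax((boundary_mm + h - xs) / (2 * h), 0), 1)
        else ifelse(xs < boundary_mm, 1, ifelse(xs > boundary_mm, 0, 0.5))
  shp <- c(1L, 1L, 1L); shp[axis] <- length(xs)
  W <- array(rep(wa, each = prod(dim(vol_a$values)[seq_len(axis - 1)])),
             dim(vol_a$values))
  out <- vol_a
  out$values <- W * vol_a$values + (1 - W) * vol_b$values
  out
}
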