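#' Pearson correlation between two images
#'
#' Similarity metric used to compare the reference and fast engines: plain
#' Pearson correlation over all pixels (or voxels).
#'
#' @param a,b Numeric arrays of identical dimensions.
#' @return Correlation in `[-1, 1]`.
#' @export
correlation_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("images must have identical dimensions")
  a <- as.vector(a); b <- as.vector(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant image")
  stats::cor(a, b)
}

#' Subtraction-image statistics on the (0, 255) scale
#'
#' Windows both images to (0, 255) using the REFERENCE image's min/max (so a
#' perfect test image yields exactly zero difference), and reports the mean
#' and standard deviation of the absolute subtraction image on that scale,
#' plus the same as percentages of full scale (255).
#'
#' @param reference,test Numeric arrays of identical dimensions; `reference`
#'   must have nonzero dynamic range.
#' @return Object of class `subtraction_stats`: list with `abs_mean`,
#'   `abs_sd`, `rel_mean_pct`, `rel_sd_pct`.
#' @export
subtraction_stats <- function(reference, test) {
  if (!identical(dim(reference), dim(test)))
    stop("images must have identical dimensions")
  w <- range(reference)
  if (diff(w) == 0) stop("reference image has zero dynamic range")
  rescale <- function(x) pmin(pmax((x - w[1]) / (w[2] - w[1]) * 255, 0), 255)
  d <- abs(rescale(reference) - rescale(test))
  structure(list(abs_mean = mean(d), abs_sd = stats::sd(d),
                 rel_mean_pct = 100 * mean(d) / 255,
                 rel_sd_pct = 100 * stats::sd(d) / 255),
            class = "subtraction_stats")
}

#' @export
print.subtraction_stats <- function(x, ...) {
  cat(sprintf("<subtraction_stats> %.3g +/- %.3g (0-255 scale); %.3g%% +/- %.3g%%\n",
              x$abs_mean, x$abs_sd, x$rel_mean_pct, x$rel_sd_pct))
  invisible(x)
}

#' Sub-pixel edge-to-edge length of an object on a DTS plane
#'
#' Extracts a 1D profile through the object, estimates the plateau and
#' background levels robustly (medians), and locates the two edges at 50
#' percent of the local step height with linear sub-pixel interpolation. The
#' 50-percent-of-step criterion is robust to the limited-angle background
#' haze around the object and, for symmetric edge blur, recovers the true
#' face position.
#'
#' @param plane In-plane matrix (e.g. from [dts_slice()] or [focal_image()])
#'   with a `pixel_mm` attribute, or supply `pixel_mm`.
#' @param axis In-plane axis to measure along (1 = rows, 2 = columns).
#' @param line_offset_mm Offset of the profile line from the plane center
#'   along the perpendicular in-plane axis, mm.
#' @param pixel_mm Optional in-plane pixel sizes (length 2), mm.
#' @return Length between the two 50-percent crossings, mm.
#' @export
measure_edge_length <- function(plane, axis = 1L, line_offset_mm = 0,
                                pixel_mm = NULL) {
  if (is.null(pixel_mm)) pixel_mm <- attr(plane, "pixel_mm")
  if (is.null(pixel_mm)) stop("pixel_mm required")
  pixel_mm <- rep_len(as.numeric(pixel_mm), 2L)
  other <- 3L - axis
  n_other <- dim(plane)[other]
  j <- round((n_other + 1) / 2 + line_offset_mm / pixel_mm[other])
  if (j < 1 || j > n_other) stop("profile line outside the plane")
  prof <- if (axis == 1L) plane[, j] else plane[j, ]
  step <- pixel_mm[axis]
  measure_profile_length(prof, step)
}

# 50%-of-step edge localization on a 1D profile; returns length in mm
measure_profile_length <- function(prof, step_mm) {
  n <- length(prof)
  rng <- range(prof)
  if (diff(rng) == 0) stop("flat profile: no edges")
  above0 <- which(prof >= mean(rng))
  if (length(above0) < 1L) stop("no object found on the profile")
  e1 <- min(above0); e2 <- max(above0)
  width <- e2 - e1 + 1L
  core <- seq.int(e1 + floor(width * 0.25), e2 - floor(width * 0.25))
  plateau <- stats::median(prof[core])
  margin <- max(2L, ceiling(width * 0.05))
  bgidx <- c(seq_len(max(e1 - margin, 0L)),
             if (e2 + margin <= n) seq.int(e2 + margin, n) else integer(0))
  if (length(bgidx) < 1L) stop("no background region on the profile")
  background <- stats::median(prof[bgidx])
  thr <- background + 0.5 * (plateau - background)
  s <- prof >= thr
  cross <- which(s[-1] != s[-n])           # edge between i and i+1
  if (length(cross) != 2L)
    stop(sprintf("ambiguous edges: found %d crossing(s), expected 2", length(cross)))
  pos <- vapply(cross, function(i) {
    i + (thr - prof[i]) / (prof[i + 1] - prof[i])
  }, numeric(1))
  (pos[2] - pos[1]) * step_mm
}

#' Cube-phantom geometric accuracy study
#'
#' Reconstructs coronal and sagittal DTS of a cube phantom for each scan arc
#' and engine, then measures the cube's LAT/LNG lengths on the coronal focal
#' plane and LNG/VRT lengths on the sagittal focal plane, five profile lines
#' per length spread over the central third of the face. Mirrors the standard
#' geometric-accuracy protocol: tabulated means/SDs and deviations from the
#' true edge length.
#'
#' @param pset Full-fan [projection_set()] of the cube phantom
#'   (line-integral or intensity domain).
#' @param arcs_deg Scan-arc widths in degrees.
#' @param engines Reconstruction engines to tabulate (`"fast"`, `"oracle"`).
#' @param spec_cor,spec_sag Coronal / sagittal [dts_volume_spec()]s.
#' @param edge_mm True cube edge length, mm.
#' @param n_lines Profile lines per length.
#' @param n_focal_slices Planes averaged into the measurement image.
#' @return Data frame, one row per (arc, engine), with measured lengths,
#'   SDs over the lines, and the worst absolute deviation from `edge_mm`.
#' @export
geometric_accuracy_report <- function(pset, arcs_deg = c(20, 40, 60, 80),
                                      engines = "fast",
                                      spec_cor = dts_volume_spec("coronal"),
                                      spec_sag = dts_volume_spec("sagittal"),
                                      edge_mm = 50, n_lines = 5L,
                                      n_focal_slices = 5L) {
  offsets <- seq(-edge_mm / 6, edge_mm / 6, length.out = n_lines)
  rows <- list()
  for (arc in arcs_deg) {
    ps_cor <- subset_arc(pset, 0, arc)
    ps_sag <- subset_arc(pset, 270, arc)
    for (eng in engines) {
      dts_cor <- reconstruct_dts(ps_cor, spec_cor, engine = eng)
      dts_sag <- reconstruct_dts(ps_sag, spec_sag, engine = eng)
      img_cor <- focal_image(dts_cor, n_focal_slices)
      img_sag <- focal_image(dts_sag, n_focal_slices)
      meas <- function(img, axis)
        vapply(offsets, function(o) measure_edge_length(img, axis, o), numeric(1))
      lat <- meas(img_cor, 1L); lng_c <- meas(img_cor, 2L)
      lng_s <- meas(img_sag, 1L); vrt <- meas(img_sag, 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        arc_deg = arc, engine = eng,
        lat_mm = mean(lat), lat_sd = stats::sd(lat),
        lng_cor_mm = mean(lng_c), lng_cor_sd = stats::sd(lng_c),
        lng_sag_mm = mean(lng_s), lng_sag_sd = stats::sd(lng_s),
        vrt_mm = mean(vrt), vrt_sd = stats::sd(vrt),
        max_abs_dev_mm = max(abs(c(lat, lng_c, lng_s, vrt) - edge_mm)))
    }
  }
  do.call(rbind, rows)
}
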