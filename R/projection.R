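#' Projection image
#'
#' One 2D detector image at a single gantry angle. `pixels` is an `nu x nv`
#' matrix (column index = detector u, row axis = LAT-ward at gantry 0; second
#' index = detector v, parallel to LNG). The `domain` tag records whether the
#' values are line integrals of attenuation (dimensionless) or transmitted
#' intensities in `(0, I0]`.
#'
#' @param pixels `nu x nv` numeric matrix.
#' @param angle_deg Gantry angle of the view in degrees.
#' @param geom The [scan_geometry()] the image belongs to.
#' @param domain `"line_integral"` or `"intensity"`.
#' @return Object of class `projection_image`.
#' @export
projection_image <- function(pixels, angle_deg, geom,
                             domain = c("line_integral", "intensity")) {
  domain <- match.arg(domain)
  det <- geom$detector
  if (!identical(dim(pixels), c(det$nu, det$nv)))
    stop(sprintf("pixels must be %dx%d to match the detector", det$nu, det$nv))
  if (domain == "line_integral" && any(pixels < 0))
    stop("line-integral pixels must be >= 0")
  if (domain == "intensity" && any(pixels <= 0))
    stop("intensity pixels must be > 0")
  structure(list(pixels = pixels, angle_deg = angle_deg, geom = geom,
                 domain = domain),
            class = "projection_image")
}

#' Projection set
#'
#' Ordered stack of projection images, one per geometry angle, in a shared
#' value domain. Stored as an `nu x nv x n_angles` array.
#'
#' @param images `nu x nv x n` array (or list of matrices).
#' @param geom [scan_geometry()] whose angles match the third dimension.
#' @param domain Shared domain tag.
#' @return Object of class `projection_set`.
#' @export
projection_set <- function(images, geom, domain = c("line_integral", "intensity")) {
  domain <- match.arg(domain)
  if (is.list(images)) images <- simplify2array(images)
  det <- geom$detector
  d <- dim(images)
  if (length(d) != 3L || d[1] != det$nu || d[2] != det$nv || d[3] != n_angles(geom))
    stop("images must be nu x nv x n_angles matching the geometry")
  structure(list(images = images, geom = geom, domain = domain),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<projection_set> %d view(s) of %dx%d pixels, %s domain\n",
              d[3], d[1], d[2], x$domain))
  invisible(x)
}

#' Extract one view from a projection set
#' @param pset A [projection_set()].
#' @param i View index (1-based, in geometry order).
#' @return A [projection_image()].
#' @export
pset_image <- function(pset, i) {
  projection_image(pset$images[, , i], pset$geom$angles_deg[i], pset$geom,
                   domain = pset$domain)
}

#' Restrict a projection set to a narrow arc
#'
#' Companion of [select_arc()]: keeps the views whose angles fall in the
#' circular window, together with the matching sub-geometry.
#'
#' @param pset A [projection_set()].
#' @param center_deg,arc_deg Arc center and total width in degrees.
#' @return A [projection_set()].
#' @export
subset_arc <- function(pset, center_deg, arc_deg) {
  keep <- arc_members(pset$geom$angles_deg, center_deg, arc_deg)
  if (!any(keep))
    stop(sprintf("no views within %.6g deg of %.6g deg", arc_deg / 2, center_deg))
  g <- scan_geometry(pset$geom$detector, pset$geom$angles_deg[keep],
                     sad_mm = pset$geom$source_axis_distance_mm,
                     sdd_mm = pset$geom$source_detector_distance_mm,
                     angular_spacing_deg = pset$geom$angular_spacing_deg)
  projection_set(pset$images[, , keep, drop = FALSE], g, domain = pset$domain)
}

#' Convert between line-integral and intensity domains
#'
#' `to_intensity()` applies the Beer-Lambert law `I = I0 * exp(-q)` to a
#' line-integral image; `to_line_integral()` inverts it with the logarithm
#' conversion `q = ln(I0 / I)`. Both flip the domain tag and are exact
#' round-trips of each other.
#'
#' @param p A [projection_image()] or [projection_set()].
#' @param I0 Flood (unattenuated) intensity level, > 0.
#' @return The converted object.
#' @export
to_intensity <- function(p, I0 = 1.0) {
  if (I0 <= 0) stop("I0 must be > 0")
  if (inherits(p, "projection_set")) {
    if (p$domain != "line_integral") stop("input must be in line-integral domain")
    if (any(p$images < 0)) stop("negative line integrals")
    return(projection_set(I0 * exp(-p$images), p$geom, domain = "intensity"))
  }
  if (p$domain != "line_integral") stop("input must be in line-integral domain")
  if (any(p$pixels < 0)) stop("negative line integrals")
  projection_image(I0 * exp(-p$pixels), p$angle_deg, p$geom, domain = "intensity")
}

#' @rdname to_intensity
#' @export
to_line_integral <- function(p, I0 = 1.0) {
  if (I0 <= 0) stop("I0 must be > 0")
  if (inherits(p, "projection_set")) {
    if (p$domain != "intensity") stop("input must be in intensity domain")
    return(projection_set(log(I0 / p$images), p$geom, domain = "line_integral"))
  }
  if (p$domain != "intensity") stop("input must be in intensity domain")
  projection_image(log(I0 / p$pixels), p$angle_deg, p$geom, domain = "line_integral")
}

#' Write / read a projection set as raw float32 images + JSON metadata
#'
#' One `view_####.raw` per angle (little-endian float32, column-major nu x nv)
#' plus `meta.json` carrying the geometry, ordered angles and domain tag.
#'
#' @param pset A [projection_set()].
#' @param dir Directory (created if needed).
#' @return `write_projection_set()` the directory invisibly;
#'   `read_projection_set()` a [projection_set()].
#' @export
write_projection_set <- function(pset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- pset$geom
  meta <- list(format = "dtsalign-projections-v1",
               sad_mm = g$source_axis_distance_mm,
               sdd_mm = g$source_detector_distance_mm,
               detector = list(nu = g$detector$nu, nv = g$detector$nv,
                               pixel_mm = g$detector$pixel_mm),
               angles_deg = g$angles_deg,
               angular_spacing_deg = g$angular_spacing_deg,
               domain = pset$domain, dtype = "float32", byte_order = "little")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(n_angles(g))) {
    con <- file(file.path(dir, sprintf("view_%04d.raw", i)), "wb")
    writeBin(as.numeric(pset$images[, , i]), con, size = 4L, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' @rdname write_projection_set
#' @export
read_projection_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "dtsalign-projections-v1"))
    stop("not a dtsalign projection set: ", dir)
  det <- do.call(detector_spec, as.list(meta$detector))
  g <- scan_geometry(det, meta$angles_deg, sad_mm = meta$sad_mm,
                     sdd_mm = meta$sdd_mm,
                     angular_spacing_deg = meta$angular_spacing_deg)
  n <- n_angles(g)
  imgs <- array(0, c(det$nu, det$nv, n))
  for (i in seq_len(n)) {
    con <- file(file.path(dir, sprintf("view_%04d.raw", i)), "rb")
    imgs[, , i] <- readBin(con, "numeric", n = det$nu * det$nv, size = 4L,
                           endian = "little")
    close(con)
  }
  projection_set(imgs, g, domain = meta$domain)
}
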