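#' Detector specification
#'
#' Describes the flat-panel kV detector of the on-board imager: pixel grid and
#' (square) physical pixel pitch. The default mirrors a 512x384 panel with
#' 0.776 mm pixels, i.e. a 397 mm x 298 mm active area.
#'
#' @param nu,nv Number of detector columns (u, in the rotation plane) and rows
#'   (v, parallel to the patient longitudinal axis).
#' @param pixel_mm Physical detector pixel pitch in mm.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(nu = 512L, nv = 384L, pixel_mm = 0.776) {
  nu <- as.integer(nu); nv <- as.integer(nv)
  if (nu < 1L || nv < 1L) stop("detector dimensions must be >= 1")
  if (!is.finite(pixel_mm) || pixel_mm <= 0) stop("detector_pixel_mm must be > 0")
  structure(list(nu = nu, nv = nv, pixel_mm = pixel_mm), class = "detector_spec")
}

#' Cone-beam scan geometry
#'
#' Low-level constructor for an acquisition geometry: source-axis distance
#' (SAD), source-detector distance (SDD), detector grid, and an ordered list of
#' gantry angles. Angles are stored unwrapped (strictly monotone along the
#' rotation direction); use [gantry_frame()] to obtain per-angle source and
#' detector bases.
#'
#' Patient axes are LAT (x, left-right), LNG (y, superior-inferior), VRT
#' (z, anterior-posterior), origin at the isocenter. Gantry 0 degrees puts the
#' source anterior (+VRT); the central ray then points along -VRT, producing
#' the coronal view. Rotation is counterclockwise seen from the couch foot, so
#' gantry angles decrease along the standard 200-degree full-fan scan.
#'
#' @param detector A [detector_spec()].
#' @param angles_deg Ordered gantry angles in degrees (unwrapped, strictly
#'   monotone).
#' @param sad_mm Source-to-isocenter distance in mm.
#' @param sdd_mm Source-to-detector distance in mm; must exceed `sad_mm`.
#' @param angular_spacing_deg Nominal angular spacing (range / n projections).
#' @return An object of class `scan_geometry`.
#' @seealso [make_full_fan_geometry()], [select_arc()]
#' @export
scan_geometry <- function(detector, angles_deg, sad_mm = 1000, sdd_mm = 1500,
                          angular_spacing_deg = NULL) {
  if (!inherits(detector, "detector_spec")) detector <- do.call(detector_spec, detector)
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) < 1L) stop("at least one gantry angle is required")
  if (!(sdd_mm > sad_mm && sad_mm > 0)) stop("need sdd_mm > sad_mm > 0")
  if (length(angles_deg) > 1L) {
    d <- diff(angles_deg)
    if (!(all(d > 0) || all(d < 0)))
      stop("angles_deg must be strictly monotone along the rotation direction")
  }
  if (is.null(angular_spacing_deg)) {
    angular_spacing_deg <- if (length(angles_deg) > 1L)
      abs(stats::median(diff(angles_deg))) else 1.0
  }
  structure(list(
    source_axis_distance_mm = sad_mm,
    source_detector_distance_mm = sdd_mm,
    detector = detector,
    angles_deg = angles_deg,
    angular_spacing_deg = angular_spacing_deg
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  a <- x$angles_deg
  cat(sprintf(
    "<scan_geometry> %d angle(s), spacing %.4g deg, span [%.4g, %.4g] deg\n",
    length(a), x$angular_spacing_deg, min(a), max(a)))
  cat(sprintf("  SAD %.6g mm, SDD %.6g mm, detector %dx%d @ %.4g mm\n",
              x$source_axis_distance_mm, x$source_detector_distance_mm,
              x$detector$nu, x$detector$nv, x$detector$pixel_mm))
  invisible(x)
}

n_angles <- function(geom) length(geom$angles_deg)

#' Full-fan acquisition geometry
#'
#' Builds the evenly spaced gantry-angle set of a full-fan cone-beam scan.
#' The nominal angular spacing is `range_deg / n_projections` (the convention
#' under which the standard 200-degree, 375-view protocol has 0.53-degree
#' spacing). Views sit at the centers of the angular bins: the i-th angle is
#' `start_deg + sign * (i - 1/2) * spacing`, with the sign given by
#' `direction` ("ccw" = decreasing angles, the on-board imager's 20 to -180
#' degree sweep; "cw" = increasing). Bin centering makes arc view-counts
#' consistent with the protocol arithmetic: a 20-degree arc of the standard
#' full fan holds floor(20 / 0.533) = 37 views, a 40-degree arc 75.
#'
#' @param start_deg First gantry angle in degrees.
#' @param range_deg Total scan range in degrees, > 0.
#' @param n_projections Number of projections, >= 1.
#' @param detector A [detector_spec()].
#' @param sad_mm,sdd_mm Source-axis and source-detector distances (mm).
#' @param direction `"ccw"` (angles decrease from `start_deg`) or `"cw"`.
#' @return A [scan_geometry()].
#' @examples
#' g <- make_full_fan_geometry(20, 200, 375)
#' round(g$angular_spacing_deg, 2)  # 0.53
#' @export
make_full_fan_geometry <- function(start_deg = 20, range_deg = 200,
                                   n_projections = 375,
                                   detector = detector_spec(),
                                   sad_mm = 1000, sdd_mm = 1500,
                                   direction = c("ccw", "cw")) {
  direction <- match.arg(direction)
  n_projections <- as.integer(n_projections)
  if (is.na(n_projections) || n_projections < 1L)
    stop("n_projections must be a positive count")
  if (!is.finite(range_deg) || range_deg <= 0)
    stop("range_deg must be > 0")
  spacing <- range_deg / n_projections
  sgn <- if (direction == "ccw") -1 else 1
  angles <- start_deg + sgn * spacing * (seq_len(n_projections) - 0.5)
  scan_geometry(detector, angles, sad_mm = sad_mm, sdd_mm = sdd_mm,
                angular_spacing_deg = spacing)
}

#' Map angles to [0, 360)
#' @param angle_deg Angle(s) in degrees.
#' @return Equivalent angle(s) in `[0, 360)`.
#' @export
wrap_angle <- function(angle_deg) ((angle_deg %% 360) + 360) %% 360

#' Circular distance between angles (degrees)
#' @param a,b Angles in degrees.
#' @return Distance in `[0, 180]`.
#' @export
circular_distance <- function(a, b) {
  d <- abs(wrap_angle(a) - wrap_angle(b))
  pmin(d, 360 - d)
}

#' Select a narrow arc from a geometry
#'
#' Keeps exactly the gantry angles whose circular distance to `center_deg` is
#' at most `arc_deg / 2` (order preserved; 270 and -90 degrees are the same
#' direction). This is how the 20-80 degree DTS arcs are carved out of a
#' full-fan projection set: coronal DTS uses the arc centered at 0 degrees,
#' sagittal DTS the arc centered at 270 degrees.
#'
#' @param geom A [scan_geometry()].
#' @param center_deg Central angle of the arc in degrees.
#' @param arc_deg Total arc width in degrees, > 0.
#' @return A [scan_geometry()] restricted to the arc.
#' @export
select_arc <- function(geom, center_deg, arc_deg) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (!is.finite(arc_deg) || arc_deg <= 0) stop("arc_deg must be > 0")
  keep <- arc_members(geom$angles_deg, center_deg, arc_deg)
  if (!any(keep))
    stop(sprintf("no angles within %.6g deg of %.6g deg", arc_deg / 2, center_deg))
  scan_geometry(geom$detector, geom$angles_deg[keep],
                sad_mm = geom$source_axis_distance_mm,
                sdd_mm = geom$source_detector_distance_mm,
                angular_spacing_deg = geom$angular_spacing_deg)
}

# membership mask of angles in a circular window (tolerant to fp rounding)
arc_members <- function(angles_deg, center_deg, arc_deg) {
  circular_distance(angles_deg, center_deg) <= arc_deg / 2 + 1e-9
}

#' Projection-count savings of a DTS acquisition
#'
#' Percentage of cone-beam projections saved by acquiring `n_dts` projections
#' instead of the `n_full` of a full scan: `100 * (n_full - n_dts) / n_full`.
#' Two 20-degree arcs at the standard 0.53-degree spacing need about 75
#' projections versus 375 for a full fan, an 80 percent saving.
#'
#' @param n_dts Projections acquired for DTS (both arcs), `0 <= n_dts <= n_full`.
#' @param n_full Projections of the full scan, > 0.
#' @return Savings in percent.
#' @export
projection_savings <- function(n_dts, n_full) {
  if (!is.finite(n_full) || n_full <= 0) stop("n_full must be > 0")
  if (!is.finite(n_dts) || n_dts < 0) stop("n_dts must be >= 0")
  if (n_dts > n_full) stop("n_dts must not exceed n_full")
  100 * (n_full - n_dts) / n_full
}

#' Per-angle source/detector frame
#'
#' Orthonormal frame of the gantry at `angle_deg`: the source position, the
#' central-ray unit direction `d0` (source toward isocenter), the detector
#' in-plane unit axes `eu` (horizontal, in the rotation plane) and `ev`
#' (parallel to +LNG). All vectors in patient axes (LAT, LNG, VRT).
#'
#' @param geom A [scan_geometry()].
#' @param angle_deg Gantry angle in degrees.
#' @return List with `source`, `d0`, `eu`, `ev` (length-3 numeric vectors) and
#'   `det_center` (detector center position).
#' @export
gantry_frame <- function(geom, angle_deg) {
  th <- angle_deg * pi / 180
  sad <- geom$source_axis_distance_mm
  sdd <- geom$source_detector_distance_mm
  s <- c(-sin(th), 0, cos(th)) * sad
  d0 <- c(sin(th), 0, -cos(th))
  eu <- c(cos(th), 0, sin(th))
  ev <- c(0, 1, 0)
  list(source = s, d0 = d0, eu = eu, ev = ev, det_center = s + sdd * d0)
}

# physical (u, v) coordinate of the center of detector pixel (iu, iv), 1-based
detector_pixel_uv <- function(geom, iu, iv) {
  det <- geom$detector
  list(u = (iu - (det$nu + 1) / 2) * det$pixel_mm,
       v = (iv - (det$nv + 1) / 2) * det$pixel_mm)
}

#' Ray through a detector pixel
#'
#' Origin (the X-ray source) and unit direction, in patient axes, of the ray
#' from the source through the physical center of detector pixel `(iu, iv)`
#' at gantry angle `angle_deg`. At gantry 0 degrees the central ray is
#' `(0, 0, -1)`: anterior source, posterior-pointing beam, coronal view.
#'
#' @param geom A [scan_geometry()].
#' @param angle_deg Gantry angle in degrees.
#' @param iu,iv 1-based detector pixel indices (column, row).
#' @return List with `origin` and `direction` (unit norm), both length-3.
#' @export
source_and_ray <- function(geom, angle_deg, iu, iv) {
  det <- geom$detector
  if (iu < 1 || iu > det$nu || iv < 1 || iv > det$nv)
    stop(sprintf("pixel (%d, %d) outside %dx%d detector grid", iu, iv, det$nu, det$nv))
  fr <- gantry_frame(geom, angle_deg)
  uv <- detector_pixel_uv(geom, iu, iv)
  p <- fr$det_center + uv$u * fr$eu + uv$v * fr$ev
  d <- p - fr$source
  list(origin = fr$source, direction = d / sqrt(sum(d^2)))
}

#' Read a scan geometry from a JSON config
#'
#' Config keys: `sad_mm`, `sdd_mm`, `detector {nu, nv, pixel_mm}`,
#' `scan {start_deg, range_deg, n_projections}` and optionally
#' `arcs [{center_deg, arc_deg}]` (returned as an attribute).
#'
#' @param path Path to a JSON file.
#' @return A [scan_geometry()]; any `arcs` entry is attached as
#'   `attr(, "arcs")` (data frame with `center_deg`, `arc_deg`).
#' @export
read_geometry_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- do.call(detector_spec, as.list(cfg$detector))
  g <- make_full_fan_geometry(
    start_deg = cfg$scan$start_deg, range_deg = cfg$scan$range_deg,
    n_projections = cfg$scan$n_projections, detector = det,
    sad_mm = cfg$sad_mm %||% 1000, sdd_mm = cfg$sdd_mm %||% 1500)
  if (!is.null(cfg$arcs)) attr(g, "arcs") <- as.data.frame(cfg$arcs)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
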