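#' Build a phantom volume from a spec list
#'
#' @param spec List with `kind` (`"cube"` or `"pelvis"`) plus the arguments of
#'   [make_cube_phantom()] / [make_pelvis_phantom()].
#' @return A [voxel_volume()].
#' @export
make_phantom <- function(spec) {
  kind <- spec$kind %||% "cube"
  spec$kind <- NULL
  switch(kind,
         cube = do.call(make_cube_phantom, spec),
         pelvis = do.call(make_pelvis_phantom, spec),
         stop("unknown phantom kind: ", kind))
}

#' Forward-project a volume over the arcs needed for coronal + sagittal DTS
#'
#' Convenience wrapper: selects the union of the two narrow arcs (centered at
#' `centers_deg`) from a full-fan geometry and computes DRRs over it with the
#' fast engine.
#'
#' @param vol A [voxel_volume()].
#' @param geom Full-fan [scan_geometry()].
#' @param arc_deg Arc width in degrees.
#' @param centers_deg Arc centers (default coronal 0 and sagittal 270).
#' @return A [projection_set()] (line-integral domain).
#' @export
project_arcs <- function(vol, geom, arc_deg, centers_deg = c(0, 270)) {
  keep <- Reduce(`|`, lapply(centers_deg, function(cc)
    arc_members(geom$angles_deg, cc, arc_deg)))
  if (!any(keep)) stop("no projection angles inside the requested arcs")
  g <- scan_geometry(geom$detector, geom$angles_deg[keep],
                     sad_mm = geom$source_axis_distance_mm,
                     sdd_mm = geom$source_detector_distance_mm,
                     angular_spacing_deg = geom$angular_spacing_deg)
  drr_fast(vol, g)
}

#' One-call positioning simulation: phantom shift -> recovered shift
#'
#' Runs the full two-session workflow on synthetic data: reconstruct onboard
#' DTS (coronal + sagittal) from projections of the unshifted volume, shift
#' the volume by a known displacement, rebuild the reference DTS, and
#' register. The recovered [shift_result()] should match `shift_mm`.
#'
#' @param vol Planning volume ([voxel_volume()]).
#' @param geom Full-fan [scan_geometry()].
#' @param shift_mm Applied (LAT, LNG, VRT) displacement, mm.
#' @param arc_deg DTS arc width, degrees.
#' @param spec_cor,spec_sag Coronal / sagittal [dts_volume_spec()]s.
#' @param engine Reconstruction engine.
#' @param search_mm,n_focal_slices Registration parameters.
#' @return A [shift_result()].
#' @export
recover_shift <- function(vol, geom, shift_mm, arc_deg = 40,
                          spec_cor = dts_volume_spec("coronal"),
                          spec_sag = dts_volume_spec("sagittal"),
                          engine = "fast", search_mm = 10,
                          n_focal_slices = 5L) {
  ps_o <- project_arcs(vol, geom, arc_deg)
  ps_r <- project_arcs(shift_volume(vol, shift_mm), geom, arc_deg)
  odts_cor <- reconstruct_dts(subset_arc(ps_o, 0, arc_deg), spec_cor, engine)
  odts_sag <- reconstruct_dts(subset_arc(ps_o, 270, arc_deg), spec_sag, engine)
  rdts_cor <- reconstruct_dts(subset_arc(ps_r, 0, arc_deg), spec_cor, engine)
  rdts_sag <- reconstruct_dts(subset_arc(ps_r, 270, arc_deg), spec_sag, engine)
  two_session_registration(odts_cor, rdts_cor, odts_sag, rdts_sag,
                           search_mm = search_mm,
                           n_focal_slices = n_focal_slices)
}

#' Run the full simulation workflow from a JSON config
#'
#' Config keys: `phantom` (see [make_phantom()]), `sad_mm`, `sdd_mm`,
#' `detector {nu, nv, pixel_mm}`, `scan {start_deg, range_deg,
#' n_projections}`, `arc_deg`, `shift_mm`, `dts {pixel_mm, slice_mm,
#' n_inplane, n_slices}`, `search_mm`, `n_focal_slices`.
#'
#' @param config Path to a JSON file, or an equivalent list.
#' @return List with the applied shift, the recovered [shift_result()], and
#'   per-axis errors in mm.
#' @export
simulate_positioning <- function(config) {
  cfg <- if (is.character(config))
    jsonlite::read_json(config, simplifyVector = TRUE) else config
  vol <- make_phantom(as.list(cfg$phantom))
  det <- do.call(detector_spec, as.list(cfg$detector))
  geom <- make_full_fan_geometry(
    start_deg = cfg$scan$start_deg %||% 20,
    range_deg = cfg$scan$range_deg %||% 200,
    n_projections = cfg$scan$n_projections %||% 375,
    detector = det, sad_mm = cfg$sad_mm %||% 1000,
    sdd_mm = cfg$sdd_mm %||% 1500)
  dts <- as.list(cfg$dts %||% list())
  spec_cor <- dts_volume_spec("coronal",
                              pixel_mm = dts$pixel_mm %||% 0.5,
                              slice_mm = dts$slice_mm %||% 1.0,
                              n_inplane = dts$n_inplane %||% c(128L, 128L),
                              n_slices = dts$n_slices %||% 64L)
  spec_sag <- dts_volume_spec("sagittal",
                              pixel_mm = dts$pixel_mm %||% 0.5,
                              slice_mm = dts$slice_mm %||% 1.0,
                              n_inplane = dts$n_inplane %||% c(128L, 128L),
                              n_slices = dts$n_slices %||% 64L)
  shift <- rep_len(as.numeric(cfg$shift_mm %||% 0), 3L)
  res <- recover_shift(vol, geom, shift,
                       arc_deg = cfg$arc_deg %||% 40,
                       spec_cor = spec_cor, spec_sag = spec_sag,
                       search_mm = cfg$search_mm %||% 10,
                       n_focal_slices = cfg$n_focal_slices %||% 5L)
  list(applied_mm = shift, recovered = res,
       error_mm = c(lat = res$lat_mm - shift[1],
                    lng = res$lng_mm - shift[2],
                    vrt = res$vrt_mm - shift[3]))
}
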