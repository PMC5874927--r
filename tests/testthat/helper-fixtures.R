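# Shared fixtures, built lazily and cached for the whole test run.
# Scales are reduced from the desk scale so the full suite stays fast; the
# asserted bounds are never relaxed.

.fx <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small scale: 96 mm cube grid, 128x96 detector, 150-view full fan
geom_small <- function() memo("geom_small", function()
  make_full_fan_geometry(20, 200, 150, detector_spec(128, 96, 1.552)))

cube_small <- function() memo("cube_small", function()
  make_cube_phantom(50, 96, 1))

# cube projections over the union of the coronal/sagittal 80-degree arcs
cube_pset <- function() memo("cube_pset", function()
  project_arcs(cube_small(), geom_small(), 80))

# pelvis at 1.25 mm voxels; LNG extent trimmed so caps stay on the detector
pelvis_small <- function() memo("pelvis_small", function()
  make_pelvis_phantom(c(96, 96, 80), 1.25))

# tiny scale for oracle/fast comparisons (the oracle is pure R)
geom_tiny <- function() memo("geom_tiny", function()
  make_full_fan_geometry(20, 200, 150, detector_spec(64, 48, 3)))

cube_tiny <- function() memo("cube_tiny", function()
  make_cube_phantom(30, 48, 1.5))

pelvis_tiny <- function() memo("pelvis_tiny", function()
  make_pelvis_phantom(c(48, 48, 40), 1.5, body_semi_mm = c(26, 20)))

# wide in-plane DTS grids for edge-length work: the profile must reach
# background beyond the off-plane-blur lobes outside the cube faces
spec_cor_wide <- function(n_slices = 32L)
  dts_volume_spec("coronal", 0.5, 1, c(200L, 160L), n_slices)

spec_sag_wide <- function(n_slices = 32L)
  dts_volume_spec("sagittal", 0.5, 1, c(160L, 200L), n_slices)

spec_cor_reg <- function() dts_volume_spec("coronal", 0.5, 1, c(128L, 128L), 32L)
spec_sag_reg <- function() dts_volume_spec("sagittal", 0.5, 1, c(128L, 128L), 32L)

expect_max_abs <- function(x, bound) expect_lt(max(abs(x)), bound)
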