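#' 2D translational registration by normalized cross-correlation
#'
#' Registers two DTS stacks of identical specification by (1) averaging the
#' central `n_focal_slices` planes of each into a focal image, (2) exhaustive
#' integer-pixel normalized cross-correlation over lags within `search_mm`,
#' and (3) parabolic sub-pixel refinement of the peak in each axis. Ties at
#' the integer peak are broken toward the smaller-magnitude shift. The
#' returned shift is the displacement of the moving image's content relative
#' to the fixed image, in mm along the two in-plane axes.
#'
#' @param fixed,moving DTS [voxel_volume()]s with identical specs, or plain
#'   in-plane matrices carrying a `pixel_mm` attribute.
#' @param search_mm Search radius in mm (must be at least the expected shift).
#' @param n_focal_slices Central planes averaged into the focal image.
#' @return List with `shift_mm` (length 2, in-plane axes), `ncc_peak`, and
#'   `ncc` (the integer-lag correlation surface with lag vectors `du`, `dv`).
#' @export
register_translation_2d <- function(fixed, moving, search_mm = 10,
                                    n_focal_slices = 5L) {
  as_focal <- function(x) {
    if (inherits(x, "voxel_volume")) focal_image(x, n_focal_slices)
    else x
  }
  fim <- as_focal(fixed); mim <- as_focal(moving)
  if (!identical(dim(fim), dim(mim))) stop("focal images must have identical dims")
  px <- attr(fim, "pixel_mm")
  if (is.null(px)) px <- attr(mim, "pixel_mm")
  if (is.null(px)) stop("pixel_mm attribute required")
  px <- rep_len(as.numeric(px), 2L)
  if (stats::sd(fim) == 0 || stats::sd(mim) == 0)
    stop("no structure to register (constant focal image)")
  r1 <- ceiling(search_mm / px[1]); r2 <- ceiling(search_mm / px[2])
  n1 <- nrow(fim); n2 <- ncol(fim)
  if (2 * r1 >= n1 || 2 * r2 >= n2) stop("search radius too large for the image")
  lags1 <- -r1:r1; lags2 <- -r2:r2
  ncc <- matrix(-Inf, length(lags1), length(lags2))
  for (a in seq_along(lags1)) {
    d1 <- lags1[a]
    i1 <- max(1L, 1L - d1):min(n1, n1 - d1)
    for (b in seq_along(lags2)) {
      d2 <- lags2[b]
      i2 <- max(1L, 1L - d2):min(n2, n2 - d2)
      Fs <- fim[i1, i2]
      Ms <- mim[i1 + d1, i2 + d2]
      if (stats::sd(Fs) == 0 || stats::sd(Ms) == 0) next
      ncc[a, b] <- stats::cor(as.vector(Fs), as.vector(Ms))
    }
  }
  peak <- max(ncc)
  cand <- which(ncc == peak, arr.ind = TRUE)
  mag <- (lags1[cand[, 1]] * px[1])^2 + (lags2[cand[, 2]] * px[2])^2
  best <- cand[which.min(mag), ]
  d1 <- lags1[best[1]]; d2 <- lags2[best[2]]
  refine <- function(idx, along) {
    cm <- ncc; v <- if (along == 1) cm[, best[2]] else cm[best[1], ]
    i <- idx
    if (i <= 1L || i >= length(v)) return(0)
    c0 <- v[i]; cm1 <- v[i - 1]; cp1 <- v[i + 1]
    den <- cm1 - 2 * c0 + cp1
    if (!is.finite(den) || den >= 0) return(0)
    delta <- 0.5 * (cm1 - cp1) / den
    max(min(delta, 0.5), -0.5)
  }
  s1 <- (d1 + refine(best[1], 1)) * px[1]
  s2 <- (d2 + refine(best[2], 2)) * px[2]
  list(shift_mm = c(s1, s2), ncc_peak = peak,
       ncc = list(values = ncc, du = lags1 * px[1], dv = lags2 * px[2]))
}

#' Shift result of a two-session DTS registration
#'
#' @param lat_mm,vrt_mm Lateral and vertical shifts, mm.
#' @param lng_coronal_mm,lng_sagittal_mm The two longitudinal estimates, mm.
#' @param ncc_coronal,ncc_sagittal Per-session NCC peak values.
#' @return Object of class `shift_result`; `lng_mm` is the mean of the two
#'   session estimates.
#' @export
shift_result <- function(lat_mm, lng_coronal_mm, lng_sagittal_mm, vrt_mm,
                         ncc_coronal = NA_real_, ncc_sagittal = NA_real_) {
  structure(list(
    lat_mm = lat_mm,
    lng_mm = (lng_coronal_mm + lng_sagittal_mm) / 2,
    vrt_mm = vrt_mm,
    lng_coronal_mm = lng_coronal_mm,
    lng_sagittal_mm = lng_sagittal_mm,
    ncc_peak = c(coronal = ncc_coronal, sagittal = ncc_sagittal)
  ), class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("<shift_result> LAT %.2f mm, LNG %.2f mm, VRT %.2f mm\n",
              x$lat_mm, x$lng_mm, x$vrt_mm))
  cat(sprintf("  LNG per session: coronal %.2f, sagittal %.2f mm; NCC %.3f / %.3f\n",
              x$lng_coronal_mm, x$lng_sagittal_mm,
              x$ncc_peak[["coronal"]], x$ncc_peak[["sagittal"]]))
  invisible(x)
}

#' Two-session DTS registration
#'
#' Recovers the 3D target shift from two 2D sessions: the coronal
#' ODTS-vs-RDTS match yields (LAT, LNG), the sagittal match yields (LNG,
#' VRT), and the final LNG is the mean of the two session estimates. The
#' returned displacements are those of the reference (RDTS) content relative
#' to the onboard (ODTS) content, i.e. the couch correction that moves the
#' onboard anatomy onto the planned position.
#'
#' @param odts_cor,rdts_cor Coronal onboard / reference DTS volumes.
#' @param odts_sag,rdts_sag Sagittal onboard / reference DTS volumes.
#' @param search_mm,n_focal_slices Passed to [register_translation_2d()].
#' @return A [shift_result()].
#' @export
two_session_registration <- function(odts_cor, rdts_cor, odts_sag, rdts_sag,
                                     search_mm = 10, n_focal_slices = 5L) {
  run <- function(fixed, moving, session) {
    tryCatch(register_translation_2d(fixed, moving, search_mm, n_focal_slices),
             error = function(e)
               stop(sprintf("%s registration session failed: %s",
                            session, conditionMessage(e)), call. = FALSE))
  }
  cor_res <- run(odts_cor, rdts_cor, "coronal")    # in-plane axes (LAT, LNG)
  sag_res <- run(odts_sag, rdts_sag, "sagittal")   # in-plane axes (LNG, VRT)
  shift_result(lat_mm = cor_res$shift_mm[1],
               lng_coronal_mm = cor_res$shift_mm[2],
               lng_sagittal_mm = sag_res$shift_mm[1],
               vrt_mm = sag_res$shift_mm[2],
               ncc_coronal = cor_res$ncc_peak,
               ncc_sagittal = sag_res$ncc_peak)
}
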