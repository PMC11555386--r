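#' Acquisition settings for simulated and real imaging data
#'
#' Bundles the camera/acquisition geometry used throughout the pipeline.
#' Defaults describe the TIRF/dSTORM set-up the assay was developed on:
#' a 103.5 nm camera pixel, a 512 x 512 pixel field of view (FOV), 8000
#' dSTORM frames at 30 ms exposure, and a 15 nm super-resolution
#' reconstruction pixel (about half the 30 nm resolution limit).
#'
#' Coordinates are in nm with the origin at the top-left FOV corner,
#' x to the right and y downwards; pixel indices are 0-based with
#' half-open pixel intervals.
#'
#' @param camera_pixel_nm camera pixel size in nm.
#' @param fov_px integer pair, FOV width and height in camera pixels.
#' @param n_frames number of dSTORM frames per acquisition.
#' @param exposure_ms camera exposure time per frame in ms.
#' @param render_pixel_nm reconstruction (histogram rendering) pixel in nm;
#'   must not exceed the camera pixel.
#' @return An object of class `acquisition_settings`.
#' @export
#' @examples
#' s <- acquisition_settings()
#' fov_nm(s)
acquisition_settings <- function(camera_pixel_nm = 103.5,
                                 fov_px = c(512L, 512L),
                                 n_frames = 8000L,
                                 exposure_ms = 30,
                                 render_pixel_nm = 15) {
  check_scalar_positive(camera_pixel_nm, "camera_pixel_nm")
  check_scalar_positive(n_frames, "n_frames")
  check_scalar_positive(exposure_ms, "exposure_ms")
  check_scalar_positive(render_pixel_nm, "render_pixel_nm")
  if (length(fov_px) == 1L) fov_px <- rep(fov_px, 2L)
  if (length(fov_px) != 2L || any(!is.finite(fov_px)) || any(fov_px <= 0)) {
    abort("`fov_px` must be one or two positive integers.")
  }
  if (render_pixel_nm > camera_pixel_nm) {
    abort("`render_pixel_nm` must not exceed `camera_pixel_nm`.")
  }
  structure(
    list(
      camera_pixel_nm = camera_pixel_nm,
      fov_px = as.integer(round(fov_px)),
      n_frames = as.integer(round(n_frames)),
      exposure_ms = exposure_ms,
      render_pixel_nm = render_pixel_nm
    ),
    class = "acquisition_settings"
  )
}

#' @export
print.acquisition_settings <- function(x, ...) {
  cat("Acquisition settings\n")
  cat(sprintf("  camera pixel : %.1f nm\n", x$camera_pixel_nm))
  cat(sprintf("  FOV          : %d x %d px (%.1f x %.1f um)\n",
              x$fov_px[1], x$fov_px[2],
              x$fov_px[1] * x$camera_pixel_nm / 1000,
              x$fov_px[2] * x$camera_pixel_nm / 1000))
  cat(sprintf("  frames       : %d @ %.0f ms\n", x$n_frames, x$exposure_ms))
  cat(sprintf("  render pixel : %.1f nm\n", x$render_pixel_nm))
  invisible(x)
}

#' Field-of-view extent in nm
#'
#' @param settings an [acquisition_settings()] object.
#' @return Numeric pair `c(x, y)`: FOV extent in nm.
#' @export
fov_nm <- function(settings) {
  stopifnot(inherits(settings, "acquisition_settings"))
  settings$fov_px * settings$camera_pixel_nm
}

#' Spot-detection parameters for diffraction-limited counting
#'
#' Parameters of the path-connected aggregate recognition used by
#' [detect_spots()]: a large-radius median-filter background estimate is
#' subtracted, pixels above `k_sigma` robust noise SDs are grouped into
#' 8-connected components, and components outside the area band are
#' discarded.
#'
#' @param k_sigma detection threshold in units of the robust noise SD
#'   (median absolute deviation x 1.4826).
#' @param min_area_px,max_area_px accepted component area band in pixels.
#' @param background_radius_px radius of the median background filter.
#' @return An object of class `spot_params`.
#' @export
spot_params <- function(k_sigma = 5,
                        min_area_px = 2L,
                        max_area_px = 200L,
                        background_radius_px = 20L) {
  check_scalar_positive(k_sigma, "k_sigma")
  check_scalar_positive(min_area_px, "min_area_px")
  check_scalar_positive(max_area_px, "max_area_px")
  check_scalar_positive(background_radius_px, "background_radius_px")
  if (min_area_px > max_area_px) {
    abort("`min_area_px` must not exceed `max_area_px`.")
  }
  structure(
    list(
      k_sigma = k_sigma,
      min_area_px = as.integer(min_area_px),
      max_area_px = as.integer(max_area_px),
      background_radius_px = as.integer(background_radius_px)
    ),
    class = "spot_params"
  )
}

#' @export
print.spot_params <- function(x, ...) {
  cat(sprintf(
    "Spot detection: threshold %.1f sigma, area %d-%d px, background radius %d px\n",
    x$k_sigma, x$min_area_px, x$max_area_px, x$background_radius_px))
  invisible(x)
}
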