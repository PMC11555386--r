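#' Simulate a diffraction-limited TIRF image stack
#'
#' Emulates the diffraction-limited counting acquisition (50 frames at
#' 50 ms exposure in the assay): every frame is an independent Poisson
#' realisation of a constant background plus Gaussian point-spread
#' function (PSF) spots at fixed positions.  Positions are continuous
#' 0-based camera-pixel coordinates; a spot at the FOV corner is legal
#' (its PSF is simply clipped).
#'
#' @param spots a data frame with columns `x_px`, `y_px`, `brightness`
#'   (expected photons per frame per spot); may have zero rows.
#' @param settings an [acquisition_settings()] object (`fov_px` is used).
#' @param n_frames number of frames (default 50).
#' @param background_mean expected background photons per pixel per frame;
#'   must be positive.
#' @param psf_sigma_px PSF standard deviation in camera pixels (~1.3 px).
#' @param seed optional RNG seed.
#' @return A list of class `tirf_sim` with `stack` (array
#'   `fov_y x fov_x x n_frames`) and `truth` (the spot table).
#' @export
#' @examples
#' sim <- simulate_tirf_stack(
#'   tibble::tibble(x_px = 10, y_px = 12, brightness = 200),
#'   acquisition_settings(fov_px = 32), seed = 1)
#' dim(sim$stack)
simulate_tirf_stack <- function(spots,
                                settings = acquisition_settings(),
                                n_frames = 50L,
                                background_mean = 10,
                                psf_sigma_px = 1.3,
                                seed = NULL) {
  if (!is.data.frame(spots)) abort("`spots` must be a data frame.")
  if (nrow(spots) > 0) {
    req <- c("x_px", "y_px", "brightness")
    miss <- setdiff(req, names(spots))
    if (length(miss)) abort(sprintf("`spots` lacks column(s): %s.",
                                    paste(miss, collapse = ", ")))
    if (any(spots$brightness <= 0)) abort("Spot `brightness` must be positive.")
  }
  check_scalar_positive(background_mean, "background_mean")
  check_scalar_positive(psf_sigma_px, "psf_sigma_px")
  check_scalar_positive(n_frames, "n_frames")
  nx <- settings$fov_px[1]
  ny <- settings$fov_px[2]
  expected <- matrix(background_mean, nrow = ny, ncol = nx)
  if (nrow(spots) > 0) {
    half <- ceiling(5 * psf_sigma_px)
    for (i in seq_len(nrow(spots))) {
      cx <- spots$x_px[i]
      cy <- spots$y_px[i]
      xs <- max(0L, floor(cx) - half):min(nx - 1L, floor(cx) + half)
      ys <- max(0L, floor(cy) - half):min(ny - 1L, floor(cy) + half)
      if (!length(xs) || !length(ys)) next
      gx <- exp(-((xs + 0.5 - cx - 0.5)^2) / (2 * psf_sigma_px^2))
      gy <- exp(-((ys + 0.5 - cy - 0.5)^2) / (2 * psf_sigma_px^2))
      g <- outer(gy, gx) / (2 * pi * psf_sigma_px^2)
      expected[ys + 1L, xs + 1L] <-
        expected[ys + 1L, xs + 1L] + spots$brightness[i] * g
    }
  }
  with_seed(seed, {
    stack <- array(
      rpois(ny * nx * n_frames, rep(as.vector(expected), n_frames)),
      dim = c(ny, nx, n_frames)
    )
    structure(list(stack = stack, truth = tibble::as_tibble(spots),
                   background_mean = background_mean,
                   psf_sigma_px = psf_sigma_px),
              class = "tirf_sim")
  })
}

#' @export
print.tirf_sim <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("Simulated TIRF stack: %d x %d px, %d frames, %d true spot(s)\n",
              d[2], d[1], d[3], nrow(x$truth)))
  invisible(x)
}
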