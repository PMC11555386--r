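#' Render a localization table into a 2D count image
#'
#' Histogram rendering: each localization increments the reconstruction
#' pixel containing it, so the pixel sum equals the number of
#' localizations.  The default reconstruction pixel is 15 nm, about half
#' the 30 nm spatial resolution limit of the assay.
#'
#' @param locs localization tibble with `x_nm`, `y_nm` columns.
#' @param render_pixel_nm reconstruction pixel size in nm.
#' @param fov optional FOV extent in nm (`c(x, y)` or a single number);
#'   defaults to the extent of `settings`, or to the data extent if
#'   neither is given.
#' @param settings optional [acquisition_settings()] supplying the FOV.
#' @return Integer matrix (rows = y, cols = x) with attributes
#'   `render_pixel_nm` and `fov_nm`.
#' @export
#' @examples
#' locs <- tibble::tibble(x_nm = c(5, 20), y_nm = c(5, 20))
#' sum(render_localizations(locs, 15, fov = 45))
render_localizations <- function(locs, render_pixel_nm = 15,
                                 fov = NULL, settings = NULL) {
  check_scalar_positive(render_pixel_nm, "render_pixel_nm")
  if (is.null(fov)) {
    fov <- if (!is.null(settings)) fov_nm(settings) else {
      if (nrow(locs) == 0) c(render_pixel_nm, render_pixel_nm) else
        c(max(locs$x_nm), max(locs$y_nm)) + render_pixel_nm
    }
  }
  if (length(fov) == 1L) fov <- rep(fov, 2L)
  nx <- max(1L, as.integer(ceiling(fov[1] / render_pixel_nm)))
  ny <- max(1L, as.integer(ceiling(fov[2] / render_pixel_nm)))
  img <- matrix(0L, ny, nx)
  if (nrow(locs) > 0) {
    ix <- pmin(pmax(floor(locs$x_nm / render_pixel_nm), 0), nx - 1L)
    iy <- pmin(pmax(floor(locs$y_nm / render_pixel_nm), 0), ny - 1L)
    img[] <- tabulate(ix * ny + iy + 1L, nbins = nx * ny)
  }
  attr(img, "render_pixel_nm") <- render_pixel_nm
  attr(img, "fov_nm") <- fov
  img
}
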