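#' Segment aggregates from a rendered localization image
#'
#' Binarizes the count image at >= 1 localization, labels 8-connected
#' (path-connected) components, discards components carrying fewer than
#' `min_localizations` localizations, and computes per-aggregate
#' morphology: area A (pixel count x pixel area), perimeter P (Crofton
#' approximation on the component mask), circularity C = 4*pi*A/P^2
#' (clipped to 1, since discrete perimeters can undershoot), and the
#' equivalent circular diameters d_area = 2*sqrt(A/pi) and
#' d_perim = P/pi.  Centroids are localization-count weighted.
#'
#' @param img rendered count image from [render_localizations()].
#' @param min_localizations minimum localizations per kept aggregate.
#' @param render_pixel_nm reconstruction pixel in nm; defaults to the
#'   attribute stored by [render_localizations()].
#' @return Tibble with one row per aggregate: `aggregate_id`, `n_locs`,
#'   `area_um2`, `perimeter_um`, `circularity`, `d_area_um`,
#'   `d_perim_um`, `centroid_x_nm`, `centroid_y_nm`.  The attribute
#'   `discarded_localizations` counts localizations in rejected
#'   components (so kept + discarded = total).
#' @export
segment_aggregates <- function(img, min_localizations = 5L,
                               render_pixel_nm = attr(img, "render_pixel_nm")) {
  if (is.null(render_pixel_nm)) {
    abort("`render_pixel_nm` missing: pass it or use a rendered image.")
  }
  check_scalar_positive(render_pixel_nm, "render_pixel_nm")
  empty <- tibble::tibble(
    aggregate_id = integer(), n_locs = integer(), area_um2 = numeric(),
    perimeter_um = numeric(), circularity = numeric(), d_area_um = numeric(),
    d_perim_um = numeric(), centroid_x_nm = numeric(), centroid_y_nm = numeric()
  )
  labels <- label_components(img)
  k <- max(labels)
  if (k == 0L) {
    attr(empty, "discarded_localizations") <- 0L
    return(empty)
  }
  px_um <- render_pixel_nm / 1000
  nr <- nrow(img)
  pxi <- which(labels > 0L)
  lab <- labels[pxi]
  cnt <- img[pxi]
  r <- ((pxi - 1L) %% nr) + 1L
  c <- ((pxi - 1L) %/% nr) + 1L
  n_locs <- as.integer(tapply(cnt, lab, sum))
  keep <- which(n_locs >= min_localizations)
  discarded <- sum(n_locs[-keep]) # total locs in rejected components
  if (length(keep) == 0L) {
    attr(empty, "discarded_localizations") <- as.integer(sum(n_locs))
    return(empty)
  }
  rows <- split(seq_along(lab), lab)
  out <- purrr::map(keep, function(j) {
    ii <- rows[[j]]
    rj <- r[ii]; cj <- c[ii]; wj <- cnt[ii]
    # per-component mask on its bounding box
    mask <- matrix(FALSE, diff(range(rj)) + 1L, diff(range(cj)) + 1L)
    mask[cbind(rj - min(rj) + 1L, cj - min(cj) + 1L)] <- TRUE
    a_um2 <- length(ii) * px_um^2
    p_um <- crofton_perimeter(mask) * px_um
    tibble::tibble(
      n_locs = sum(wj),
      area_um2 = a_um2,
      perimeter_um = p_um,
      circularity = min(1, 4 * pi * a_um2 / p_um^2),
      # pixel centers: pixel (r, c) is centered at (c - 0.5, r - 0.5) px
      centroid_x_nm = sum(wj * (cj - 0.5)) / sum(wj) * render_pixel_nm,
      centroid_y_nm = sum(wj * (rj - 0.5)) / sum(wj) * render_pixel_nm
    )
  }) |> dplyr::bind_rows()
  out <- dplyr::mutate(out,
    aggregate_id = dplyr::row_number(),
    d_area_um = area_to_diameter(.data$area_um2),
    d_perim_um = perimeter_to_diameter(.data$perimeter_um),
    .before = 1
  )
  out <- dplyr::relocate(out, "aggregate_id", "n_locs", "area_um2",
                         "perimeter_um", "circularity", "d_area_um",
                         "d_perim_um")
  attr(out, "discarded_localizations") <- as.integer(discarded)
  attr(out, "render_pixel_nm") <- render_pixel_nm
  out
}

#' Equivalent circular diameter from area
#'
#' The size of an aggregate is reported as the diameter of the circle
#' with the same area: d = 2*sqrt(A/pi).
#'
#' @param area_um2 areas in um^2 (must be positive).
#' @return Diameters in um.
#' @export
#' @examples
#' area_to_diameter(pi / 4) # exactly 1 um
area_to_diameter <- function(area_um2) {
  if (length(area_um2) == 0) return(numeric())
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    abort("Areas must be positive and finite.")
  }
  2 * sqrt(area_um2 / pi)
}

#' Equivalent circular diameter from perimeter
#'
#' The diameter of the circle with the same perimeter: d = P/pi.
#'
#' @param perimeter_um perimeters in um (must be positive).
#' @return Diameters in um.
#' @export
#' @examples
#' perimeter_to_diameter(pi) # exactly 1 um
perimeter_to_diameter <- function(perimeter_um) {
  if (length(perimeter_um) == 0) return(numeric())
  if (any(!is.finite(perimeter_um)) || any(perimeter_um <= 0)) {
    abort("Perimeters must be positive and finite.")
  }
  perimeter_um / pi
}

#' Filter aggregates below the spatial resolution limit
#'
#' Species smaller than the ~30 nm resolution limit all appear the same
#' size and are excluded, so that the analysis quantifies genuine
#' aggregates rather than unresolved monomers.
#'
#' @param aggregates tibble from [segment_aggregates()] (needs
#'   `d_area_um`).
#' @param min_diameter_um resolution cut in um (default 0.03 = 30 nm).
#' @return The retained rows, with attribute `excluded_fraction`.
#' @export
filter_by_resolution <- function(aggregates, min_diameter_um = 0.03) {
  check_scalar_positive(min_diameter_um, "min_diameter_um")
  if (!"d_area_um" %in% names(aggregates)) {
    abort("`aggregates` must have a `d_area_um` column.")
  }
  keep <- aggregates$d_area_um >= min_diameter_um
  out <- aggregates[keep, , drop = FALSE]
  attr(out, "excluded_fraction") <-
    if (nrow(aggregates) == 0) 0 else mean(!keep)
  out
}

#' Frame-sufficiency diagnostics for a dSTORM acquisition
#'
#' Re-runs rendering and segmentation using only the frames before each
#' breakpoint and reports the interquartile range (IQR) of the area and
#' circularity distributions: when the IQRs stop changing, morphology is
#' sampled sufficiently (for this assay, stable from 8000 frames).  The
#' localization count per inter-breakpoint frame block is also reported
#' as a photobleaching check — with stable blinking the blocks are
#' Poisson-equal.
#'
#' @param locs localization tibble (`frame`, `x_nm`, `y_nm`).
#' @param breakpoints increasing frame breakpoints.
#' @param n_frames total frames in the acquisition; defaults to the
#'   table's `n_frames` attribute.
#' @param render_pixel_nm reconstruction pixel in nm.
#' @param fov FOV extent in nm (see [render_localizations()]).
#' @param min_localizations per-aggregate localization floor.
#' @param min_diameter_um resolution cut applied before the IQRs.
#' @return Tibble with one row per breakpoint: `breakpoint`,
#'   `n_localizations` (cumulative), `n_aggregates`, `iqr_area_um2`,
#'   `iqr_circularity`, `block_localizations` (count in
#'   `(previous, this]` frame block).
#' @export
frame_sufficiency <- function(locs,
                              breakpoints = c(2000, 5000, 8000, 11000,
                                              14000, 16000),
                              n_frames = attr(locs, "n_frames"),
                              render_pixel_nm = 15,
                              fov = NULL,
                              min_localizations = 5L,
                              min_diameter_um = 0.03) {
  breakpoints <- sort(unique(breakpoints))
  if (is.null(n_frames)) n_frames <- max(locs$frame) + 1L
  if (any(breakpoints > n_frames)) {
    abort(sprintf("Breakpoint(s) beyond the acquisition (%d frames): %s.",
                  n_frames,
                  paste(breakpoints[breakpoints > n_frames], collapse = ", ")))
  }
  if (is.null(fov) && nrow(locs) > 0) {
    fov <- c(max(locs$x_nm), max(locs$y_nm)) + render_pixel_nm
  }
  prev <- c(0, head(breakpoints, -1))
  purrr::map2(breakpoints, prev, function(bp, lo) {
    sub <- locs[locs$frame < bp, , drop = FALSE]
    img <- render_localizations(sub, render_pixel_nm, fov = fov)
    agg <- segment_aggregates(img, min_localizations)
    agg <- filter_by_resolution(agg, min_diameter_um)
    tibble::tibble(
      breakpoint = bp,
      n_localizations = nrow(sub),
      n_aggregates = nrow(agg),
      iqr_area_um2 = if (nrow(agg)) IQR(agg$area_um2) else NA_real_,
      iqr_circularity = if (nrow(agg)) IQR(agg$circularity) else NA_real_,
      block_localizations = sum(locs$frame >= lo & locs$frame < bp)
    )
  }) |> dplyr::bind_rows()
}
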