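#' Average a diffraction-limited image stack
#'
#' Pixel-wise mean of a multi-frame stack.  Frame averaging pools the
#' photon statistics of the (static) field, improving the spot
#' signal-to-noise ratio by about the square root of the frame count
#' before detection.
#'
#' @param stack a 3D array (`y` x `x` x `frame`), a list of matrices, or
#'   a single matrix (returned as-is).
#' @return A numeric matrix: the mean image.
#' @export
#' @examples
#' average_stack(array(1, dim = c(4, 4, 10)))[1, 1]
average_stack <- function(stack) {
  if (inherits(stack, "tirf_sim")) stack <- stack$stack
  if (is.list(stack) && !is.data.frame(stack)) {
    if (length(stack) == 0) abort("Empty stack: nothing to average.")
    stack <- simplify2array(stack)
  }
  if (is.matrix(stack)) return(stack * 1.0)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    abort("`stack` must be a non-empty 3D array or list of matrices.")
  }
  rowMeans(stack, dims = 2L)
}

#' Detect diffraction-limited spots in a field of view
#'
#' Path-connected aggregate recognition: a large-radius median-filter
#' background is subtracted; the residual noise scale is estimated
#' robustly (median absolute deviation x 1.4826, stable against bright
#' spots); pixels above `k_sigma` x sigma are grouped into 8-connected
#' components; components outside the `[min_area_px, max_area_px]` band
#' are discarded; the survivors are counted with centroids.  The
#' threshold is sigma-relative, so counting is invariant to positive
#' intensity rescaling.  Spots touching the image border are kept.
#'
#' @param image a 2D numeric matrix (e.g. from [average_stack()]).
#' @param params a [spot_params()] object.
#' @param fov optional FOV identifier carried into the result.
#' @return An object of class `fov_count`: list with `fov`, `count`,
#'   `centroids` (tibble `x_px`, `y_px`, `area_px`, 0-based pixel-center
#'   coordinates), `background` (median background level) and `sigma`
#'   (robust noise SD).
#' @export
#' @examples
#' img <- matrix(0, 32, 32); img[10:11, 10:11] <- 50
#' detect_spots(img)$count
detect_spots <- function(image, params = spot_params(), fov = NA) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a 2D numeric matrix.")
  }
  rng <- range(image)
  if (rng[1] == rng[2]) {
    if (rng[1] > 0) abort("Uninformative image: all pixels saturated at one value.")
    # blank image: nothing to count
    return(new_fov_count(fov, tibble::tibble(x_px = numeric(),
                                             y_px = numeric(),
                                             area_px = integer()),
                         background = rng[1], sigma = 0, params = params))
  }
  scale <- max(abs(rng))
  bg <- EBImage::medianFilter(image / scale, params$background_radius_px) * scale
  resid <- image - bg
  sigma <- mad(resid)
  if (sigma == 0) sigma <- sd(resid)
  mask <- resid > params$k_sigma * sigma
  labels <- label_components(mask + 0L)
  k <- max(labels)
  cent <- tibble::tibble(x_px = numeric(), y_px = numeric(), area_px = integer())
  if (k > 0) {
    px <- which(labels > 0)
    lab <- labels[px]
    r <- ((px - 1L) %% nrow(image)) + 1L
    c <- ((px - 1L) %/% nrow(image)) + 1L
    area <- tabulate(lab, k)
    keep <- which(area >= params$min_area_px & area <= params$max_area_px)
    if (length(keep)) {
      cent <- tibble::tibble(
        # pixel centers, 0-based convention: pixel i spans [i-1, i)
        x_px = tapply(c - 0.5, lab, mean)[keep],
        y_px = tapply(r - 0.5, lab, mean)[keep],
        area_px = area[keep]
      )
    }
  }
  new_fov_count(fov, cent, background = median(bg), sigma = sigma,
                params = params)
}

new_fov_count <- function(fov, centroids, background, sigma, params) {
  structure(
    list(fov = fov, count = nrow(centroids), centroids = centroids,
         background = background, sigma = sigma, params = params),
    class = "fov_count"
  )
}

#' @export
print.fov_count <- function(x, ...) {
  cat(sprintf("FOV %s: %d spot(s); background %.2f, noise sigma %.3f\n",
              as.character(x$fov), x$count, x$background, x$sigma))
  invisible(x)
}

#' Summarize spot counts across the fields of view of one sample
#'
#' Each sample well is imaged at several FOVs (12 in the standard
#' protocol) and reported as the mean count per FOV.
#'
#' @param fov_counts a list of [detect_spots()] results, or a numeric
#'   vector of per-FOV counts.
#' @param expected_fov FOVs expected per sample (flagged when fewer).
#' @return One-row tibble: `n_fov`, `mean_count`, `sd_count`,
#'   `sufficient_fov`.
#' @export
#' @examples
#' summarize_sample(c(10, 12, 8))
summarize_sample <- function(fov_counts, expected_fov = 12L) {
  if (is.list(fov_counts)) {
    fov_counts <- vapply(fov_counts, function(x) {
      if (inherits(x, "fov_count")) x$count else as.numeric(x)
    }, numeric(1))
  }
  if (length(fov_counts) == 0) abort("No FOV counts supplied.")
  tibble::tibble(
    n_fov = length(fov_counts),
    mean_count = mean(fov_counts),
    sd_count = if (length(fov_counts) > 1) sd(fov_counts) else 0,
    sufficient_fov = length(fov_counts) >= expected_fov
  )
}

#' Compare a sample against its assay control wells
#'
#' Each experiment carries quality-control wells (buffer-only,
#' no-capture-antibody, and optionally a non-target detection IgG).
#' The sample passes when its mean count exceeds every control mean by
#' the required factor.  Raw counts are never background-subtracted:
#' controls are compared against, not removed.
#'
#' @param sample_mean mean spot count per FOV of the sample.
#' @param controls named numeric vector of control-well mean counts,
#'   e.g. `c(buffer = 2, no_capture = 5)`.
#' @param min_ratio required sample/control ratio (default 3).
#' @return Tibble with one row per control (`control`, `mean_count`,
#'   `ratio`, `pass`) and attribute `overall_pass`.
#' @export
#' @examples
#' control_assessment(60, c(no_capture = 5))
control_assessment <- function(sample_mean, controls, min_ratio = 3) {
  check_scalar_positive(min_ratio, "min_ratio")
  if (length(controls) == 0 || is.null(names(controls))) {
    warn("No named control wells supplied; assessment is vacuous.")
    out <- tibble::tibble(control = character(), mean_count = numeric(),
                          ratio = numeric(), pass = logical())
    attr(out, "overall_pass") <- NA
    return(out)
  }
  known <- c("buffer", "no_capture", "detection_IgG")
  if (!any(names(controls) %in% known)) {
    warn(sprintf("None of the standard control wells (%s) present.",
                 paste(known, collapse = ", ")))
  }
  ratio <- ifelse(controls > 0, sample_mean / controls, Inf)
  out <- tibble::tibble(
    control = names(controls),
    mean_count = as.numeric(controls),
    ratio = as.numeric(ratio),
    pass = as.numeric(ratio) >= min_ratio
  )
  attr(out, "overall_pass") <- all(out$pass)
  out
}
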