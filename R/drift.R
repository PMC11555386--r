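#' Correct lateral drift in a localization table
#'
#' Redundant block cross-correlation: the acquisition is split into
#' frame blocks, each block is rendered to a count image over a common
#' grid, lightly blurred, and registered to the first block by the
#' cross-correlation peak (with parabolic sub-pixel refinement).  The
#' per-block shifts are linearly interpolated in frame and subtracted
#' from every localization; corrected coordinates are clamped to the
#' FOV.  Blocks with too few localizations (< `min_locs_per_block`)
#' make registration unreliable: a warning is raised and the identity
#' correction returned.
#'
#' @param locs localization tibble (`frame`, `x_nm`, `y_nm`, ...).
#' @param block_frames frames per registration block.
#' @param render_pixel_nm rendering pixel for the block images (nm).
#' @param fov FOV extent in nm (`c(x, y)`); defaults to the data extent.
#' @param min_locs_per_block minimum localizations per block.
#' @return A list of class `drift_corrected`: `locs` (corrected table),
#'   `drift` (tibble `block`, `frame_center`, `dx_nm`, `dy_nm`) and
#'   `method`.
#' @export
drift_correct <- function(locs,
                          block_frames = 1000L,
                          render_pixel_nm = 15,
                          fov = NULL,
                          min_locs_per_block = 100L) {
  check_scalar_positive(block_frames, "block_frames")
  if (nrow(locs) == 0) abort("Empty localization table.")
  if (is.null(fov)) fov <- c(max(locs$x_nm), max(locs$y_nm)) + render_pixel_nm
  if (length(fov) == 1L) fov <- rep(fov, 2L)
  block <- floor(locs$frame / block_frames)
  blocks <- sort(unique(block))
  if (length(blocks) < 2L) {
    abort("Need at least 2 frame blocks for drift correction.")
  }
  per_block <- tabulate(match(block, blocks), length(blocks))
  identity_trace <- tibble::tibble(
    block = blocks,
    frame_center = (blocks + 0.5) * block_frames,
    dx_nm = 0, dy_nm = 0
  )
  if (any(per_block < min_locs_per_block)) {
    warn(sprintf(
      "Block(s) with fewer than %d localizations; returning identity correction.",
      min_locs_per_block))
    return(structure(list(locs = locs, drift = identity_trace,
                          method = "identity (insufficient localizations)"),
                     class = "drift_corrected"))
  }
  imgs <- purrr::map(blocks, function(b) {
    blur_image(render_localizations(locs[block == b, , drop = FALSE],
                                    render_pixel_nm, fov = fov))
  })
  ref_fft <- fft(imgs[[1]])
  shifts <- purrr::map(imgs, function(im) {
    if (identical(im, imgs[[1]])) return(c(0, 0))
    xcorr_shift(ref_fft, im)
  })
  drift <- identity_trace
  drift$dx_nm <- vapply(shifts, `[`, numeric(1), 1) * render_pixel_nm
  drift$dy_nm <- vapply(shifts, `[`, numeric(1), 2) * render_pixel_nm
  # per-localization shift, linear in frame between block centers
  dx <- approx(drift$frame_center, drift$dx_nm, xout = locs$frame,
               rule = 2)$y
  dy <- approx(drift$frame_center, drift$dy_nm, xout = locs$frame,
               rule = 2)$y
  out <- locs
  out$x_nm <- pmin(pmax(locs$x_nm - dx, 0), fov[1] - 1e-9)
  out$y_nm <- pmin(pmax(locs$y_nm - dy, 0), fov[2] - 1e-9)
  structure(list(locs = out, drift = drift,
                 method = "redundant block cross-correlation"),
            class = "drift_corrected")
}

#' @export
print.drift_corrected <- function(x, ...) {
  cat(sprintf("Drift correction (%s): %d blocks, max |shift| %.1f nm\n",
              x$method, nrow(x$drift),
              max(abs(c(x$drift$dx_nm, x$drift$dy_nm)))))
  invisible(x)
}

# Small separable binomial blur; stabilises the correlation peak of
# sparse blink histograms.
blur_image <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  sm <- t(apply(img, 1, function(v) {
    as.numeric(stats::filter(c(0, 0, v, 0, 0), k, sides = 2))[3:(length(v) + 2)]
  }))
  sm <- apply(sm, 2, function(v) {
    as.numeric(stats::filter(c(0, 0, v, 0, 0), k, sides = 2))[3:(length(v) + 2)]
  })
  sm
}

# Shift (dx, dy) in whole pixels of image `im` relative to the
# reference whose FFT is `ref_fft`, from the circular cross-correlation
# peak.  Integer-peak registration: zero drift maps to an exact
# identity correction, and accuracy is one render pixel — the contract
# downstream segmentation needs.
xcorr_shift <- function(ref_fft, im) {
  cc <- Re(fft(ref_fft * Conj(fft(im)), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  pk <- which.max(cc)
  pr <- ((pk - 1L) %% nr) + 1L
  pc <- ((pk - 1L) %/% nr) + 1L
  wrap <- function(i, n) if (i - 1L > n / 2) i - 1L - n else i - 1L
  # correlation of ref with im shifted by (dy, dx): peak at -shift
  c(-wrap(pc, nc), -wrap(pr, nr))
}
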