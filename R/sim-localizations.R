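#' Ellipse axis ratio for a target circularity
#'
#' Solves for the semi-axis ratio b/a of an ellipse whose circularity
#' (4 pi A / P^2, with the Ramanujan perimeter approximation) equals `circ`.
#' Used by the ground-truth generator to turn sampled (diameter,
#' circularity) pairs into ellipse semi-axes.
#'
#' @param circ circularity values in (0, 1].
#' @return Axis ratios in (0, 1].
#' @export
#' @examples
#' ellipse_axis_ratio(1)   # 1: a circle
ellipse_axis_ratio <- function(circ) {
  if (any(!is.finite(circ)) || any(circ <= 0) || any(circ > 1)) {
    abort("`circ` must lie in (0, 1].")
  }
  circ_of <- function(r) {
    a <- 1 / sqrt(r)
    b <- sqrt(r)
    p <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
    4 * pi * (pi * a * b) / p^2
  }
  vapply(circ, function(ci) {
    if (ci >= circ_of(1) - 1e-12) return(1)
    stats::uniroot(function(r) circ_of(r) - ci,
                   lower = 1e-6, upper = 1, tol = 1e-10)$root
  }, numeric(1))
}

#' Generate ground-truth aggregates for a simulated field of view
#'
#' Samples elliptical aggregates from a two-component morphology mixture:
#' a "small round" population (equivalent diameter 35-150 nm, circularity
#' 0.7-1) and a "large irregular" population (150-1000 nm, circularity
#' 0.2-0.7).  The mixture weight is the knob downstream group-difference
#' experiments turn.  Centers are uniform over the FOV with a margin so
#' every aggregate fits inside.
#'
#' @param n number of aggregates.
#' @param settings an [acquisition_settings()] object.
#' @param frac_small_round mixture weight of the small-round component.
#' @param d_small_nm,d_large_nm diameter ranges (nm) of the two components.
#' @param circ_small,circ_large circularity ranges of the two components.
#' @param n_fluorophores fluorophores per aggregate (fixed count).
#' @param seed optional RNG seed.
#' @return A tibble with one row per aggregate: `truth_id`, center
#'   (`x_nm`, `y_nm`), semi-axes (`a_nm`, `b_nm`), orientation `theta`,
#'   `n_fluorophores`, `class`, and the true equivalent diameter
#'   `d_true_nm` and circularity `circ_true`.
#' @export
truth_aggregates <- function(n,
                             settings = acquisition_settings(),
                             frac_small_round = 0.3,
                             d_small_nm = c(35, 150),
                             d_large_nm = c(150, 1000),
                             circ_small = c(0.7, 1),
                             circ_large = c(0.2, 0.7),
                             n_fluorophores = 10L,
                             seed = NULL) {
  stopifnot(n >= 0, frac_small_round >= 0, frac_small_round <= 1)
  fov <- fov_nm(settings)
  with_seed(seed, {
    if (n == 0) {
      return(tibble::tibble(
        truth_id = integer(), x_nm = numeric(), y_nm = numeric(),
        a_nm = numeric(), b_nm = numeric(), theta = numeric(),
        n_fluorophores = integer(), class = character(),
        d_true_nm = numeric(), circ_true = numeric()
      ))
    }
    small <- runif(n) < frac_small_round
    d <- ifelse(small,
                runif(n, d_small_nm[1], d_small_nm[2]),
                runif(n, d_large_nm[1], d_large_nm[2]))
    circ <- ifelse(small,
                   runif(n, circ_small[1], circ_small[2]),
                   runif(n, circ_large[1], circ_large[2]))
    r <- ellipse_axis_ratio(circ)
    # semi-axes with a*b = (d/2)^2 so the equivalent-area diameter is d
    a <- (d / 2) / sqrt(r)
    b <- (d / 2) * sqrt(r)
    margin <- a + 1 # semi-major axis bounds the extent in any direction
    tibble::tibble(
      truth_id = seq_len(n),
      x_nm = runif(n, margin, fov[1] - margin),
      y_nm = runif(n, margin, fov[2] - margin),
      a_nm = a, b_nm = b,
      theta = runif(n, 0, pi),
      n_fluorophores = as.integer(rep(n_fluorophores, n)),
      class = ifelse(small, "small_round", "large_irregular"),
      d_true_nm = d, circ_true = circ
    )
  })
}

#' Simulate a dSTORM localization table from ground-truth aggregates
#'
#' Emulates a blinking-fluorophore acquisition: each aggregate carries a
#' fixed number of fluorophores placed uniformly over its ellipse
#' interior; each fluorophore emits a Poisson number of blink events
#' spread uniformly over the frames; each blink is localized at the
#' fluorophore position plus isotropic Gaussian noise whose per-blink
#' sigma is drawn from a truncated normal (default mean 17 nm, SD 7 nm,
#' floor 1 nm — the lateral localization uncertainty regime of the
#' assay).  With the fluorophore count fixed, the total localization
#' count per aggregate is exactly Poisson(`mean_localizations`); the
#' assay-typical mean is 58 localizations per aggregate.
#'
#' @param truths tibble from [truth_aggregates()].  A column
#'   `mean_localizations` in `truths`, when present, sets a
#'   per-aggregate expectation overriding the scalar argument (used
#'   e.g. to keep the per-fluorophore blink rate constant across
#'   aggregates of different sizes).
#' @param settings an [acquisition_settings()] object.
#' @param mean_localizations expected localizations per aggregate.
#' @param sigma_mean_nm,sigma_sd_nm,sigma_min_nm truncated-normal
#'   parameters of the per-localization lateral uncertainty; set
#'   `sigma_mean_nm = 0` (with `sigma_sd_nm = 0`) for a noise-free table.
#' @param photons_meanlog,photons_sdlog lognormal intensity parameters.
#' @param seed optional RNG seed.
#' @return A tibble sorted by frame with columns `id`, `frame` (0-based),
#'   `x_nm`, `y_nm`, `photons`, `uncertainty_nm` and the ground-truth
#'   index `truth_id`.
#' @export
#' @examples
#' s <- acquisition_settings(fov_px = 64)
#' tr <- truth_aggregates(3, s, seed = 1)
#' locs <- simulate_localizations(tr, s, seed = 1)
simulate_localizations <- function(truths,
                                   settings = acquisition_settings(),
                                   mean_localizations = 58,
                                   sigma_mean_nm = 17,
                                   sigma_sd_nm = 7,
                                   sigma_min_nm = 1,
                                   photons_meanlog = log(1000),
                                   photons_sdlog = 0.3,
                                   seed = NULL) {
  fov <- fov_nm(settings)
  empty <- tibble::tibble(
    id = integer(), frame = integer(), x_nm = numeric(), y_nm = numeric(),
    photons = numeric(), uncertainty_nm = numeric(), truth_id = integer()
  )
  if (nrow(truths) == 0) {
    attr(empty, "n_frames") <- settings$n_frames
    return(empty)
  }
  bad <- truths$x_nm - truths$a_nm < 0 | truths$x_nm + truths$a_nm > fov[1] |
    truths$y_nm - truths$a_nm < 0 | truths$y_nm + truths$a_nm > fov[2]
  if (any(bad)) {
    abort(sprintf("Aggregate(s) outside the FOV: truth_id %s.",
                  paste(truths$truth_id[bad], collapse = ", ")))
  }
  if (!"mean_localizations" %in% names(truths)) {
    truths$mean_localizations <- mean_localizations
  }
  with_seed(seed, {
    per_agg <- purrr::pmap(truths, function(truth_id, x_nm, y_nm, a_nm, b_nm,
                                            theta, n_fluorophores,
                                            mean_localizations, ...) {
      nf <- max(1L, n_fluorophores)
      lambda <- mean_localizations / nf
      blinks <- rpois(nf, lambda)
      total <- sum(blinks)
      if (total == 0) return(NULL)
      # fluorophores uniform over the ellipse interior
      u <- sqrt(runif(nf))
      phi <- runif(nf, 0, 2 * pi)
      ex <- a_nm * u * cos(phi)
      ey <- b_nm * u * sin(phi)
      fx <- x_nm + ex * cos(theta) - ey * sin(theta)
      fy <- y_nm + ex * sin(theta) + ey * cos(theta)
      idx <- rep.int(seq_len(nf), blinks)
      sig <- if (sigma_mean_nm <= 0 && sigma_sd_nm <= 0) {
        rep(0, total)
      } else {
        rtnorm_min(total, sigma_mean_nm, sigma_sd_nm, sigma_min_nm)
      }
      tibble::tibble(
        frame = sample.int(settings$n_frames, total, replace = TRUE) - 1L,
        x_nm = fx[idx] + rnorm(total, 0, 1) * sig,
        y_nm = fy[idx] + rnorm(total, 0, 1) * sig,
        photons = rlnorm(total, photons_meanlog, photons_sdlog),
        uncertainty_nm = sig,
        truth_id = truth_id
      )
    })
    out <- dplyr::bind_rows(per_agg)
    if (nrow(out) == 0) return(empty)
    out <- dplyr::mutate(out,
      x_nm = pmin(pmax(.data$x_nm, 0), fov[1] - 1e-9),
      y_nm = pmin(pmax(.data$y_nm, 0), fov[2] - 1e-9)
    )
    out <- dplyr::arrange(out, .data$frame)
    out <- dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
    attr(out, "n_frames") <- settings$n_frames
    out
  })
}
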