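# Super-resolution morphology: rendering, segmentation, morphometrics,
# resolution filtering, frame sufficiency, drift correction.

test_that("histogram rendering conserves localization counts", {
  empty <- tibble::tibble(x_nm = numeric(), y_nm = numeric())
  expect_true(all(render_localizations(empty, 15, fov = 150) == 0))

  s <- acquisition_settings(fov_px = 32)
  tr <- truth_aggregates(2, s, seed = 1)
  locs <- simulate_localizations(tr, s, seed = 2)
  img <- render_localizations(locs, 15, settings = s)
  expect_equal(sum(img), nrow(locs))
  expect_true(is.integer(img))
})

test_that("a point source renders within a 7x7 pixel window", {
  s <- acquisition_settings(fov_px = 16)
  tr <- tibble::tibble(truth_id = 1L, x_nm = 800, y_nm = 800,
                       a_nm = 0.5, b_nm = 0.5, theta = 0,
                       n_fluorophores = 1L, class = "pt",
                       d_true_nm = 1, circ_true = 1)
  locs <- simulate_localizations(tr, s, mean_localizations = 5000, seed = 5)
  img <- render_localizations(locs, 15, settings = s)
  ctr <- floor(800 / 15) + 1
  frac <- sum(img[(ctr - 3):(ctr + 3), (ctr - 3):(ctr + 3)]) / sum(img)
  expect_gt(frac, 0.95)
})

test_that("segmentation produces correct morphology for simple shapes", {
  # a filled disk of diameter 20 render pixels is nearly circular
  n <- 26
  mask <- outer(1:n, 1:n, function(i, j) (i - 13.5)^2 + (j - 13.5)^2 <= 100)
  img <- matrix(0L, n, n)
  img[mask] <- 5L
  attr(img, "render_pixel_nm") <- 15
  agg <- segment_aggregates(img)
  expect_equal(nrow(agg), 1)
  expect_gte(agg$circularity, 0.9)
  expect_equal(agg$d_area_um, 2 * sqrt(agg$area_um2 / pi))
  expect_equal(agg$d_perim_um, agg$perimeter_um / pi)

  # two disks separated by background are two aggregates
  img2 <- matrix(0L, 20, 20)
  img2[3:6, 3:6] <- 3L
  img2[10:13, 10:13] <- 3L
  attr(img2, "render_pixel_nm") <- 15
  expect_equal(nrow(segment_aggregates(img2)), 2)

  # a component carrying too few localizations is discarded
  img3 <- matrix(0L, 8, 8)
  img3[4, 4] <- 3L
  attr(img3, "render_pixel_nm") <- 15
  out <- segment_aggregates(img3, min_localizations = 10)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "discarded_localizations"), 3L)
})

test_that("localizations are conserved through segmentation", {
  s <- acquisition_settings(fov_px = 64)
  tr <- truth_aggregates(10, s, seed = 3)
  locs <- simulate_localizations(tr, s, seed = 4)
  img <- render_localizations(locs, 15, settings = s)
  agg <- segment_aggregates(img, min_localizations = 20)
  expect_equal(sum(agg$n_locs) + attr(agg, "discarded_localizations"),
               nrow(locs))
})

test_that("circularity is invariant to translation and 90-degree rotation", {
  img <- matrix(0L, 16, 16)
  img[3:7, 3:5] <- 2L
  img[5, 6:9] <- 2L
  attr(img, "render_pixel_nm") <- 15
  base <- segment_aggregates(img)

  shifted <- matrix(0L, 16, 16)
  shifted[6:16, 5:16] <- img[1:11, 1:12]
  attr(shifted, "render_pixel_nm") <- 15
  rotated <- matrix(0L, 16, 16)
  rotated[] <- t(img[16:1, ])
  attr(rotated, "render_pixel_nm") <- 15

  for (other in list(shifted, rotated)) {
    o <- segment_aggregates(other)
    expect_equal(o$circularity, base$circularity)
    expect_equal(o$area_um2, base$area_um2)
    expect_equal(o$perimeter_um, base$perimeter_um)
  }
})

test_that("equivalent diameters follow their defining formulas", {
  expect_equal(area_to_diameter(pi / 4), 1)
  expect_equal(perimeter_to_diameter(pi), 1)
  expect_error(area_to_diameter(0), "positive")
  expect_error(area_to_diameter(-1), "positive")
  expect_error(perimeter_to_diameter(0), "positive")

  # for a near-perfect rendered disk both diameters agree within 1%
  # (a generous radius keeps pixelation bias below the tolerance)
  n <- 131
  mask <- outer(1:n, 1:n, function(i, j) (i - 66)^2 + (j - 66)^2 <= 60^2)
  img <- matrix(0L, n, n)
  img[mask] <- 2L
  attr(img, "render_pixel_nm") <- 15
  agg <- segment_aggregates(img)
  expect_lt(abs(agg$d_perim_um / agg$d_area_um - 1), 0.01)
})

test_that("the resolution filter removes sub-30 nm species", {
  ag <- tibble::tibble(d_area_um = rep(0.2, 5))
  expect_equal(nrow(filter_by_resolution(ag)), 5)
  ag2 <- tibble::tibble(d_area_um = rep(0.02, 5))
  expect_equal(nrow(filter_by_resolution(ag2)), 0)
  expect_equal(attr(filter_by_resolution(ag2), "excluded_fraction"), 1)

  # mixed population: excluded fraction matches the truth fraction
  withr::with_seed(6, {
    d <- runif(5000, 0.01, 0.2)
    ag3 <- tibble::tibble(d_area_um = d)
    kept <- filter_by_resolution(ag3)
    expect_lt(abs(nrow(kept) / 5000 - mean(d >= 0.03)), 0.02)
  })
})

test_that("frame sufficiency saturates for a stationary dense sample", {
  s <- acquisition_settings(fov_px = 96, n_frames = 16000)
  tr <- truth_aggregates(40, s, frac_small_round = 0.5,
                         d_small_nm = c(50, 120), d_large_nm = c(120, 250),
                         seed = 10)
  # labeling density matched to the localization precision so the
  # support is complete once every fluorophore has blinked
  tr <- dplyr::mutate(tr,
    n_fluorophores = pmax(10L, as.integer(ceiling(pi * a_nm * b_nm / 100))),
    mean_localizations = 20 * n_fluorophores)
  locs <- simulate_localizations(tr, s, sigma_mean_nm = 5, sigma_sd_nm = 2,
                                 seed = 11)
  fs <- frame_sufficiency(locs, c(2000, 5000, 8000, 11000, 14000, 16000))
  i8 <- which(fs$breakpoint == 8000)
  i14 <- which(fs$breakpoint == 14000)
  expect_lt(abs(fs$iqr_area_um2[i14] / fs$iqr_area_um2[i8] - 1), 0.1)

  # constant blinking rate: per-block counts equal within Poisson error
  rate <- fs$block_localizations / diff(c(0, fs$breakpoint))
  full_rate <- nrow(locs) / 16000
  expect_true(all(abs(rate - full_rate) <
                    4 * sqrt(full_rate / diff(c(0, fs$breakpoint)))))

  # a single breakpoint at n_frames reproduces the full analysis
  full <- frame_sufficiency(locs, 16000)
  img <- render_localizations(locs, 15,
                              fov = c(max(locs$x_nm), max(locs$y_nm)) + 15)
  agg <- filter_by_resolution(segment_aggregates(img, 5))
  expect_equal(full$n_aggregates, nrow(agg))
  expect_equal(full$iqr_area_um2, IQR(agg$area_um2))

  expect_error(frame_sufficiency(locs, 20000, n_frames = 16000), "eyond")
})

test_that("drift correction recovers injected drift and leaves still data alone", {
  s <- acquisition_settings(fov_px = 48, n_frames = 8000)
  dense <- tibble::tibble(truth_id = 1L, x_nm = 2500, y_nm = 2500,
                          a_nm = 200, b_nm = 200, theta = 0,
                          n_fluorophores = 400L, class = "x",
                          d_true_nm = 400, circ_true = 1)
  locs <- simulate_localizations(dense, s, mean_localizations = 8000, seed = 9)

  # zero drift: identity to the nanometer, trace at zero everywhere
  dc0 <- drift_correct(locs, block_frames = 1000, fov = fov_nm(s))
  expect_lt(max(abs(c(dc0$locs$x_nm - locs$x_nm,
                      dc0$locs$y_nm - locs$y_nm))), 1)
  expect_lt(max(abs(c(dc0$drift$dx_nm, dc0$drift$dy_nm))), 15)

  # injected linear drift: endpoint recovered within one render pixel
  s2 <- acquisition_settings(fov_px = 96, n_frames = 8000)
  tr2 <- truth_aggregates(40, s2, seed = 11)
  l2 <- simulate_localizations(tr2, s2, seed = 12)
  fr <- l2$frame / (s2$n_frames - 1)
  drifted <- dplyr::mutate(l2, x_nm = x_nm + 100 * fr, y_nm = y_nm + 60 * fr)
  dc <- drift_correct(drifted, block_frames = 1000, fov = fov_nm(s2))
  n_blocks <- nrow(dc$drift)
  expected_end <- 100 * (n_blocks - 0.5) / n_blocks * 8000 / 7999
  expect_lt(abs(dc$drift$dx_nm[n_blocks] - expected_end), 15)

  # too few localizations per block: warning and identity correction
  sparse <- locs[seq(1, nrow(locs), by = 20), ]
  expect_warning(dcs <- drift_correct(sparse, block_frames = 1000,
                                      fov = fov_nm(s)),
                 "identity")
  expect_equal(dcs$locs$x_nm, sparse$x_nm)
})
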