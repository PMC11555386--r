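# Synthetic-data generator: localization tables, TIRF stacks, cohorts,
# denaturation series.

test_that("localization simulator honors its contracts", {
  s <- acquisition_settings(fov_px = 64)

  expect_equal(nrow(simulate_localizations(truth_aggregates(0, s), s)), 0)

  # zero-noise limit: a single fluorophore localizes at one exact point
  tr1 <- truth_aggregates(1, s, n_fluorophores = 1L, seed = 5)
  locs1 <- simulate_localizations(tr1, s, sigma_mean_nm = 0, sigma_sd_nm = 0,
                                  seed = 6)
  expect_gt(nrow(locs1), 0)
  expect_equal(length(unique(paste(locs1$x_nm, locs1$y_nm))), 1)
  # and the point lies inside the aggregate's bounding circle
  expect_lte(sqrt((locs1$x_nm[1] - tr1$x_nm)^2 + (locs1$y_nm[1] - tr1$y_nm)^2),
             tr1$a_nm + 1e-9)

  # aggregate outside the FOV is rejected with its id named
  bad <- truth_aggregates(1, s, seed = 1)
  bad$x_nm <- fov_nm(s)[1] + 10
  expect_error(simulate_localizations(bad, s), "truth_id 1")

  tr <- truth_aggregates(20, s, seed = 7)
  locs <- simulate_localizations(tr, s, seed = 8)
  expect_false(is.unsorted(locs$frame))
  expect_true(all(locs$frame >= 0 & locs$frame < s$n_frames))
  expect_true(all(locs$x_nm >= 0 & locs$x_nm <= fov_nm(s)[1]))
  expect_true(all(locs$y_nm >= 0 & locs$y_nm <= fov_nm(s)[2]))
  expect_true(all(locs$uncertainty_nm > 0))

  # deterministic under a fixed seed
  expect_identical(locs, simulate_localizations(tr, s, seed = 8))
})

test_that("localization counts per aggregate are Poisson at the assay mean", {
  s <- acquisition_settings(fov_px = 256)
  tr <- truth_aggregates(200, s, seed = 2)
  locs <- simulate_localizations(tr, s, seed = 3)
  per_agg <- as.numeric(table(factor(locs$truth_id, levels = tr$truth_id)))
  expect_gte(mean(per_agg[1:100]), 52)
  expect_lte(mean(per_agg[1:100]), 64)
  ratio <- var(per_agg) / mean(per_agg)
  expect_gte(ratio, 0.7)
  expect_lte(ratio, 1.3)
})

test_that("TIRF stack simulator produces Poisson background plus spots", {
  s <- acquisition_settings(fov_px = 32)
  empty_spots <- tibble::tibble(x_px = numeric(), y_px = numeric(),
                                brightness = numeric())
  sim <- simulate_tirf_stack(empty_spots, s, background_mean = 10, seed = 1)
  expect_equal(dim(sim$stack), c(32, 32, 50))
  m <- mean(sim$stack[, , 1])
  se <- sqrt(10 / (32 * 32))
  expect_lt(abs(m - 10), 3 * se)

  # a spot at the FOV corner is legal and its truth retained
  corner <- simulate_tirf_stack(
    tibble::tibble(x_px = 0, y_px = 0, brightness = 100), s, seed = 2)
  expect_equal(nrow(corner$truth), 1)
  expect_gt(mean(corner$stack[1, 1, ]), 10)

  expect_error(simulate_tirf_stack(empty_spots, s, background_mean = 0),
               "background_mean")
  expect_error(
    simulate_tirf_stack(tibble::tibble(x_px = 1, y_px = 1, brightness = -1), s),
    "positive")
})

test_that("cohort generator is deterministic and calibrated under the null", {
  spec <- cohort_spec(n_control = 5, n_disease = 5, seed = 9)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))

  # all fold changes 1: permutation test on ASC counts is null-calibrated
  m1 <- tibble::tibble(marker = "ASC", mean = 40, dispersion = 10, fold = 1)
  ps <- vapply(1:100, function(s) {
    coh <- simulate_cohort(cohort_spec(6, 6, markers = m1, seed = s))
    a <- coh$counts[coh$counts$marker == "ASC", ]
    permutation_exact_test(a$value[a$group == "disease"],
                           a$value[a$group == "control"])$p_value
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.9)

  # and the AUC distribution is centred at one half
  aucs <- vapply(1:100, function(s) {
    coh <- simulate_cohort(cohort_spec(10, 10, markers = m1, seed = s))
    a <- coh$counts[coh$counts$marker == "ASC", ]
    auc(a$value, a$group)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("cohort morphology mixture plants the stated small-round excess", {
  coh <- simulate_cohort(cohort_spec(4, 4, include_morphology = TRUE,
                                     n_aggregates_per_subject = 4000,
                                     seed = 4))
  boundary <- pi * 0.075^2 # 150 nm diameter
  f <- tapply(coh$morphology$area_um2 <= boundary &
                coh$morphology$circularity >= 0.7,
              list(coh$morphology$subject), mean)
  grp <- tapply(coh$morphology$group, list(coh$morphology$subject),
                function(g) g[1])
  excess <- mean(f[grp == "disease"]) - mean(f[grp == "control"])
  expect_lt(abs(excess - 0.08), 0.03)
})

test_that("denaturation generator matches its closed form", {
  d0 <- simulate_denaturation(100, 0.5, concs = c(0, 0.5, 1), noise_cv = 0)
  expect_equal(d0$count_mean[d0$conc_M == 0], 100)
  expect_equal(d0$count_mean[d0$conc_M == 0.5], 100 / exp(1))

  # round trip through the fitter at 5% noise
  d <- simulate_denaturation(100, 0.5, noise_cv = 0.05, seed = 3)
  fit <- fit_denaturation(d)
  expect_lt(abs(fit$c_e - 0.5) / 0.5, 0.1)

  expect_error(simulate_denaturation(0, 0.5), "n0")
  expect_error(simulate_denaturation(10, -1), "c_e")
})

test_that("ellipse axis ratio reproduces the requested circularity", {
  expect_equal(ellipse_axis_ratio(1), 1)
  for (target in c(0.3, 0.5, 0.8)) {
    r <- ellipse_axis_ratio(target)
    a <- 1 / sqrt(r)
    b <- sqrt(r)
    p <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
    expect_equal(4 * pi * (pi * a * b) / p^2, target, tolerance = 1e-6)
  }
  expect_error(ellipse_axis_ratio(1.2))
})
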