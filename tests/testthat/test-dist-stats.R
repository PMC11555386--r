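# ECDFs, KS difference curves, and the combined threshold search.

test_that("the ECDF is the standard right-continuous step function", {
  e <- ecdf_curve(c(3, 1, 2))
  expect_equal(e$value, c(1, 2, 3))
  expect_equal(e$frac[e$value == 2], 2 / 3)
  expect_equal(max(e$frac), 1)

  same <- ecdf_curve(rep(4, 10))
  expect_true(all(same$value == 4))
  expect_equal(max(same$frac), 1)

  expect_error(ecdf_curve(numeric()), "at least one")

  # DKW: sup deviation from the uniform CDF at n = 1e4
  withr::with_seed(13, {
    u <- runif(1e4)
    e2 <- ecdf_curve(u)
    expect_lt(max(abs(e2$frac - e2$value)), 0.03)
  })
})

test_that("ECDF difference curves carry the KS band", {
  x <- c(1, 2, 3, 4, 5)
  d0 <- ecdf_difference(x, x)
  expect_equal(d0$D, 0)
  expect_true(all(d0$curve$delta == 0))

  d1 <- ecdf_difference(x, x + 10)
  expect_equal(d1$D, 1)

  # band: c(0.01) * sqrt((n + m)/(n m)) with c(0.01) = 1.628
  d2 <- ecdf_difference(rnorm(50), rnorm(40))
  expect_equal(d2$band, 1.628 * sqrt(90 / 2000), tolerance = 1e-3)

  # Delta ECDF integrates to mean(b) - mean(a) for bounded supports
  withr::with_seed(14, {
    a <- runif(200)
    b <- runif(300) + 0.3
    d3 <- ecdf_difference(a, b)
    g <- d3$curve$value
    integral <- sum(d3$curve$delta[-length(g)] * diff(g))
    expect_equal(integral, mean(b) - mean(a), tolerance = 0.02)
  })
})

test_that("the two-sample KS test is calibrated", {
  expect_equal(ks_two_sample(1:10, 1:10)$p_value, 1)
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)

  # agreement with the reference asymptotic implementation
  withr::with_seed(15, {
    a <- rnorm(80)
    b <- rnorm(120, 0.3)
    mine <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(mine$D, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-4)
  })

  # null p-values are uniform: rejection rate near alpha
  withr::with_seed(16, {
    rej <- mean(vapply(1:1000, function(i) {
      ks_two_sample(rnorm(100), rnorm(100))$p_value < 0.05
    }, logical(1)))
    expect_gte(rej, 0.03)
    expect_lte(rej, 0.08)
  })
})

test_that("the small-round fraction is a plain proportion", {
  ag <- tibble::tibble(area_um2 = c(0.01, 0.2, 0.03, 0.5),
                       circularity = c(0.9, 0.3, 0.8, 0.9))
  expect_equal(fraction_small_round(ag, Inf, 0), 1)
  expect_equal(fraction_small_round(ag, 0, 1.01), 0)
  expect_equal(fraction_small_round(ag, 0.05, 0.5), 0.5)
  expect_error(fraction_small_round(ag[0, ], 1, 0), "empty")
})

test_that("a single-cell grid reduces to fraction plus permutation test", {
  coh <- simulate_cohort(cohort_spec(4, 4, include_morphology = TRUE,
                                     n_aggregates_per_subject = 100,
                                     seed = 21))
  m <- coh$morphology
  thr <- threshold_search(m, area_grid = 0.02, circ_grid = 0.6)
  f <- tapply(m$area_um2 <= 0.02 & m$circularity >= 0.6, m$subject, mean)
  grp <- tapply(m$group, m$subject, function(g) g[1])
  expect_equal(thr$delta_f,
               unname(mean(f[grp == "disease"]) - mean(f[grp == "control"])))
  ref <- permutation_exact_test(f[grp == "disease"], f[grp == "control"])
  expect_equal(thr$p_value, ref$p_value)
})

test_that("threshold search is invariant to subject order and label swap", {
  coh <- simulate_cohort(cohort_spec(4, 4, include_morphology = TRUE,
                                     n_aggregates_per_subject = 200,
                                     seed = 22))
  m <- coh$morphology
  grid_a <- c(0.01, 0.02, 0.05)
  grid_c <- c(0.4, 0.7)
  t1 <- threshold_search(m, grid_a, grid_c)
  t2 <- threshold_search(m[sample.int(nrow(m)), ], grid_a, grid_c)
  expect_equal(t1$area_max, t2$area_max)
  expect_equal(t1$delta_f, t2$delta_f)

  swapped <- threshold_search(m, grid_a, grid_c, case_group = "control")
  expect_equal(swapped$delta_f, -t1$delta_f)
  expect_equal(swapped$p_value, t1$p_value)
})

test_that("grid refinement never decreases the maximal fraction difference", {
  coh <- simulate_cohort(cohort_spec(4, 4, include_morphology = TRUE,
                                     n_aggregates_per_subject = 300,
                                     seed = 23))
  coarse_a <- c(0.01, 0.05)
  fine_a <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  coarse <- threshold_search(coh$morphology, coarse_a, c(0.5, 0.8))
  fine <- threshold_search(coh$morphology, fine_a, c(0.3, 0.5, 0.65, 0.8))
  expect_gte(max(abs(fine$grid$delta_f)), max(abs(coarse$grid$delta_f)))
})

test_that("the significance gate respects the attainable permutation floor", {
  # 3 vs 3 subjects: the smallest exact two-sided p is 2/20 = 0.1, so no
  # grid cell can pass the 0.05 gate whatever the data look like
  coh <- simulate_cohort(cohort_spec(3, 3, include_morphology = TRUE,
                                     n_aggregates_per_subject = 200,
                                     small_round_excess = 0, seed = 24))
  thr <- threshold_search(coh$morphology)
  expect_false(thr$significant)
  expect_gte(min(thr$grid$p_value), 0.1)
})
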