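# Cohort biomarker statistics: AUC, ROC, permutation and binomial
# tests, composite expressions, power, precision.

test_that("rank-based AUC equals brute-force pair counting", {
  lab <- rep(c("disease", "control"), each = 3)
  expect_equal(auc(c(1, 2, 3, 1, 2, 3) + c(10, 10, 10, 0, 0, 0), lab), 1)
  expect_equal(auc(rep(5, 6), lab), 0.5)
  # enumerating all 9 pairs: 7 wins, 0 ties
  expect_equal(auc(c(3, 5, 7, 1, 2, 6), lab), 7 / 9)
  expect_equal(pairwise_auc(c(3, 5, 7, 1, 2, 6), lab, "disease"), 7 / 9)

  withr::with_seed(31, {
    for (i in 1:50) {
      n1 <- sample(2:8, 1)
      n0 <- sample(2:8, 1)
      scores <- sample(1:6, n1 + n0, replace = TRUE) # ties likely
      labels <- rep(c("disease", "control"), c(n1, n0))
      expect_equal(auc(scores, labels),
                   pairwise_auc(scores, labels, "disease"))
      # complement symmetry
      expect_equal(auc(scores, labels) + auc(-scores, labels), 1)
    }
  })
  expect_error(auc(1:3, rep("a", 3)), "classes")
})

test_that("the ROC curve is monotone and integrates to the AUC", {
  withr::with_seed(32, {
    scores <- rnorm(40)
    labels <- rep(c("disease", "control"), 20)
    scores[labels == "disease"] <- scores[labels == "disease"] + 1
    roc <- roc_curve(scores, labels)
    expect_true(all(diff(roc$tpr) >= 0))
    expect_true(all(diff(roc$fpr) >= 0))
    trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
    expect_equal(trap, attr(roc, "auc"))
    skip_if_not_installed("pROC")
    ref <- pROC::roc(labels, scores, levels = c("control", "disease"),
                     direction = "<", quiet = TRUE)
    expect_equal(attr(roc, "auc"), as.numeric(ref$auc))
  })
})

test_that("the exact permutation test enumerates group assignments", {
  expect_equal(permutation_exact_test(rep(2, 4), rep(2, 3))$p_value, 1)
  expect_equal(permutation_exact_test(c(1, 2, 3), c(10, 11, 12))$p_value,
               2 / 20)

  withr::with_seed(33, {
    for (i in 1:10) {
      x <- rnorm(sample(3:5, 1))
      y <- rnorm(sample(3:5, 1), mean = runif(1, 0, 2))
      expect_equal(permutation_exact_test(x, y)$p_value, brute_perm_p(x, y))
      # invariance to shift and positive rescaling
      expect_equal(permutation_exact_test(3 * x + 7, 3 * y + 7)$p_value,
                   permutation_exact_test(x, y)$p_value)
    }
  })

  # Monte-Carlo path agrees with the exact path within sampling error
  withr::with_seed(34, {
    x <- rnorm(5, 1)
    y <- rnorm(5)
    exact <- permutation_exact_test(x, y)$p_value
    mc <- permutation_exact_test(x, y, max_exact = 10, n_perm = 2e4,
                                 seed = 1)
    expect_equal(mc$method, "monte_carlo")
    expect_lt(abs(mc$p_value - exact),
              3 * sqrt(exact * (1 - exact) / 2e4) + 2 / 2e4)
  })
})

test_that("the binomial group-size test matches the exact tail sum", {
  expect_equal(binomial_group_size_test(10, 10), 1)
  expect_equal(binomial_group_size_test(0, 8), 2 * 0.5^8)
  # two-sided exact tail sum for 30 vs 20
  p_manual <- sum(dbinom(0:50, 50, 0.5)[dbinom(0:50, 50, 0.5) <=
                                          dbinom(30, 50, 0.5) + 1e-12])
  expect_equal(binomial_group_size_test(30, 20), p_manual)
  expect_equal(round(binomial_group_size_test(30, 20), 1), 0.2)
  expect_error(binomial_group_size_test(0, 0), "not both zero")
})

test_that("group-max normalization scales every group to a maximum of one", {
  expect_equal(group_max_normalize(c(2, 4, 8), rep("a", 3)),
               c(0.25, 0.5, 1))
  two <- group_max_normalize(c(1, 5, 2, 10), c("a", "a", "b", "b"))
  expect_equal(max(two[1:2]), 1)
  expect_equal(max(two[3:4]), 1)
  expect_equal(group_max_normalize(rep(7, 4), rep(c("a", "b"), 2)),
               rep(1, 4))
  expect_error(group_max_normalize(c(0, 0), c("a", "a")), "positive")
})

test_that("composite expressions score cohorts per the grammar", {
  cohort <- tibble::tibble(
    subject = rep(c("s1", "s2"), each = 3),
    group = rep(c("control", "disease"), each = 3),
    marker = rep(c("ASC", "ptau", "Abeta"), 2),
    value = c(2, 1, 4, 6, 4, 2)
  )
  id <- evaluate_composite(cohort, "ASC")
  expect_equal(id$score, c(2, 6))
  ratio <- evaluate_composite(
    cohort, composite_expression(c("ptau", "ASC"), "Abeta"))
  expect_equal(ratio$score[ratio$subject == "s2"], (4 + 6) / 2)

  expect_error(evaluate_composite(cohort, composite_expression("nope")),
               "nope")
  zero <- cohort
  zero$value[zero$marker == "Abeta" & zero$subject == "s1"] <- 0
  expect_error(
    evaluate_composite(zero, composite_expression("ASC", "Abeta")),
    "s1")

  # group-max normalization makes ratio scores scale-invariant per group
  coh2 <- tibble::tibble(
    subject = rep(sprintf("s%d", 1:6), each = 2),
    group = rep(rep(c("control", "disease"), each = 2), 3),
    marker = rep(c("ASC", "Abeta"), 6),
    value = c(2, 10, 3, 20, 4, 15, 5, 30, 6, 25, 7, 40)
  )
  e <- composite_expression("ASC", "Abeta", normalize_denominator = TRUE)
  base <- evaluate_composite(coh2, e)
  doubled <- dplyr::mutate(coh2, value = ifelse(
    marker == "Abeta" & group == "disease", value * 2, value))
  expect_equal(evaluate_composite(doubled, e)$score, base$score)
})

test_that("the composite grammar enumeration has the closed-form size", {
  count_for <- function(k) k + choose(k, 2) + k * (k - 1) +
    choose(k, 2) * (k - 2)
  expect_length(enumerate_composites(c("a", "b", "c")), count_for(3))
  expect_length(enumerate_composites(letters[1:4]), count_for(4))
  expect_equal(composite_search(
    tibble::tibble(subject = sprintf("s%d", 1:4),
                   group = rep(c("control", "disease"), 2),
                   marker = "m1", value = c(1, 2, 3, 4)))$expression,
    "m1")
})

test_that("the search recovers a planted composite in most cohorts", {
  # planted design: two correlated disease signals plus a stable
  # reference marker under a shared per-subject loading nuisance, so
  # (m1 + m2) / m3 has the largest true effect
  mk <- tibble::tibble(marker = c("m1", "m2", "m3"),
                       mean = c(30, 30, 100),
                       dispersion = c(6, 6, 100),
                       fold = c(2.5, 2.5, 1))
  first <- vapply(1:100, function(s) {
    coh <- simulate_cohort(cohort_spec(20, 20, markers = mk,
                                       subject_effect_cv = 0.8, seed = s))
    composite_search(coh$counts)$expression[1]
  }, character(1))
  expect_gte(mean(first == "(m1 + m2) / m3"), 0.9)
})

test_that("fold changes, correlations and power behave as defined", {
  expect_equal(fold_change(c(4, 6), c(4, 6))$fold_mean, 1)
  expect_equal(fold_change(c(4, 6), c(2, 3))$fold_mean, 2)
  expect_error(fold_change(1:3, c(0, 0)), "positive")

  expect_equal(correlate(1:10, 1:10)$estimate, 1)
  expect_equal(correlate(1:10, -(1:10))$estimate, -1)
  expect_equal(correlate(1:10, exp(1:10), method = "spearman")$estimate, 1)
  expect_lt(correlate(1:10, exp(1:10))$estimate, 1)
  expect_error(correlate(1:10, rep(1, 10)), "variance")

  expect_equal(power_two_sample_t(0, 10, 0.05), 0.05)
  # reference: base R's power calculator
  expect_equal(power_two_sample_t(2, 10),
               stats::power.t.test(n = 10, delta = 2, sd = 1)$power,
               tolerance = 1e-6)
  # monotone in effect size and group size
  grid_d <- c(0.2, 0.5, 1, 2)
  expect_true(all(diff(vapply(grid_d, power_two_sample_t,
                              numeric(1), n_per_group = 10)) > 0))
  grid_n <- c(3, 5, 10, 20)
  expect_true(all(diff(vapply(grid_n, function(n)
    power_two_sample_t(1, n), numeric(1))) > 0))
})

test_that("assay precision CVs follow the definition", {
  same <- tibble::tibble(sample = rep("a", 3), plate = 1, value = rep(5, 3))
  expect_equal(cv_precision(same)$intra_cv, 0)

  two <- tibble::tibble(sample = rep("a", 2), plate = 1, value = c(90, 110))
  expect_equal(cv_precision(two)$intra_cv, 100 * sd(c(90, 110)) / 100)

  withr::with_seed(6, {
    d <- tidyr::expand_grid(sample = sprintf("s%d", 1:20), plate = 1:2)
    d$value <- 100 * exp(rnorm(nrow(d), 0, 0.15))
    cv <- cv_precision(d)
    expect_lt(abs(cv$inter_cv - 15), 3)
    expect_true(is.na(cv$intra_cv)) # no within-plate duplicates here
  })
  expect_error(cv_precision(tibble::tibble(sample = "a", plate = 1,
                                           value = 1)),
               "at least 2")
})
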