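#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic:
#' the probability that a random case scores above a random control,
#' ties counting one half.  Exact under ties, unlike a trapezoid on a
#' coarse curve.
#'
#' @param scores numeric biomarker scores.
#' @param labels group labels (exactly two levels, both present).
#' @param case label of the positive (disease) class; defaults to
#'   `"disease"` if present, otherwise the second level.  Scores are not
#'   flipped: an AUC below 0.5 is reported as-is.
#' @return The AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(1, 2, 3, 4), c("control", "control", "disease", "disease"))
auc <- function(scores, labels, case = NULL) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  lev <- unique(labels)
  if (length(lev) != 2L) abort("Both classes must be present (exactly two).")
  if (is.null(case)) case <- if ("disease" %in% lev) "disease" else lev[2]
  pos <- labels == case
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve of a biomarker score
#'
#' Sweeps the sorted unique scores as thresholds (score >= threshold
#' calls disease) and reports the false/true positive rates.  The
#' attached AUC is the rank-based [auc()], which equals the trapezoidal
#' integral of this curve.
#'
#' @inheritParams auc
#' @return Tibble of class `speck_roc` with `threshold`, `fpr`, `tpr`,
#'   and attributes `auc` and `case`.
#' @export
roc_curve <- function(scores, labels, case = NULL) {
  a <- auc(scores, labels, case) # validates inputs
  lev <- unique(labels)
  if (is.null(case)) case <- if ("disease" %in% lev) "disease" else lev[2]
  pos <- labels == case
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  )
  out <- tibble::new_tibble(out, class = "speck_roc")
  attr(out, "auc") <- a
  attr(out, "case") <- case
  out
}

#' Exact two-group permutation test on the difference of means
#'
#' The default group-comparison test of the assay.  When the number of
#' group assignments C(n + m, n) does not exceed `max_exact`, all
#' assignments are enumerated and the p-value is the exact proportion
#' with |difference of means| at least the observed (the observed split
#' is one of them, so p >= 1/C(n+m, n)).  Larger problems fall back to
#' Monte-Carlo resampling with the observed split included and the
#' resample count reported.
#'
#' @param x,y numeric samples for the two groups.
#' @param two_sided two-sided test (default) or one-sided
#'   (mean(x) > mean(y)).
#' @param max_exact enumeration budget (default C(20, 10) = 184756).
#' @param n_perm Monte-Carlo resamples when not exact.
#' @param seed RNG seed for the Monte-Carlo path (recorded in output).
#' @return Object of class `perm_test`: list with `p_value`,
#'   `statistic` (observed mean difference), `method`, `n_permutations`,
#'   `seed`.
#' @export
#' @examples
#' permutation_exact_test(c(1, 2, 3), c(10, 11, 12))$p_value # 2/20
permutation_exact_test <- function(x, y, two_sided = TRUE,
                                   max_exact = 184756,
                                   n_perm = 1e5, seed = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  obs <- mean(x) - mean(y)
  eps <- 1e-12
  n_assign <- choose(n1 + n2, n1)
  if (n_assign <= max_exact) {
    comb <- combn(n1 + n2, n1)
    sums <- colSums(matrix(pooled[comb], nrow = n1))
    deltas <- sums / n1 - (sum(pooled) - sums) / n2
    extreme <- if (two_sided) abs(deltas) >= abs(obs) - eps else
      deltas >= obs - eps
    p <- mean(extreme)
    method <- "exact"
    n_used <- length(deltas)
    used_seed <- NULL
  } else {
    used_seed <- seed %||% 0L
    deltas <- with_seed(used_seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n1 + n2, n1)
        mean(pooled[idx]) - mean(pooled[-idx])
      }, numeric(1))
    })
    extreme <- if (two_sided) abs(deltas) >= abs(obs) - eps else
      deltas >= obs - eps
    p <- (1 + sum(extreme)) / (1 + n_perm) # observed split included
    method <- "monte_carlo"
    n_used <- n_perm
  }
  structure(
    list(p_value = p, statistic = obs, method = method,
         n_permutations = n_used, two_sided = two_sided, seed = used_seed),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s): mean difference %.4g, p = %.4g\n",
              x$method, if (x$two_sided) "two-sided" else "one-sided",
              x$statistic, x$p_value))
  invisible(x)
}

#' Exact binomial test for a group-size comparison
#'
#' Two-sided exact binomial test of n1 successes in n1 + n2 trials at
#' probability one half — the convention for comparing cohort sample
#' sizes.
#'
#' @param n1,n2 the two group sizes (non-negative, not both zero).
#' @return The two-sided p-value.
#' @export
#' @examples
#' binomial_group_size_test(30, 20) # ~0.2
binomial_group_size_test <- function(n1, n2) {
  if (n1 < 0 || n2 < 0 || (n1 + n2) == 0) {
    abort("Group sizes must be non-negative and not both zero.")
  }
  binom.test(n1, n1 + n2, p = 0.5)$p.value
}

#' Normalize values by the maximum within each diagnostic group
#'
#' Divides each value by the maximum observed in its own group, so every
#' group attains 1 — the normalisation applied to the amyloid-beta
#' denominator of the composite ratios.  Note that using the subject's
#' own diagnostic label leaks group information into the score; this is
#' reproduced as specified and flagged here so users can judge it.
#'
#' @param values numeric vector (the marker to normalize).
#' @param groups group label per value.
#' @return `values` divided by their group maxima.
#' @export
#' @examples
#' group_max_normalize(c(2, 4, 8), rep("a", 3))
group_max_normalize <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal length.")
  }
  mx <- tapply(values, groups, max)
  if (any(!is.finite(mx)) || any(mx <= 0)) {
    abort("Every group must have a positive finite maximum.")
  }
  as.numeric(values / mx[as.character(groups)])
}

#' Composite biomarker expression
#'
#' A formula over marker names drawn from the grammar
#' `m`, `m1 + m2`, `m1 / m3`, `(m1 + m2) / m3`, optionally with
#' group-max normalization of the denominator marker.
#'
#' @param numerator character vector of one or two marker names (summed).
#' @param denominator optional single marker name.
#' @param normalize_denominator apply [group_max_normalize()] to the
#'   denominator marker before dividing?
#' @return Object of class `composite_expr`.
#' @export
#' @examples
#' composite_expression(c("ptau", "ASC"), "Abeta")
composite_expression <- function(numerator, denominator = NULL,
                                 normalize_denominator = FALSE) {
  if (length(numerator) < 1 || length(numerator) > 2) {
    abort("`numerator` must name one or two markers.")
  }
  if (!is.null(denominator) && length(denominator) != 1) {
    abort("`denominator` must be a single marker name.")
  }
  structure(
    list(numerator = as.character(numerator),
         denominator = if (is.null(denominator)) NULL else
           as.character(denominator),
         normalize_denominator = isTRUE(normalize_denominator)),
    class = "composite_expr"
  )
}

#' @export
format.composite_expr <- function(x, ...) {
  num <- paste(x$numerator, collapse = " + ")
  if (is.null(x$denominator)) return(num)
  if (length(x$numerator) > 1) num <- paste0("(", num, ")")
  den <- if (x$normalize_denominator) paste0("norm(", x$denominator, ")") else
    x$denominator
  paste0(num, " / ", den)
}

#' @export
print.composite_expr <- function(x, ...) {
  cat("Composite biomarker:", format(x), "\n")
  invisible(x)
}

#' Score a composite biomarker expression on a cohort
#'
#' Evaluates the expression per subject on a long cohort table.  When
#' the normalization flag is set, the denominator marker is group-max
#' normalized before dividing.
#'
#' @param cohort long tibble with `subject`, `group`, `marker`, `value`
#'   (e.g. the `counts` element of [simulate_cohort()]).
#' @param expr a [composite_expression()], or a plain marker name.
#' @return Tibble with `subject`, `group`, `score`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_control = 3, n_disease = 3, seed = 1))
#' evaluate_composite(coh$counts, composite_expression("ASC"))
evaluate_composite <- function(cohort, expr) {
  if (is.character(expr)) expr <- composite_expression(expr)
  stopifnot(inherits(expr, "composite_expr"))
  wide <- tidyr::pivot_wider(cohort, id_cols = c("subject", "group"),
                             names_from = "marker", values_from = "value")
  needed <- c(expr$numerator, expr$denominator)
  for (m in needed) {
    if (!m %in% names(wide)) {
      abort(sprintf("Marker `%s` is absent from the cohort.", m))
    }
    bad <- is.na(wide[[m]])
    if (any(bad)) {
      abort(sprintf("Marker `%s` missing for subject %s.",
                    m, wide$subject[which(bad)[1]]))
    }
  }
  num <- rowSums(wide[, expr$numerator, drop = FALSE])
  if (is.null(expr$denominator)) {
    score <- num
  } else {
    den <- wide[[expr$denominator]]
    if (expr$normalize_denominator) {
      den <- group_max_normalize(den, wide$group)
    }
    if (any(den == 0)) {
      abort(sprintf("Zero denominator (`%s`) for subject %s.",
                    expr$denominator, wide$subject[which(den == 0)[1]]))
    }
    score <- num / den
  }
  tibble::tibble(subject = wide$subject, group = wide$group,
                 score = as.numeric(score))
}

#' Enumerate composite biomarker expressions over a marker set
#'
#' The grammar closure: every single marker `m`, unordered sum
#' `m1 + m2`, ordered ratio `m1 / m2`, and `(m1 + m2) / m3` with `m3`
#' outside the numerator.  For `k` markers that is
#' `k + C(k,2) + k(k-1) + C(k,2)(k-2)` expressions.
#'
#' @param markers character vector of marker names.
#' @param normalize_denominator markers that are group-max normalized
#'   whenever they appear as a denominator.
#' @return List of [composite_expression()] objects.
#' @export
enumerate_composites <- function(markers, normalize_denominator = character()) {
  markers <- unique(as.character(markers))
  k <- length(markers)
  if (k < 1) abort("Need at least one marker.")
  out <- list()
  for (m in markers) out <- c(out, list(composite_expression(m)))
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      out <- c(out, list(composite_expression(c(markers[i], markers[j]))))
    }
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      out <- c(out, list(composite_expression(
        markers[i], markers[j],
        normalize_denominator = markers[j] %in% normalize_denominator)))
    }
  }
  if (k >= 3) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) for (d in seq_len(k)) {
      if (d == i || d == j) next
      out <- c(out, list(composite_expression(
        c(markers[i], markers[j]), markers[d],
        normalize_denominator = markers[d] %in% normalize_denominator)))
    }
  }
  out
}

#' Enumerative composite-biomarker search ranked by AUC
#'
#' Evaluates every expression of the composite grammar over the marker
#' set and ranks them by AUC (descending), ties broken lexicographically
#' by the expression string, so the ranking is deterministic.
#' Morphology-derived metrics (e.g. a per-subject morphologically
#' distinct fraction) participate simply by being present as additional
#' markers in the cohort table.
#'
#' @param cohort long cohort tibble (`subject`, `group`, `marker`,
#'   `value`).
#' @param markers markers to search over (default: all in the cohort).
#' @param case label of the positive class (see [auc()]).
#' @param normalize_denominator markers to group-max normalize when used
#'   as denominators.
#' @return Tibble with `expression`, `auc`, `rank`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_control = 5, n_disease = 5, seed = 1))
#' head(composite_search(coh$counts), 3)
composite_search <- function(cohort, markers = NULL, case = NULL,
                             normalize_denominator = character()) {
  if (is.null(markers)) markers <- unique(cohort$marker)
  if (length(markers) < 1) abort("Need at least one marker.")
  exprs <- enumerate_composites(markers, normalize_denominator)
  res <- purrr::map(exprs, function(e) {
    # count markers can be zero; a ratio undefined for some subject is
    # dropped from the ranking rather than aborting the search
    sc <- tryCatch(evaluate_composite(cohort, e), error = function(err) NULL)
    if (is.null(sc)) return(NULL)
    tibble::tibble(expression = format(e),
                   auc = auc(sc$score, sc$group, case))
  }) |> dplyr::bind_rows()
  if (nrow(res) == 0) abort("No composite expression could be evaluated.")
  res <- dplyr::arrange(res, dplyr::desc(.data$auc), .data$expression)
  dplyr::mutate(res, rank = dplyr::row_number())
}

#' Fold change between disease and control groups
#'
#' Ratio of group means (primary) and of group medians (also reported,
#' since cohort data are usually displayed as box plots).
#'
#' @param disease,control numeric values for the two groups.
#' @return One-row tibble: `fold_mean`, `fold_median`.
#' @export
#' @examples
#' fold_change(c(4, 6), c(2, 3))
fold_change <- function(disease, control) {
  disease <- disease[is.finite(disease)]
  control <- control[is.finite(control)]
  if (length(control) == 0 || mean(control) <= 0) {
    abort("Control mean must be positive.")
  }
  if (length(disease) == 0) abort("`disease` must be non-empty.")
  tibble::tibble(
    fold_mean = mean(disease) / mean(control),
    fold_median = if (median(control) > 0)
      median(disease) / median(control) else NA_real_
  )
}

#' Correlation between two biomarkers
#'
#' Pearson's correlation, or Spearman rank correlation when the
#' dependence is non-linear.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `estimate`, `p_value`, `method`, `n`.
#' @export
#' @examples
#' correlate(1:10, exp(1:10), method = "spearman")
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 method = method, n = length(x))
}

#' Power of the two-sided two-sample t-test
#'
#' Computed from the noncentral t distribution with noncentrality
#' d * sqrt(n/2) and 2n - 2 degrees of freedom.  At the planning values
#' of the assay (Cohen's d = 2, n = 10 per group, alpha = 0.05) the
#' power is 99% to the nearest percent.
#'
#' @param d_cohen standardized effect size (Cohen's d, >= 0).
#' @param n_per_group subjects per group (>= 2).
#' @param alpha two-sided significance level.
#' @return The power in `[0, 1]`.
#' @export
#' @examples
#' power_two_sample_t(2, 10)
power_two_sample_t <- function(d_cohen, n_per_group, alpha = 0.05) {
  if (d_cohen < 0) abort("`d_cohen` must be >= 0.")
  if (n_per_group < 2) abort("`n_per_group` must be >= 2.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  df <- 2 * n_per_group - 2
  ncp <- d_cohen * sqrt(n_per_group / 2)
  tcrit <- qt(1 - alpha / 2, df)
  (1 - pt(tcrit, df, ncp)) + pt(-tcrit, df, ncp)
}

#' Intra- and inter-assay precision (coefficient of variation)
#'
#' Per-sample CV is 100 * SD / mean.  Intra-assay CV averages the CVs of
#' within-plate replicate sets; inter-assay CV averages the per-sample
#' CVs of plate-level values across plates.  A CV below 20% is the
#' conventional acceptability bound.
#'
#' @param data tibble with one measurement per row.
#' @param sample,plate,value column names (strings) identifying the
#'   sample, the plate/run, and the measured value.
#' @param cv_limit acceptability bound in percent (default 20).
#' @return Object of class `cv_precision`: list with `intra_cv`,
#'   `inter_cv`, `acceptable`, `cv_limit` and the `per_sample` tables.
#' @export
#' @examples
#' d <- tibble::tibble(sample = rep("a", 2), plate = 1, value = c(90, 110))
#' cv_precision(d)$intra_cv # ~14.1
cv_precision <- function(data, sample = "sample", plate = "plate",
                         value = "value", cv_limit = 20) {
  for (col in c(sample, plate, value)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  }
  d <- tibble::tibble(sample = data[[sample]], plate = data[[plate]],
                      value = data[[value]])
  if (any(!is.finite(d$value))) abort("Non-finite measurement values.")
  cnt <- dplyr::count(d, .data$sample)
  if (any(cnt$n < 2)) abort("Every sample needs at least 2 replicates.")
  cv_of <- function(v) {
    if (length(v) == 0) return(NA_real_)
    if (mean(v) == 0) abort("Zero mean measurement: CV undefined.")
    100 * sd(v) / mean(v)
  }
  intra_tbl <- d |>
    dplyr::group_by(.data$sample, .data$plate) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(cv = cv_of(.data$value), .groups = "drop")
  inter_tbl <- d |>
    dplyr::group_by(.data$sample, .data$plate) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$sample) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(cv = cv_of(.data$value), .groups = "drop")
  intra <- if (nrow(intra_tbl)) mean(intra_tbl$cv) else NA_real_
  inter <- if (nrow(inter_tbl)) mean(inter_tbl$cv) else NA_real_
  structure(
    list(intra_cv = intra, inter_cv = inter,
         acceptable = all(c(intra, inter) < cv_limit, na.rm = TRUE),
         cv_limit = cv_limit,
         per_sample = list(intra = intra_tbl, inter = inter_tbl)),
    class = "cv_precision"
  )
}

#' @export
print.cv_precision <- function(x, ...) {
  cat(sprintf("Assay precision: intra-CV %.1f%%, inter-CV %.1f%% (limit %.0f%%) — %s\n",
              x$intra_cv, x$inter_cv, x$cv_limit,
              if (isTRUE(x$acceptable)) "acceptable" else "NOT acceptable"))
  invisible(x)
}
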