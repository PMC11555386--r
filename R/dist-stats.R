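#' Empirical cumulative distribution curve
#'
#' Standard right-continuous ECDF, returned as a tidy curve (the pooled
#' per-aggregate size and shape distributions are compared between
#' diagnostic groups as cumulative histograms).
#'
#' @param values numeric vector (at least one finite value).
#' @return Tibble with `value` (sorted) and `frac` (cumulative fraction,
#'   ending at 1).
#' @export
#' @examples
#' ecdf_curve(c(3, 1, 2))
ecdf_curve <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("Need at least one finite value.")
  tibble::tibble(value = sort(values),
                 frac = seq_along(values) / length(values))
}

# two-sample KS critical coefficient at confidence `1 - alpha`:
# c(alpha) = sqrt(-log(alpha/2) / 2); c(0.01) = 1.628
ks_coefficient <- function(alpha) sqrt(-log(alpha / 2) / 2)

#' Two-group ECDF difference curve with a KS confidence band
#'
#' Computes Delta ECDF = F_a - F_b on the pooled sorted grid together
#' with the two-sample Kolmogorov-Smirnov band
#' c(alpha) * sqrt((n + m) / (n * m)) at the requested confidence
#' (c = 1.628 at 99%).  Grid regions where |Delta| exceeds the band are
#' flagged; they are where the two morphology distributions differ
#' beyond sampling noise.
#'
#' @param a,b numeric samples (group a minus group b is reported).
#' @param confidence band confidence level (default 0.99).
#' @return Object of class `ecdf_diff`: list with `curve` (tibble
#'   `value`, `delta`, `exceeds`), `band`, `D` (max |Delta|), `n`, `m`,
#'   `confidence`.
#' @export
#' @examples
#' d <- ecdf_difference(rnorm(100), rnorm(100, 1))
#' d$D > d$band
ecdf_difference <- function(a, b, confidence = 0.99) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) abort("Both samples must be non-empty.")
  if (confidence <= 0 || confidence >= 1) abort("`confidence` must be in (0, 1).")
  grid <- sort(unique(c(a, b)))
  delta <- ecdf(a)(grid) - ecdf(b)(grid)
  band <- ks_coefficient(1 - confidence) *
    sqrt((length(a) + length(b)) / (length(a) * length(b)))
  structure(
    list(
      curve = tibble::tibble(value = grid, delta = delta,
                             exceeds = abs(delta) > band),
      band = band,
      D = max(abs(delta)),
      n = length(a), m = length(b),
      confidence = confidence
    ),
    class = "ecdf_diff"
  )
}

#' @export
print.ecdf_diff <- function(x, ...) {
  cat(sprintf(
    "ECDF difference (n = %d vs m = %d): D = %.4f, %d%% KS band = %.4f%s\n",
    x$n, x$m, x$D, round(100 * x$confidence), x$band,
    if (x$D > x$band) " (exceeded)" else ""))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of |F_a - F_b|; the p-value comes from the
#' asymptotic Kolmogorov distribution evaluated at
#' D * sqrt(n*m/(n+m)).
#'
#' @param a,b numeric samples.
#' @return One-row tibble: `D`, `p_value`, `n`, `m`.
#' @export
#' @examples
#' ks_two_sample(1:10, 1:10)
ks_two_sample <- function(a, b) {
  d <- ecdf_difference(a, b)
  lambda <- d$D * sqrt(d$n * d$m / (d$n + d$m))
  p <- if (lambda == 0) 1 else {
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  tibble::tibble(D = d$D, p_value = p, n = d$n, m = d$m)
}

#' Fraction of morphologically distinctive (small, round) aggregates
#'
#' Proportion of aggregates with area <= `area_max` AND circularity >=
#' `circ_min` — the "smaller and rounder" phenotype fraction used as a
#' per-subject biomarker.
#'
#' @param aggregates tibble with `area_um2` and `circularity` columns.
#' @param area_max area threshold in um^2.
#' @param circ_min circularity threshold.
#' @return The fraction in `[0, 1]`.
#' @export
#' @examples
#' ag <- tibble::tibble(area_um2 = c(0.01, 0.2), circularity = c(0.9, 0.3))
#' fraction_small_round(ag, 0.05, 0.5)
fraction_small_round <- function(aggregates, area_max, circ_min) {
  if (nrow(aggregates) == 0) {
    abort("Fraction undefined for an empty aggregate set.")
  }
  mean(aggregates$area_um2 <= area_max & aggregates$circularity >= circ_min)
}

#' Search the combined area/circularity threshold separating two groups
#'
#' Scans a grid of (area_max, circ_min) thresholds; at each cell the
#' per-subject small-round fractions are computed and the two groups
#' compared with an exact permutation test on the difference of group
#' means.  Among the cells with p below `alpha`, the one maximizing the
#' absolute fraction difference is returned (ties broken by smaller p,
#' then smaller area_max, then smaller circ_min).  When no cell is
#' significant the best |difference| is returned flagged
#' `significant = FALSE`.  Subjects — not pooled aggregates — are the
#' unit of the test.  No multiplicity correction is applied across the
#' grid: the procedure is a maximizing scan, and the full grid is
#' returned so users can bootstrap if desired.
#'
#' @param morph tibble of per-aggregate morphology with columns
#'   `subject`, `group`, `area_um2`, `circularity` (e.g. the
#'   `morphology` element of [simulate_cohort()]).
#' @param area_grid area thresholds; default 40 log-spaced steps between
#'   the pooled 5th and 95th area percentiles.
#' @param circ_grid circularity thresholds (default 0, 0.05, ..., 1).
#' @param case_group label of the case group (difference is case minus
#'   the other group); defaults to `"disease"` if present, otherwise the
#'   second group level.
#' @param alpha significance gate (default 0.05).
#' @param max_exact largest number of group assignments enumerated
#'   exactly; beyond it the permutation p is Monte-Carlo.
#' @param n_perm Monte-Carlo resamples when not exact.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return Object of class `morph_threshold`: the selected `area_max`,
#'   `circ_min`, `delta_f`, `p_value`, `significant`, the per-subject
#'   `fractions` at the selected cell, and the full `grid` tibble.
#' @export
threshold_search <- function(morph,
                             area_grid = NULL,
                             circ_grid = seq(0, 1, by = 0.05),
                             case_group = NULL,
                             alpha = 0.05,
                             max_exact = 184756,
                             n_perm = 1e4,
                             seed = NULL) {
  req <- c("subject", "group", "area_um2", "circularity")
  miss <- setdiff(req, names(morph))
  if (length(miss)) abort(sprintf("`morph` lacks column(s): %s.",
                                  paste(miss, collapse = ", ")))
  groups <- unique(morph$group)
  if (length(groups) != 2L) abort("Exactly two groups are required.")
  if (is.null(case_group)) {
    case_group <- if ("disease" %in% groups) "disease" else groups[2]
  }
  ctrl_group <- setdiff(groups, case_group)
  subj <- unique(morph[, c("subject", "group")])
  if (min(table(subj$group)) < 2L) abort("Need at least 2 subjects per group.")
  if (is.null(area_grid)) {
    qs <- quantile(morph$area_um2, c(0.05, 0.95))
    area_grid <- exp(seq(log(qs[1]), log(qs[2]), length.out = 40))
  }
  area_grid <- sort(area_grid)
  circ_grid <- sort(circ_grid)

  is_case <- subj$group == case_group
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  # per-subject fractions at every grid cell via a 2D cumulative
  # histogram: count(area <= a_i & circ >= c_j) for all (i, j) at once
  cells <- tidyr::expand_grid(area_max = area_grid, circ_min = circ_grid)
  n_a <- length(area_grid)
  n_c <- length(circ_grid)
  by_subj <- split(morph[, c("area_um2", "circularity")], morph$subject)
  by_subj <- by_subj[subj$subject]
  fmat <- vapply(by_subj, function(d) {
    ba <- findInterval(d$area_um2, area_grid, left.open = TRUE) + 1L
    bc <- findInterval(d$circularity, circ_grid)
    h <- matrix(0, n_a + 1L, n_c + 1L)
    tab <- table(factor(ba, levels = 1:(n_a + 1L)),
                 factor(bc + 1L, levels = 1:(n_c + 1L)))
    h[] <- tab
    cum <- apply(h, 2, cumsum)                       # area <= a_i
    cum <- t(apply(cum, 1, function(v) rev(cumsum(rev(v))))) # circ >= c_j
    # cell (i, j): counts with bin_a <= i and bin_c >= j
    as.vector(t(cum[seq_len(n_a), 2:(n_c + 1L), drop = FALSE])) / nrow(d)
  }, numeric(nrow(cells)))
  # fmat: cells (area outer, circ inner) x subjects
  if (!is.matrix(fmat)) fmat <- matrix(fmat, nrow = nrow(cells))
  delta_obs <- colMeans(t(fmat[, is_case, drop = FALSE])) -
    colMeans(t(fmat[, !is_case, drop = FALSE]))

  n_assign <- choose(n1 + n2, n1)
  eps <- 1e-12
  if (n_assign <= max_exact) {
    comb <- combn(n1 + n2, n1)
    assign_mat <- matrix(0, ncol(comb), n1 + n2)
    assign_mat[cbind(rep(seq_len(ncol(comb)), each = n1), as.vector(comb))] <- 1
    method <- "exact"
    n_used <- ncol(comb)
  } else {
    assign_mat <- with_seed(seed %||% 0L, {
      t(replicate(n_perm, {
        v <- numeric(n1 + n2)
        v[sample.int(n1 + n2, n1)] <- 1
        v
      }))
    })
    assign_mat[1, ] <- as.numeric(is_case) # include the observed split
    method <- "monte_carlo"
    n_used <- nrow(assign_mat)
  }
  # assignment x cells mean differences, in cell chunks to bound memory
  p_vals <- numeric(nrow(cells))
  chunk <- max(1L, floor(2e6 / nrow(assign_mat)))
  for (start in seq(1L, nrow(cells), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(cells))
    fm <- t(fmat[idx, , drop = FALSE])
    deltas <- (assign_mat %*% fm) / n1 - ((1 - assign_mat) %*% fm) / n2
    p_vals[idx] <- colMeans(
      abs(deltas) >= matrix(abs(delta_obs[idx]), nrow(deltas),
                            length(idx), byrow = TRUE) - eps)
  }

  grid <- dplyr::mutate(cells, delta_f = delta_obs, p_value = p_vals)
  sig <- grid$p_value < alpha
  pool <- if (any(sig)) grid[sig, ] else grid
  ord <- order(-abs(pool$delta_f), pool$p_value, pool$area_max, pool$circ_min)
  best <- pool[ord[1], ]
  sel <- which(cells$area_max == best$area_max &
                 cells$circ_min == best$circ_min)[1]
  fractions <- tibble::tibble(
    subject = subj$subject, group = subj$group, fraction = fmat[sel, ]
  )
  structure(
    list(
      area_max = best$area_max,
      circ_min = best$circ_min,
      delta_f = best$delta_f,
      p_value = best$p_value,
      significant = any(sig),
      case_group = case_group,
      control_group = ctrl_group,
      fractions = fractions,
      grid = grid,
      alpha = alpha,
      permutation = method,
      n_permutations = n_used,
      multiplicity_corrected = FALSE
    ),
    class = "morph_threshold"
  )
}

#' @export
print.morph_threshold <- function(x, ...) {
  cat("Combined morphology threshold search\n")
  cat(sprintf("  area <= %.4g um^2, circularity >= %.2f\n",
              x$area_max, x$circ_min))
  cat(sprintf("  fraction difference (%s - %s): %+.3f, p = %.4g (%s)%s\n",
              x$case_group, x$control_group, x$delta_f, x$p_value,
              x$permutation,
              if (x$significant) "" else " [no significant cell]"))
  cat("  note: maximizing scan over the grid, no multiplicity correction\n")
  invisible(x)
}
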