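# broom-style tidiers for the package's fitted objects.

#' Tidy a denaturation fit
#'
#' @param x a [fit_denaturation()] result.
#' @param ... unused.
#' @return Tibble with one row per parameter (`N0`, `c_e`): `estimate`
#'   and delta-method `std_error`.
#' @method tidy denat_fit
#' @export
tidy.denat_fit <- function(x, ...) {
  se <- suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"]
  slope <- coef(x$fit)[["conc_M"]]
  tibble::tibble(
    term = c("N0", "c_e"),
    estimate = c(x$n0, x$c_e),
    std_error = c(x$n0 * se[["(Intercept)"]],
                  if (x$decaying) se[["conc_M"]] / slope^2 else NA_real_)
  )
}

#' @rdname tidy.denat_fit
#' @return `glance()`: one-row tibble with `r_squared`, `n`, `decaying`,
#'   `zero_adjusted`.
#' @method glance denat_fit
#' @export
glance.denat_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    n = nrow(x$data),
    decaying = x$decaying,
    zero_adjusted = x$zero_adjusted
  )
}

#' Tidy a threshold-search result
#'
#' @param x a [threshold_search()] result.
#' @param ... unused.
#' @return `tidy()`: the full grid tibble (`area_max`, `circ_min`,
#'   `delta_f`, `p_value`).
#' @method tidy morph_threshold
#' @export
tidy.morph_threshold <- function(x, ...) x$grid

#' @rdname tidy.morph_threshold
#' @return `glance()`: one-row tibble with the selected threshold and
#'   its test summary.
#' @method glance morph_threshold
#' @export
glance.morph_threshold <- function(x, ...) {
  tibble::tibble(
    area_max = x$area_max, circ_min = x$circ_min,
    delta_f = x$delta_f, p_value = x$p_value,
    significant = x$significant, permutation = x$permutation,
    n_permutations = x$n_permutations
  )
}

#' Tidy a permutation test
#'
#' @param x a [permutation_exact_test()] result.
#' @param ... unused.
#' @return One-row tibble: `statistic`, `p_value`, `method`,
#'   `n_permutations`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n_permutations = x$n_permutations)
}

#' Tidy a precision assessment
#'
#' @param x a [cv_precision()] result.
#' @param ... unused.
#' @return One-row tibble: `intra_cv`, `inter_cv`, `acceptable`,
#'   `cv_limit`.
#' @method glance cv_precision
#' @export
glance.cv_precision <- function(x, ...) {
  tibble::tibble(intra_cv = x$intra_cv, inter_cv = x$inter_cv,
                 acceptable = x$acceptable, cv_limit = x$cv_limit)
}
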