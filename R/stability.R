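#' Fit an exponential denaturation curve
#'
#' Aggregate counts under increasing denaturant concentration follow
#' N(c) = N0 * exp(-c / c_e); c_e is the concentration at which the
#' fitted curve falls to N0/e (~0.4 of the untreated count).  The fit is
#' log-linear least squares — robust at small counts — with zero counts
#' replaced by 0.5 (continuity correction, flagged in the result).
#' Counts that do not decrease across the full concentration range are
#' flagged non-decaying and c_e is not reported.
#'
#' @param data optional data frame with the concentration and count
#'   columns (e.g. from [simulate_denaturation()] or
#'   [read_denaturation()]).
#' @param conc,count column names when `data` is given, or numeric
#'   vectors when it is not.
#' @return Object of class `denat_fit`: list with `n0`, `c_e`,
#'   `r_squared`, `decaying`, `zero_adjusted`, the underlying `fit`
#'   (an `lm` on log counts) and the `data` used.  Supports [tidy()],
#'   [glance()], `predict()` and [autoplot()].
#' @export
#' @examples
#' d <- simulate_denaturation(100, 0.5, noise_cv = 0)
#' fit_denaturation(d)$c_e
fit_denaturation <- function(data = NULL, conc = "conc_M",
                             count = "count_mean") {
  if (is.data.frame(data)) {
    for (col in c(conc, count)) {
      if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
    }
    cc <- data[[conc]]
    nn <- data[[count]]
  } else {
    cc <- data %||% conc
    if (is.character(cc)) abort("Provide a data frame or numeric vectors.")
    nn <- count
  }
  ok <- is.finite(cc) & is.finite(nn)
  cc <- cc[ok]; nn <- nn[ok]
  if (any(nn < 0)) abort("Counts must be non-negative.")
  if (sum(nn > 0) < 3) abort("Need at least 3 concentrations with positive counts.")
  ord <- order(cc)
  cc <- cc[ord]; nn <- nn[ord]
  zero_adjusted <- any(nn == 0)
  nn_fit <- ifelse(nn == 0, 0.5, nn)
  df <- tibble::tibble(conc_M = cc, count = nn, log_count = log(nn_fit))
  fit <- lm(log_count ~ conc_M, data = df)
  slope <- coef(fit)[["conc_M"]]
  n0 <- exp(coef(fit)[["(Intercept)"]])
  decaying <- slope < 0
  c_e <- if (decaying) -1 / slope else NA_real_
  structure(
    list(n0 = n0, c_e = c_e,
         r_squared = suppressWarnings(summary(fit))$r.squared,
         decaying = decaying,
         zero_adjusted = zero_adjusted,
         fit = fit, data = df),
    class = "denat_fit"
  )
}

#' @export
print.denat_fit <- function(x, ...) {
  if (x$decaying) {
    cat(sprintf("Denaturation fit: N(c) = %.1f * exp(-c / %.3g M), R^2 = %.3f\n",
                x$n0, x$c_e, x$r_squared))
    cat(sprintf("  at c = c_e the fitted count is N0/e = %.1f\n", x$n0 / exp(1)))
  } else {
    cat("Denaturation fit: counts do not decay over the range (flagged).\n")
  }
  if (x$zero_adjusted) cat("  zero counts replaced by 0.5 before logging\n")
  invisible(x)
}

#' Predicted counts from a denaturation fit
#'
#' @param object a [fit_denaturation()] result.
#' @param newdata optional vector of concentrations (molar) or a data
#'   frame with a `conc_M` column; defaults to the fitted
#'   concentrations.
#' @param ... unused.
#' @return Predicted counts N0 * exp(-c / c_e).
#' @export
predict.denat_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$conc_M else
    if (is.data.frame(newdata)) newdata$conc_M else newdata
  if (!object$decaying) {
    return(exp(predict(object$fit, tibble::tibble(conc_M = cc))))
  }
  object$n0 * exp(-cc / object$c_e)
}

#' Fraction of aggregates removed by immunodepletion
#'
#' 1 - after/before, clipped to `[0, 1]`; chemical specificity of the
#' assay shows as near-complete depletion when the target protein is
#' immunoprecipitated away.
#'
#' @param count_before,count_after aggregate counts before and after
#'   depletion (`count_before` > 0).
#' @return Fraction removed in `[0, 1]`.
#' @export
#' @examples
#' depletion_fraction(100, 25)
depletion_fraction <- function(count_before, count_after) {
  if (any(!is.finite(count_before)) || any(count_before <= 0)) {
    abort("`count_before` must be positive.")
  }
  if (any(!is.finite(count_after)) || any(count_after < 0)) {
    abort("`count_after` must be non-negative.")
  }
  pmin(pmax(1 - count_after / count_before, 0), 1)
}
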