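#' Cohort specification for the synthetic two-group study generator
#'
#' Defines the conditions of a simulated case-control study: group sizes,
#' per-marker negative-binomial baselines and disease/control fold
#' changes, an optional per-subject aggregate morphology component, and
#' an optional shared per-subject scale factor emulating sample
#' loading/concentration nuisance.
#'
#' Default markers emulate the serum aggregate panel of the assay: ASC
#' specks (fold 4.2, the late-stage disease regime), amyloid-beta
#' (fold 1: its serum counts barely change with disease, which is what
#' makes it usable as a normalising denominator), p-tau and
#' alpha-synuclein (moderately increased).  Morphology, when enabled,
#' draws each subject's aggregates from the two-component mixture of
#' [truth_aggregates()] (area/circularity values, not rendered images),
#' with the small-round mixture weight increased in disease by
#' `small_round_excess`.
#'
#' @param n_control,n_disease subjects per group (at least 2 each).
#' @param markers data frame with columns `marker`, `mean` (control
#'   negative-binomial mean), `dispersion` (NB size parameter) and
#'   `fold` (disease/control fold change, > 0).
#' @param include_morphology simulate per-subject aggregate morphology?
#' @param n_aggregates_per_subject aggregates drawn per subject.
#' @param small_round_frac_control control-group small-round fraction.
#' @param small_round_excess added small-round fraction in disease.
#' @param subject_effect_cv coefficient of variation of a lognormal
#'   per-subject factor multiplying all marker means of that subject
#'   (0 = off).
#' @param seed RNG seed used by [simulate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 20L,
                        n_disease = 20L,
                        markers = default_markers(),
                        include_morphology = FALSE,
                        n_aggregates_per_subject = 300L,
                        small_round_frac_control = 0.30,
                        small_round_excess = 0.08,
                        subject_effect_cv = 0,
                        seed = NULL) {
  if (n_control < 2 || n_disease < 2) abort("Need at least 2 subjects per group.")
  req <- c("marker", "mean", "dispersion", "fold")
  miss <- setdiff(req, names(markers))
  if (length(miss)) abort(sprintf("`markers` lacks column(s): %s.",
                                  paste(miss, collapse = ", ")))
  if (any(markers$fold <= 0)) abort("Fold changes must be > 0.")
  if (any(markers$mean <= 0) || any(markers$dispersion <= 0)) {
    abort("Marker means and dispersions must be > 0.")
  }
  frac_d <- small_round_frac_control + small_round_excess
  if (small_round_frac_control < 0 || small_round_frac_control > 1 ||
      frac_d < 0 || frac_d > 1) {
    abort("Small-round fractions must lie in [0, 1].")
  }
  if (subject_effect_cv < 0) abort("`subject_effect_cv` must be >= 0.")
  structure(
    list(
      n_control = as.integer(n_control),
      n_disease = as.integer(n_disease),
      markers = tibble::as_tibble(markers),
      include_morphology = isTRUE(include_morphology),
      n_aggregates_per_subject = as.integer(n_aggregates_per_subject),
      small_round_frac_control = small_round_frac_control,
      small_round_excess = small_round_excess,
      subject_effect_cv = subject_effect_cv,
      seed = seed
    ),
    class = "cohort_spec"
  )
}

#' Default marker panel of the synthetic cohort generator
#'
#' @return Tibble of marker baselines: control NB mean, dispersion (NB
#'   size) and disease/control fold change.
#' @export
default_markers <- function() {
  tibble::tibble(
    marker = c("ASC", "Abeta", "ptau", "asyn"),
    mean = c(40, 100, 20, 25),
    dispersion = c(10, 10, 10, 10),
    fold = c(4.2, 1.0, 2.5, 2.0)
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d control vs %d disease subjects\n",
              x$n_control, x$n_disease))
  print(x$markers)
  if (x$include_morphology) {
    cat(sprintf("Morphology: %d aggregates/subject, small-round %.2f (control) vs %.2f (disease)\n",
                x$n_aggregates_per_subject, x$small_round_frac_control,
                x$small_round_frac_control + x$small_round_excess))
  }
  if (x$subject_effect_cv > 0) {
    cat(sprintf("Shared subject scale factor CV: %.2f\n", x$subject_effect_cv))
  }
  invisible(x)
}

#' Simulate a two-group cohort of per-subject marker counts
#'
#' Marker counts are negative-binomial with group-specific means
#' (control mean times fold change in disease), optionally multiplied by
#' a shared lognormal per-subject factor (mean 1).  When morphology is
#' enabled, each subject additionally receives a set of aggregate
#' (area, circularity) values from the two-component morphology mixture,
#' with the disease group's small-round weight shifted up by the planted
#' excess.  Output is deterministic under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `speck_cohort`: a list with `counts`
#'   (long tibble `subject`, `group`, `marker`, `value`), `morphology`
#'   (tibble `subject`, `group`, `area_um2`, `circularity`, or `NULL`)
#'   and the `spec`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_control = 5, n_disease = 5, seed = 1))
#' head(coh$counts)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    subjects <- tibble::tibble(
      subject = sprintf("S%03d", seq_len(spec$n_control + spec$n_disease)),
      group = rep(c("control", "disease"), c(spec$n_control, spec$n_disease))
    )
    cv <- spec$subject_effect_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      subjects$scale <- rlnorm(nrow(subjects), -sdlog^2 / 2, sdlog)
    } else {
      subjects$scale <- 1
    }
    counts <- tidyr::crossing(subjects, spec$markers) |>
      dplyr::mutate(
        mu = .data$mean * ifelse(.data$group == "disease", .data$fold, 1) *
          .data$scale,
        value = rnbinom(dplyr::n(), mu = .data$mu, size = .data$dispersion)
      ) |>
      dplyr::select("subject", "group", "marker", "value") |>
      dplyr::arrange(.data$subject, .data$marker)

    morphology <- NULL
    if (spec$include_morphology) {
      morphology <- purrr::pmap(subjects, function(subject, group, scale) {
        w <- spec$small_round_frac_control +
          if (group == "disease") spec$small_round_excess else 0
        n <- spec$n_aggregates_per_subject
        small <- runif(n) < w
        d_nm <- ifelse(small, runif(n, 35, 150), runif(n, 150, 1000))
        circ <- ifelse(small, runif(n, 0.7, 1), runif(n, 0.2, 0.7))
        tibble::tibble(
          subject = subject, group = group,
          area_um2 = pi * (d_nm / 2000)^2,
          circularity = circ
        )
      }) |> dplyr::bind_rows()
    }
    structure(list(counts = counts, morphology = morphology, spec = spec),
              class = "speck_cohort")
  })
}

#' @export
print.speck_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d markers\n",
              dplyr::n_distinct(x$counts$subject),
              dplyr::n_distinct(x$counts$marker)))
  if (!is.null(x$morphology)) {
    cat(sprintf("With morphology: %d aggregates total\n", nrow(x$morphology)))
  }
  invisible(x)
}
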