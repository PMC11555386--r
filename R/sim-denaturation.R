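#' Simulate a chemical denaturation series
#'
#' Aggregate counts decay exponentially with denaturant concentration:
#' N(c) = N0 * exp(-c / c_e), where `c_e` is the concentration at which
#' the count falls to N0/e.  Multiplicative lognormal noise with the
#' given coefficient of variation is applied; with `noise_cv = 0` the
#' curve is exact.
#'
#' @param n0 untreated count (aggregates per FOV), > 0.
#' @param c_e characteristic denaturant concentration in molar, > 0.
#' @param concs denaturant concentrations (molar); default covers the
#'   fine-increment range 0.05-0.72 M used to bracket c_e in the assay.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param n_fov fields of view per concentration (reported SE scale).
#' @param seed optional RNG seed.
#' @return Tibble with `conc_M`, `count_mean`, `count_se`.
#' @export
#' @examples
#' simulate_denaturation(100, 0.5, noise_cv = 0)
simulate_denaturation <- function(n0 = 100,
                                  c_e = 0.5,
                                  concs = seq(0.05, 0.72, length.out = 8),
                                  noise_cv = 0.05,
                                  n_fov = 12L,
                                  seed = NULL) {
  check_scalar_positive(n0, "n0")
  check_scalar_positive(c_e, "c_e")
  if (any(concs < 0)) abort("Concentrations must be >= 0.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  concs <- sort(concs)
  with_seed(seed, {
    mu <- n0 * exp(-concs / c_e)
    eps <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      rlnorm(length(concs), -sdlog^2 / 2, sdlog)
    } else rep(1, length(concs))
    tibble::tibble(
      conc_M = concs,
      count_mean = mu * eps,
      count_se = mu * eps * noise_cv / sqrt(n_fov)
    )
  })
}
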