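# speckpull

Single-aggregate quantification and biomarker statistics for
inflammasome **ASC specks** imaged by single-molecule pull-down
(SiMPull) with dSTORM super-resolution.

ASC specks — micron-scale polymers of the inflammasome adaptor protein
ASC — escape dying cells and circulate in serum and CSF, making their
number, size and shape a candidate fluid biomarker of inflammation in
Parkinson's and Alzheimer's disease.  The assay captures individual
specks on an antibody surface and images them twice: a diffraction-
limited acquisition for *counting* specks per field of view, and a
dSTORM acquisition (8000 frames, ~30 nm resolution) for per-aggregate
*morphology*.  `speckpull` implements the full downstream analysis for
people running or modelling this kind of single-aggregate assay:

* **Spot counting** — frame averaging, median-background subtraction,
  a robust σ-relative threshold (MAD × 1.4826), 8-connected component
  counting with an area band, per-sample summaries over 12 FOVs, and
  control-well assessment (compare, never subtract).
* **Morphology** — drift correction by block cross-correlation,
  15 nm histogram rendering, connected-component segmentation, and
  per-aggregate area *A*, Crofton perimeter *P*, circularity
  *C* = 4π*A*/*P*², equivalent diameters *d* = 2√(*A*/π) and *P*/π,
  with a 30 nm resolution cut and frame-sufficiency diagnostics.
* **Distribution statistics** — ECDF difference curves with the
  two-sample Kolmogorov–Smirnov 99% band
  (1.628·√((n+m)/(nm))), and a grid search for the combined
  (area ≤ a, circularity ≥ c) threshold maximizing the between-group
  difference in per-subject "small and round" fractions, gated by an
  exact permutation test.
* **Biomarker statistics** — rank-based (Mann–Whitney) AUC and ROC
  curves, exact permutation and binomial tests, fold changes,
  correlations, group-max denominator normalization, an enumerative
  composite-biomarker search over the grammar
  {m, m₁+m₂, m₁/m₃, (m₁+m₂)/m₃}, noncentral-t power analysis, and
  intra/inter-assay CV precision.
* **Stability** — exponential denaturation-curve fitting
  N(c) = N₀·exp(−c/cₑ) and immunodepletion fractions.
* **Synthetic data** — a first-class generator for blinking-
  fluorophore localization tables with ground truth, Poisson TIRF
  stacks, two-group cohorts with planted fold changes and morphology
  effects, and denaturation series, so the whole pipeline is testable
  without any patient data.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods
for fitted objects and `autoplot()` methods for curves and grids.
A thin CLI lives at `inst/cli/speckpull`
(subcommands `simulate`, `count`, `morph`, `stats`, `biomarker`,
`fit-denaturation`, `run`).

## Worked example

```r
library(speckpull)

coh <- simulate_cohort(cohort_spec(n_control = 10, n_disease = 10,
                                   include_morphology = TRUE,
                                   n_aggregates_per_subject = 2000,
                                   seed = 42))
thr <- threshold_search(coh$morphology, seed = 1)
glance(thr)
#> # A tibble: 1 × 7
#>   area_max circ_min delta_f   p_value significant permutation n_permutations
#>      <dbl>    <dbl>   <dbl>     <dbl> <lgl>       <chr>                <int>
#> 1   0.0305     0.65  0.0770 0.0000108 TRUE        exact               184756

asc <- subset(coh$counts, marker == "ASC")
auc(asc$value, asc$group)
#> [1] 0.99
fold_change(asc$value[asc$group == "disease"],
            asc$value[asc$group == "control"])
#> # A tibble: 1 × 2
#>   fold_mean fold_median
#>       <dbl>       <dbl>
#> 1      3.40        3.55

head(composite_search(coh$counts, normalize_denominator = "Abeta"), 3)
#> # A tibble: 3 × 3
#>   expression                   auc  rank
#>   <chr>                      <dbl> <int>
#> 1 (ASC + ptau) / norm(Abeta)  1        1
#> 2 ASC + ptau                  1        2
#> 3 ASC                         0.99     3

fit <- fit_denaturation(simulate_denaturation(100, 0.5, noise_cv = 0.05,
                                              seed = 7))
fit
#> Denaturation fit: N(c) = 101.1 * exp(-c / 0.487 M), R^2 = 0.986
#>   at c = c_e the fitted count is N0/e = 37.2
```

Reading the output: the threshold search planted an 8% excess of small
round aggregates in the disease group and recovered Δf = 0.077 with an
area threshold at the boundary of the planted small-round component
(p from the exact permutation test over all 184 756 group
assignments).  The ASC count alone separates the groups with
AUC = 0.99 at a 3.4-fold mean increase (4.2 planted, n = 10/group),
the composite (ASC + p-tau)/Aβ ranks top with AUC = 1, and the
denaturation fit recovers cₑ within 3% at 5% multiplicative noise.
Diameter conversion of the serum area thresholds:
`area_to_diameter(0.04)` → 0.226 µm and `area_to_diameter(0.05)` →
0.252 µm.

## Layout

```
R/                  implementation (synthio, speckcount, storm-morph,
                    dist-stats, biomarker, stability, io/pipeline)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/speck-quantification.Rmd   methods vignette
inst/cli/speckpull  command-line wrapper
```
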