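---
title: "Quantifying single ASC specks: counts, morphology and composite biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single ASC specks: counts, morphology and composite biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckpull)
```

## The measurement problem

ASC specks are micron-scale polymeric assemblies of the inflammasome
adaptor protein ASC.  They form when inflammasomes activate, can be
released from dying cells, and are detectable in serum, CSF and
brain-derived fluid — which makes their number, size and shape a
candidate fluid biomarker of inflammation in neurodegenerative disease.
The assay this package models captures single specks on an
antibody-coated surface (single-molecule pull-down, SiMPull) and images
them twice: a short diffraction-limited acquisition from which specks
are *counted* per field of view (FOV), and a long dSTORM acquisition
(thousands of frames of stochastically blinking fluorophores) from
which each speck's *morphology* is reconstructed at ~30 nm resolution.

`speckpull` implements the downstream quantification: spot counting
with assay controls, localization-table processing through to
per-aggregate morphometrics, two-group distribution statistics with a
threshold search for a "morphologically distinctive" phenotype,
cohort-level biomarker statistics including an enumerative
composite-marker search, and denaturation-curve fitting.  Because the
study's patient data are not publicly deposited, the package ships a
synthetic-data generator that emulates every input the pipeline
consumes; all tests and worked examples run on it.

## Diffraction-limited counting

The counting stage averages the 50-frame stack (pooling photon
statistics; the spot signal-to-noise ratio grows roughly as the square
root of the frame count), estimates the background with a large-radius
median filter, and thresholds the residual at `k_sigma` (default 5)
robust standard deviations, where the noise scale is the median
absolute deviation times 1.4826 — insensitive to the bright spots
themselves.  Pixels above threshold are grouped into 8-connected
("path-connected") components and components outside the
`[min_area_px, max_area_px]` band (defaults 2–200 px) are discarded.
Because the threshold is relative to the noise scale, counting is
invariant to positive intensity rescaling.  Spots touching the border
are kept: counts, not shapes, are the endpoint here.

Per-sample summaries average 12 FOVs by protocol (fewer FOVs are
flagged, not refused).  Control wells (buffer-only, no-capture,
non-target detection IgG) are *compared*, never subtracted: a sample
passes when its mean exceeds every control mean by a configurable
factor (default 3).

## From localizations to morphology

dSTORM processing takes ThunderSTORM-style localization tables
(nm coordinates, origin at the top-left FOV corner, x right, y down)
as its input boundary — no raw-movie fitting.  The chain is:

1. **Drift correction** by redundant block cross-correlation: the
   acquisition is split into frame blocks (default 1000 frames), each
   block is rendered and registered to the first by the integer
   cross-correlation peak, and per-localization shifts are interpolated
   linearly in frame.  Integer-peak registration was chosen over
   sub-pixel refinement deliberately: with zero drift it returns an
   exact identity (sub-pixel refinement of sparse blink histograms
   introduces a few nm of noise), and one-render-pixel accuracy is all
   the segmentation needs.  Blocks with fewer than 100 localizations
   make registration unreliable; the function warns and returns the
   identity.
2. **Histogram rendering** at a 15 nm pixel — about half the 30 nm
   resolution limit; the pixel sum always equals the localization
   count.
3. **Segmentation**: binarize at ≥ 1 localization, label 8-connected
   components, and drop components carrying fewer than
   `min_localizations` (default 5) localizations.  Localizations are
   conserved: kept plus discarded equals the table size.
4. **Morphometrics** per component: area $A$ (pixel count × pixel
   area), perimeter $P$ by the 4-direction Crofton approximation
   (plain pixel-edge counting overestimates perimeters and deflates
   circularity), circularity $C = 4\pi A/P^2$ clipped at 1 (discrete
   perimeters can undershoot), and the equivalent circular diameters
   $d_A = 2\sqrt{A/\pi}$ and $d_P = P/\pi$.  On the printed areas these
   conversions give the familiar pairings, e.g. 0.001 µm² → 0.035 µm
   and 0.108 µm² → 0.37 µm.  Stored values keep full precision;
   truncation or rounding is applied only when reporting.
5. **Resolution filtering**: species with $d_A$ below 0.03 µm all look
   alike at the resolution limit and are excluded, so the analysis
   quantifies genuine aggregates rather than unresolved monomers.

Area is the binary-mask pixel area, not a localization-count-weighted
area; the choice is flagged here because the published analysis does
not state it.  Centroids *are* count-weighted.

`frame_sufficiency()` re-runs the chain on growing frame prefixes
(2, 5, 8, 11, 14, 16 thousand frames by default) and reports the
interquartile ranges of the area and circularity distributions plus
per-block localization counts (a photobleaching check — with stable
blinking the blocks are Poisson-equal).  Morphology saturates when the
fluorophore support of each aggregate is fully sampled; at the assay's
acquisition length that happens around 8000 frames.

## Two-group distribution statistics

Group differences in size and shape are read off ECDF difference
curves $\Delta F = F_1 - F_2$ on the pooled grid, against the
two-sample Kolmogorov–Smirnov band
$c(\alpha)\sqrt{(n+m)/(nm)}$ with $c(\alpha) = \sqrt{-\ln(\alpha/2)/2}$,
i.e. $c = 1.628$ at 99% confidence.  `ks_two_sample()` reports
$D = \sup|\Delta F|$ with the asymptotic Kolmogorov p-value.

`threshold_search()` scans a grid of combined thresholds
(area ≤ a, circularity ≥ c): at each cell the per-subject fractions of
such "small and round" aggregates are computed and the groups compared
with an exact permutation test on the difference of mean fractions.
Subjects, not pooled aggregates, are the unit of the test — matching a
study design where each point is one participant — while pooled
cumulative curves remain available for display.  Among cells with
p below 0.05 the cell maximizing $|\Delta f|$ is returned, ties broken
by smaller p, then smaller area threshold.  The default grid spans the
pooled 5th–95th area percentiles in 40 log-spaced steps and
circularity in 0.05 steps.

Two caveats are intrinsic to this procedure and are surfaced in the
output rather than silently corrected.  First, it is a maximizing scan
with **no multiple-testing correction**; with more than a handful of
subjects per group the chance that *some* cell passes the 0.05 gate
under the null is substantial, so a significant scan result should be
confirmed on held-out data or by bootstrapping the whole scan.  (With
3 subjects per group the smallest attainable exact p is 0.1 and the
gate can never open — the floor of the exact test is respected.)
Second, the selected cell is well localized only where the grid's
fraction surface has structure; on plateaus the area tie-break pulls
the selection to the smallest equivalent threshold.

## Cohort biomarker statistics

The AUC is computed rank-based (Mann–Whitney; ties count one half),
which is exact under ties and equals the trapezoidal integral of the
ROC curve.  Scores are oriented with disease as the positive class and
are *not* flipped when the AUC falls below one half.  Group
comparisons use the exact permutation test on the difference of means
(full enumeration up to $\binom{n+m}{n} \le 184756$, Monte-Carlo with
a recorded seed beyond), group sizes the exact binomial test, and
associations Pearson or Spearman correlation.  Fold changes are
reported on group means (primary) and medians (because cohort data are
displayed as box plots).

Composite biomarkers combine markers through the grammar
$m$, $m_1 + m_2$, $m_1/m_3$, $(m_1+m_2)/m_3$; for $k$ markers that is
$k + \binom{k}{2} + k(k-1) + \binom{k}{2}(k-2)$ expressions.
`composite_search()` scores every expression per subject, ranks by AUC
with a deterministic lexicographic tie-break, and accepts
morphology-derived quantities (e.g. the morphologically distinct
fraction) as ordinary markers.  Denominator markers can be normalized
by their within-group maximum; note this uses the subject's own
diagnostic label and therefore leaks label information into the score
— it is provided because it is part of the assay's analysis
convention, and flagged in the documentation.  Ratios also cancel
per-subject loading nuisance, which is why a ratio can outperform its
numerator alone; the generator exposes this mechanism through
`subject_effect_cv`.  Expressions whose denominator is zero for some
subject (possible with count data) are dropped from the ranking rather
than aborting the search.

Power for the planning design uses the noncentral t distribution:
at Cohen's d = 2 and 10 subjects per group the two-sided test at
$\alpha = 0.05$ has 99% power.  Assay precision is summarized as
intra- and inter-assay coefficients of variation with the conventional
20% acceptability bound.

## Stability analysis

Chaotropic denaturation leaves monomers intact but dismantles
aggregates, so aggregate counts fall exponentially with denaturant
concentration: $N(c) = N_0 e^{-c/c_e}$, and at $c = c_e$ the fitted
curve is $N_0/e \approx 0.4$ of the untreated count.  The fit is
log-linear least squares — robust at small counts — with zero counts
replaced by 0.5 before logging (a standard continuity correction,
flagged in the result).  Counts that do not decay are flagged instead
of producing a negative $c_e$.  Immunodepletion specificity is the
complementary check: `depletion_fraction()` reports the fraction of
counts removed.

## What the synthetic generator does and does not emulate

The generator produces every input the pipeline consumes, with
defaults set to the assay's stated conditions: 103.5 nm camera pixel,
512×512 px FOV, 8000 frames at 30 ms, a mean of 58 localizations per
aggregate, and lateral localization uncertainty drawn from a truncated
normal (mean 17 nm, SD 7 nm, floor 1 nm).

* **Blinking model.** Each aggregate carries a fixed number of
  fluorophores placed uniformly over an ellipse; each fluorophore
  emits a Poisson number of blinks spread uniformly over the frames.
  With the fluorophore count fixed, total localizations per aggregate
  are exactly Poisson — no photophysics state machine, which is
  sufficient for the count and morphology statistics downstream.
  Intra-speck labeling density and blink rates are parameters, not
  asserted values, because the assay reports only the mean of 58.
* **Morphology mixture.** Aggregates come from a two-component
  mixture: "small round" (equivalent diameter 35–150 nm, circularity
  0.7–1) and "large irregular" (150–1000 nm, circularity 0.2–0.7).
  The small-round weight is the group-effect knob; the disease group's
  default excess is 0.08.  Ellipse semi-axes are solved from the
  sampled (diameter, circularity) pair via the Ramanujan perimeter
  approximation.
* **Cohorts.** Marker counts are negative-binomial (overdispersed
  counts are the realistic regime for per-FOV aggregate counts) with
  control means of 40 (ASC), 100 (amyloid-beta), 20 (p-tau) and
  25 (alpha-synuclein), dispersion 10, and disease fold changes of
  4.2, 1.0, 2.5 and 2.0 — the ASC fold matching the top of the
  reported 1.5–4.2 range, and amyloid-beta flat, which is what makes
  it usable as a normalizing denominator.  An optional shared
  lognormal per-subject factor (`subject_effect_cv`, default 0)
  emulates loading/concentration nuisance.
* **Not emulated:** 3D/astigmatic localization, spectral channels,
  camera EM-gain statistics, fluorophore dark-state kinetics, spatial
  correlation between markers within a subject, and any cohort
  covariates (age, sex).  Passing tests therefore certify the
  *analysis chain*, not robustness to those real-data effects.

## Validation conditions and problem sizes

Two validation experiments intentionally depart from the noise
defaults, for stated reasons:

* **Disk recovery.**  The render→segment→diameter chain is validated
  on simulated disks of 50–500 nm with localization precision set to
  5 nm (below the render pixel) and fluorophore spacing ~11 nm.  The
  measured support of a localization cloud is the true object dilated
  by the localization precision; at the default 17 nm uncertainty this
  adds ~2σ ≈ 30 nm to measured diameters — a physical property of the
  imaging, not a segmentation defect, and one reason the resolution
  cut sits at 30 nm.  Sub-pixel precision isolates the geometry the
  chain is responsible for; recovery is then within
  max(2 render pixels, 10%) across the range.
* **Frame-sufficiency saturation.**  Saturation requires that the
  fluorophore support is fully sampled well before the acquisition
  ends; the test therefore uses labeling density matched to a 5 nm
  precision.  At sparser labeling or larger uncertainty the ≥ 1-count
  binary mask keeps growing slowly (fresh noise keeps adding boundary
  pixels), and the area IQR drifts by ~10–15% between 8k and 14k
  frames — worth knowing when interpreting real saturation checks.

Test and acceptance runs use scaled-down problem sizes chosen to keep
estimates comfortably inside their tolerance bands: 100–200 aggregates
for Poisson checks, cohorts of 8–20 subjects per group, 10 000
aggregates per subject for threshold-boundary localization (the
boundary between the mixture components is only identifiable to one
grid step when per-subject fraction noise is below the cell-to-cell
structure), 100-seed null calibrations, and 10⁵-replicate Monte-Carlo
oracles for power.

## Worked example

```{r example, eval = FALSE}
library(speckpull)

coh <- simulate_cohort(cohort_spec(n_control = 10, n_disease = 10,
                                   include_morphology = TRUE,
                                   n_aggregates_per_subject = 2000,
                                   seed = 42))
thr <- threshold_search(coh$morphology, seed = 1)
glance(thr)

asc <- subset(coh$counts, marker == "ASC")
auc(asc$value, asc$group)
composite_search(coh$counts, normalize_denominator = "Abeta") |> head(5)

fit <- fit_denaturation(simulate_denaturation(100, 0.5, noise_cv = 0.05,
                                              seed = 7))
tidy(fit)
autoplot(fit)
```

## Known limitations

* The binary ≥ 1-localization mask makes measured areas grow slowly
  with acquisition length at high blink counts; a density-threshold
  binarization would saturate harder but introduces a tuning parameter
  the analysis convention does not define.
* The threshold scan's significance gate is per-cell; see the
  multiplicity caveat above.
* Group-max normalization is reproduced as specified, including its
  label leakage; with heavy-tailed between-subject scale variation the
  group maximum is volatile and normalized scores can be unstable.
* The drift model is rigid translation per block; rotation and
  non-linear field distortions are out of scope.
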