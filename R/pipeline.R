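#' Pipeline configuration
#'
#' One object holding every tunable of the end-to-end pipeline, with
#' defaults matching the assay conditions: 103.5 nm camera pixel, 8000
#' dSTORM frames, 15 nm render pixel, 30 nm resolution cut, 99% KS
#' confidence, p < 0.05 significance gate.  The configuration
#' round-trips losslessly through YAML ([write_config()] /
#' [read_config()]); all randomness flows from the single `seed`.
#'
#' @param acquisition list of [acquisition_settings()] arguments.
#' @param detection list of [spot_params()] arguments.
#' @param segmentation render pixel (nm), per-aggregate localization
#'   floor, and resolution cut (um).
#' @param statistics KS band confidence, significance gate, threshold
#'   grid geometry and permutation budget.
#' @param simulation synthetic study conditions: cohort sizes, marker
#'   panel (parallel vectors), morphology effect, and the demonstration
#'   counting/morphology FOV sizes.
#' @param inputs optional named list of input file paths (localization
#'   CSV, TIFF stack, cohort CSV); all must exist.
#' @param seed master RNG seed.
#' @param output_dir where [run_pipeline()] writes its report bundle.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(acquisition = list(),
                            detection = list(),
                            segmentation = list(render_pixel_nm = 15,
                                                min_localizations = 5,
                                                min_diameter_um = 0.03),
                            statistics = list(ks_confidence = 0.99,
                                              alpha = 0.05,
                                              area_grid_steps = 40,
                                              circ_step = 0.05,
                                              max_exact = 184756,
                                              n_perm = 10000),
                            simulation = list(n_control = 20,
                                              n_disease = 20,
                                              marker = c("ASC", "Abeta",
                                                         "ptau", "asyn"),
                                              marker_mean = c(40, 100, 20, 25),
                                              marker_dispersion = c(10, 10,
                                                                    10, 10),
                                              marker_fold = c(4.2, 1, 2.5, 2),
                                              n_aggregates_per_subject = 300,
                                              small_round_frac_control = 0.3,
                                              small_round_excess = 0.08,
                                              subject_effect_cv = 0,
                                              counting_fov_px = 128,
                                              counting_n_spots = 25,
                                              counting_n_fov = 3,
                                              counting_brightness = 300,
                                              counting_background = 10,
                                              morph_fov_px = 64,
                                              morph_n_aggregates = 40),
                            inputs = NULL,
                            seed = 1L,
                            output_dir = tempfile("speckpull_run_")) {
  acq <- do.call(acquisition_settings, acquisition)
  det <- do.call(spot_params, detection)
  base <- pipeline_defaults()
  cfg <- list(
    acquisition = unclass(acq),
    detection = unclass(det),
    segmentation = utils::modifyList(base$segmentation, segmentation),
    statistics = utils::modifyList(base$statistics, statistics),
    simulation = utils::modifyList(base$simulation, simulation),
    inputs = inputs,
    seed = as.integer(seed),
    output_dir = output_dir
  )
  structure(cfg, class = "pipeline_config")
}

pipeline_defaults <- function() {
  list(
    segmentation = list(render_pixel_nm = 15, min_localizations = 5,
                        min_diameter_um = 0.03),
    statistics = list(ks_confidence = 0.99, alpha = 0.05,
                      area_grid_steps = 40, circ_step = 0.05,
                      max_exact = 184756, n_perm = 10000),
    simulation = list(n_control = 20, n_disease = 20,
                      marker = c("ASC", "Abeta", "ptau", "asyn"),
                      marker_mean = c(40, 100, 20, 25),
                      marker_dispersion = c(10, 10, 10, 10),
                      marker_fold = c(4.2, 1, 2.5, 2),
                      n_aggregates_per_subject = 300,
                      small_round_frac_control = 0.3,
                      small_round_excess = 0.08,
                      subject_effect_cv = 0,
                      counting_fov_px = 128, counting_n_spots = 25,
                      counting_n_fov = 3, counting_brightness = 300,
                      counting_background = 10,
                      morph_fov_px = 64, morph_n_aggregates = 40)
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("speckpull pipeline configuration\n")
  cat(sprintf("  seed: %d, output: %s\n", x$seed, x$output_dir))
  cat(sprintf("  camera pixel %.1f nm, %d frames, render pixel %.1f nm\n",
              x$acquisition$camera_pixel_nm, x$acquisition$n_frames,
              x$segmentation$render_pixel_nm))
  cat(sprintf("  KS confidence %.2f, alpha %.2f\n",
              x$statistics$ks_confidence, x$statistics$alpha))
  invisible(x)
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns the `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- yaml::read_yaml(path)
  pipeline_config(
    acquisition = raw$acquisition[
      setdiff(names(raw$acquisition), character())],
    detection = raw$detection,
    segmentation = raw$segmentation,
    statistics = raw$statistics,
    simulation = raw$simulation,
    inputs = raw$inputs,
    seed = raw$seed,
    output_dir = raw$output_dir
  )
}

# defaults that mirror assay constants, emitted with every report so a
# run is self-describing
provenance_table <- function(config) {
  tibble::tibble(
    parameter = c("camera_pixel_nm", "n_frames", "exposure_ms",
                  "render_pixel_nm", "min_diameter_um", "ks_confidence",
                  "alpha", "mean_localizations_per_aggregate"),
    value = c(config$acquisition$camera_pixel_nm,
              config$acquisition$n_frames,
              config$acquisition$exposure_ms,
              config$segmentation$render_pixel_nm,
              config$segmentation$min_diameter_um,
              config$statistics$ks_confidence,
              config$statistics$alpha, 58),
    units = c("nm", "frames", "ms", "nm", "um", "probability",
              "probability", "count"),
    meaning = c("camera pixel size",
                "dSTORM frames per acquisition",
                "camera exposure per frame",
                "super-resolution reconstruction pixel",
                "spatial resolution cut on equivalent diameter",
                "KS confidence band level for ECDF differences",
                "significance gate for group comparisons",
                "expected localizations per aggregate")
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Chains the full assay workflow on configured inputs: spot counting
#' with control-well assessment, super-resolution morphology
#' (localizations -> render -> segment -> resolution filter),
#' distribution statistics (ECDF differences, combined threshold
#' search), and cohort biomarker statistics (fold changes, AUCs,
#' composite search including the morphologically distinct fraction).
#' Without configured input files the stages run on data simulated from
#' the configuration's study conditions.  One JSON report plus
#' per-stage CSVs are written to `output_dir`; identical configuration
#' and seed give byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return The report (a nested list), invisibly; side effect: the
#'   report bundle in `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$inputs)) {
    missing <- config$inputs[!vapply(unlist(config$inputs), file.exists,
                                     logical(1))]
    if (length(missing)) {
      abort(sprintf("Input path(s) do not exist: %s.",
                    paste(unlist(missing), collapse = ", ")))
    }
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$output_dir, "config.yaml")
  write_config(config, cfg_path)
  # parameter hash over the scientific configuration only (not the
  # output location), so identical runs report identical hashes
  hash_path <- tempfile(fileext = ".yaml")
  hashable <- unclass(config)
  hashable$output_dir <- NULL
  yaml::write_yaml(hashable, hash_path, precision = 15)
  config_md5 <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  message(sprintf("speckpull %s | seed %d | config %s",
                  as.character(utils::packageVersion("speckpull")),
                  config$seed, config_md5))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  sim <- config$simulation
  seg <- config$segmentation
  sts <- config$statistics
  out <- config$output_dir

  ## stage 1: diffraction-limited counting -------------------------------
  counting <- run_stage("count", {
    cset <- acquisition_settings(
      camera_pixel_nm = config$acquisition$camera_pixel_nm,
      fov_px = sim$counting_fov_px, n_frames = 50,
      exposure_ms = config$acquisition$exposure_ms,
      render_pixel_nm = seg$render_pixel_nm)
    fovs <- purrr::map(seq_len(sim$counting_n_fov), function(i) {
      spots <- with_seed(config$seed + i, tibble::tibble(
        x_px = runif(sim$counting_n_spots, 5, sim$counting_fov_px - 5),
        y_px = runif(sim$counting_n_spots, 5, sim$counting_fov_px - 5),
        brightness = sim$counting_brightness))
      stk <- simulate_tirf_stack(spots, cset, background_mean =
                                   sim$counting_background,
                                 seed = config$seed + 100 + i)
      detect_spots(average_stack(stk),
                   do.call(spot_params, config$detection), fov = i)
    })
    # control wells: background-only stacks
    ctrl <- purrr::map_dbl(c(buffer = 201, no_capture = 202), function(s) {
      stk <- simulate_tirf_stack(
        tibble::tibble(x_px = numeric(), y_px = numeric(),
                       brightness = numeric()),
        cset, background_mean = sim$counting_background,
        seed = config$seed + s)
      detect_spots(average_stack(stk),
                   do.call(spot_params, config$detection))$count
    })
    summary <- summarize_sample(fovs)
    assessment <- control_assessment(summary$mean_count, pmax(ctrl, 0.5))
    counts_tbl <- tibble::tibble(
      fov = vapply(fovs, function(f) as.integer(f$fov), integer(1)),
      count = vapply(fovs, function(f) f$count, integer(1)))
    readr::write_csv(counts_tbl, file.path(out, "fov_counts.csv"),
                     progress = FALSE)
    list(per_fov = counts_tbl, summary = summary,
         controls = assessment,
         controls_pass = isTRUE(attr(assessment, "overall_pass")))
  })

  ## stage 2: super-resolution morphology --------------------------------
  morphology <- run_stage("morph", {
    mset <- acquisition_settings(
      camera_pixel_nm = config$acquisition$camera_pixel_nm,
      fov_px = sim$morph_fov_px,
      n_frames = config$acquisition$n_frames,
      exposure_ms = config$acquisition$exposure_ms,
      render_pixel_nm = seg$render_pixel_nm)
    truths <- truth_aggregates(sim$morph_n_aggregates, mset,
                               frac_small_round =
                                 sim$small_round_frac_control,
                               seed = config$seed + 300)
    locs <- simulate_localizations(truths, mset, seed = config$seed + 301)
    write_localizations(locs, file.path(out, "localizations.csv"))
    img <- render_localizations(locs, seg$render_pixel_nm, settings = mset)
    agg <- segment_aggregates(img, seg$min_localizations)
    agg <- filter_by_resolution(agg, seg$min_diameter_um)
    readr::write_csv(agg, file.path(out, "aggregates.csv"), progress = FALSE)
    list(n_localizations = nrow(locs),
         n_aggregates = nrow(agg),
         excluded_fraction = attr(agg, "excluded_fraction"),
         median_d_area_um = median(agg$d_area_um),
         median_circularity = median(agg$circularity),
         aggregates = agg)
  })

  ## stage 3: cohort + distribution statistics ---------------------------
  spec <- cohort_spec(
    n_control = sim$n_control, n_disease = sim$n_disease,
    markers = tibble::tibble(marker = sim$marker, mean = sim$marker_mean,
                             dispersion = sim$marker_dispersion,
                             fold = sim$marker_fold),
    include_morphology = TRUE,
    n_aggregates_per_subject = sim$n_aggregates_per_subject,
    small_round_frac_control = sim$small_round_frac_control,
    small_round_excess = sim$small_round_excess,
    subject_effect_cv = sim$subject_effect_cv,
    seed = config$seed + 400)
  cohort <- run_stage("cohort", simulate_cohort(spec))
  write_cohort(cohort$counts, file.path(out, "cohort.csv"))
  readr::write_csv(cohort$morphology, file.path(out, "morphology.csv"),
                   progress = FALSE)

  stats_out <- run_stage("stats", {
    ctrl_area <- cohort$morphology$area_um2[cohort$morphology$group ==
                                              "control"]
    dis_area <- cohort$morphology$area_um2[cohort$morphology$group ==
                                             "disease"]
    ctrl_circ <- cohort$morphology$circularity[cohort$morphology$group ==
                                                 "control"]
    dis_circ <- cohort$morphology$circularity[cohort$morphology$group ==
                                                "disease"]
    d_area <- ecdf_difference(dis_area, ctrl_area, sts$ks_confidence)
    d_circ <- ecdf_difference(dis_circ, ctrl_circ, sts$ks_confidence)
    thr <- threshold_search(
      cohort$morphology,
      circ_grid = seq(0, 1, by = sts$circ_step),
      alpha = sts$alpha, max_exact = sts$max_exact,
      n_perm = sts$n_perm, seed = config$seed + 500)
    readr::write_csv(thr$fractions, file.path(out, "fractions.csv"),
                     progress = FALSE)
    list(size_D = d_area$D, size_band = d_area$band,
         size_exceeds_band = d_area$D > d_area$band,
         shape_D = d_circ$D, shape_band = d_circ$band,
         shape_exceeds_band = d_circ$D > d_circ$band,
         threshold = list(area_max_um2 = thr$area_max,
                          circ_min = thr$circ_min,
                          delta_fraction = thr$delta_f,
                          p_value = thr$p_value,
                          significant = thr$significant),
         threshold_obj = thr)
  })

  biomarker_out <- run_stage("biomarker", {
    counts <- cohort$counts
    folds <- counts |>
      dplyr::group_by(.data$marker) |>
      dplyr::summarise(
        fold_mean = mean(.data$value[.data$group == "disease"]) /
          mean(.data$value[.data$group == "control"]),
        auc = auc(.data$value, .data$group),
        p_value = permutation_exact_test(
          .data$value[.data$group == "disease"],
          .data$value[.data$group == "control"],
          max_exact = sts$max_exact, n_perm = sts$n_perm,
          seed = config$seed + 600)$p_value,
        .groups = "drop")
    # morphologically distinct fraction joins the panel as a marker
    mdf <- stats_out$threshold_obj$fractions |>
      dplyr::transmute(.data$subject, .data$group, marker = "ASC_mdf",
                       value = .data$fraction)
    panel <- dplyr::bind_rows(counts, mdf)
    ranked <- composite_search(panel, normalize_denominator = "Abeta")
    readr::write_csv(ranked, file.path(out, "composites.csv"),
                     progress = FALSE)
    list(markers = folds, top_composites = head(ranked, 10))
  })

  report <- list(
    package = "speckpull",
    version = as.character(utils::packageVersion("speckpull")),
    seed = config$seed,
    config_md5 = config_md5,
    provenance = provenance_table(config),
    counting = counting[c("per_fov", "summary", "controls",
                          "controls_pass")],
    morphology = morphology[c("n_localizations", "n_aggregates",
                              "excluded_fraction", "median_d_area_um",
                              "median_circularity")],
    statistics = stats_out[c("size_D", "size_band", "size_exceeds_band",
                             "shape_D", "shape_band", "shape_exceeds_band",
                             "threshold")],
    biomarker = biomarker_out
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
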