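# File formats: localization CSV (ThunderSTORM dialect), long cohort
# CSV, denaturation CSV, multi-page 16-bit TIFF stacks, YAML configs.

ts_dialect <- c(
  id = "id", frame = "frame", x_nm = "x [nm]", y_nm = "y [nm]",
  photons = "intensity [photon]", uncertainty_nm = "uncertainty [nm]"
)

#' Read a localization table (ThunderSTORM CSV dialect)
#'
#' Columns are matched by header name, so reordered files parse
#' correctly; unknown extra columns are preserved.  A missing required
#' column is an error naming it.
#'
#' @param path CSV file with header
#'   `id,frame,"x [nm]","y [nm]","intensity [photon]","uncertainty [nm]"`.
#' @return Localization tibble with columns `id`, `frame`, `x_nm`,
#'   `y_nm`, `photons`, `uncertainty_nm` (+ any extras).
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(unname(ts_dialect), names(raw))
  if (length(miss)) {
    abort(sprintf("Malformed localization file: missing column(s) %s.",
                  paste(sprintf("`%s`", miss), collapse = ", ")))
  }
  out <- dplyr::rename(raw, !!!rlang::set_names(unname(ts_dialect),
                                                names(ts_dialect)))
  dplyr::relocate(out, dplyr::all_of(names(ts_dialect)))
}

#' Write a localization table (ThunderSTORM CSV dialect)
#'
#' @param locs localization tibble (`id`, `frame`, `x_nm`, `y_nm`,
#'   `photons`, `uncertainty_nm`, extra columns kept).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  miss <- setdiff(names(ts_dialect), names(locs))
  if (length(miss)) {
    abort(sprintf("Localization table lacks column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  out <- dplyr::relocate(locs, dplyr::all_of(names(ts_dialect)))
  out <- dplyr::rename(out, !!!rlang::set_names(names(ts_dialect),
                                                unname(ts_dialect)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a long-form cohort table
#'
#' CSV with columns `subject,group,marker,value`.
#'
#' @param path CSV path.
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("subject", "group", "marker", "value"), names(out))
  if (length(miss)) {
    abort(sprintf("Malformed cohort file: missing column(s) %s.",
                  paste(miss, collapse = ", ")))
  }
  out
}

#' @param cohort cohort tibble (`subject`, `group`, `marker`, `value`).
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Read / write a denaturation curve
#'
#' CSV with columns `conc_M,count_mean,count_se`.
#'
#' @param path CSV path.
#' @return Denaturation tibble.
#' @export
read_denaturation <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("conc_M", "count_mean"), names(out))
  if (length(miss)) {
    abort(sprintf("Malformed denaturation file: missing column(s) %s.",
                  paste(miss, collapse = ", ")))
  }
  out
}

#' @param curve denaturation tibble (`conc_M`, `count_mean`,
#'   optionally `count_se`).
#' @rdname read_denaturation
#' @export
write_denaturation <- function(curve, path) {
  readr::write_csv(curve, path, progress = FALSE)
  invisible(path)
}

#' Read / write a multi-page 16-bit TIFF image stack
#'
#' Pixel counts are stored as 16-bit unsigned integers (values above
#' 65535 are clipped on write).
#'
#' @param path TIFF path.
#' @return 3D array (`y` x `x` x `frame`) of integer counts.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- simplify2array(lapply(pages, function(p) round(p * 65535)))
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  arr
}

#' @param stack 3D array or list of matrices of pixel counts.
#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  if (inherits(stack, "tirf_sim")) stack <- stack$stack
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  }
  pages <- lapply(stack, function(m) pmin(m, 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
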