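#' Spectra container: absorbance matrix, wavenumber grid, sample metadata
#'
#' The carrier object between all pipeline stages. Rows of `absorbance` are
#' samples (in the order of `meta`), columns are wavenumbers in descending
#' instrument order.
#'
#' @param absorbance Numeric matrix, samples x wavenumbers, no missing values.
#' @param grid A [wavenumber_grid()] whose length matches `ncol(absorbance)`,
#'   or a descending numeric vector of wavenumbers.
#' @param meta Data frame with columns `sample_id` (unique), `tissue`
#'   (`"BFL"` or `"FLP"`), `region_class` (integer 1..5) and optionally
#'   `set_membership` (`"unassigned"`, `"training"` or `"validation"`).
#' @return A `spectra_set` object.
#' @export
spectra_set <- function(absorbance, grid, meta) {
  absorbance <- as.matrix(absorbance)
  if (is.numeric(grid)) grid <- grid_from_points(grid)
  meta <- tibble::as_tibble(meta)
  if (!"set_membership" %in% names(meta)) meta$set_membership <- "unassigned"
  meta$region_class <- as.integer(meta$region_class)
  validate_spectra_set(absorbance, grid, meta)
  rownames(absorbance) <- meta$sample_id
  colnames(absorbance) <- format_wavenumber(grid$points)
  structure(list(absorbance = absorbance, grid = grid, meta = meta),
            class = "spectra_set")
}

format_wavenumber <- function(x) sprintf("%.2f", x)

validate_spectra_set <- function(absorbance, grid, meta) {
  if (ncol(absorbance) != length(grid$points)) {
    abort("Number of spectral variables must equal the grid length.",
          class = "nirselect_format_error")
  }
  if (nrow(absorbance) != nrow(meta)) {
    abort("Row count of `absorbance` must match `meta`.",
          class = "nirselect_metadata_error")
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    abort("Absorbance matrix contains missing or non-finite values.",
          class = "nirselect_data_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("`sample_id` must be unique within a spectra set.",
          class = "nirselect_metadata_error")
  }
  if (!all(meta$tissue %in% c("BFL", "FLP"))) {
    abort("`tissue` must be \"BFL\" or \"FLP\".", class = "nirselect_metadata_error")
  }
  if (!all(meta$region_class %in% 1:5)) {
    abort("`region_class` must be an integer in 1..5.",
          class = "nirselect_metadata_error")
  }
  invisible(TRUE)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavenumbers (%.2f to %.2f cm^-1)\n",
              nrow(x$absorbance), ncol(x$absorbance), x$grid$start, x$grid$end))
  cat("tissue:", paste(unique(x$meta$tissue), collapse = ", "),
      " classes:", paste(sort(unique(x$meta$region_class)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

# row subset keeping meta aligned (internal)
subset_samples <- function(s, i) {
  spectra_set(s$absorbance[i, , drop = FALSE], s$grid, s$meta[i, , drop = FALSE])
}

#' Read spectra and metadata from CSV
#'
#' The spectra file has a `sample_id` column followed by one column per
#' wavenumber (headers in cm^-1, descending); the metadata file is keyed by
#' `sample_id` with columns `tissue` and `region_class` (and optionally
#' `set_membership`).
#'
#' @param path Spectra CSV path.
#' @param meta_path Metadata CSV path.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path, meta_path) {
  spec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(spec)[1] != "sample_id") {
    abort("Spectra CSV must start with a `sample_id` column.",
          class = "nirselect_format_error")
  }
  wn <- suppressWarnings(as.numeric(names(spec)[-1]))
  if (anyNA(wn)) {
    abort("Spectra CSV header must be numeric wavenumbers.",
          class = "nirselect_format_error")
  }
  grid <- grid_from_points(wn)
  X <- as.matrix(spec[, -1])
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE)
  if (!all(spec$sample_id %in% meta$sample_id) ||
      !all(meta$sample_id %in% spec$sample_id)) {
    abort("Sample ids in spectra and metadata files do not match.",
          class = "nirselect_metadata_error")
  }
  meta <- meta[match(spec$sample_id, meta$sample_id), ]
  spectra_set(X, grid, meta)
}

#' Write spectra and metadata to CSV
#'
#' Inverse of [read_spectra_csv()]; wavenumber headers keep two decimals.
#'
#' @param s A [spectra_set()].
#' @param path Spectra CSV path.
#' @param meta_path Metadata CSV path.
#' @return `s`, invisibly.
#' @export
write_spectra_csv <- function(s, path, meta_path) {
  df <- tibble::as_tibble(s$absorbance, .name_repair = "minimal")
  # headers carry 6 decimals so the grid re-reads as uniform to 1e-6
  names(df) <- sprintf("%.6f", s$grid$points)
  df <- dplyr::bind_cols(tibble::tibble(sample_id = s$meta$sample_id), df)
  readr::write_csv(df, path, progress = FALSE)
  readr::write_csv(s$meta, meta_path, progress = FALSE)
  invisible(s)
}

#' Crop a spectra set to a wavenumber band
#'
#' Keeps exactly the grid points `low <= p <= high` (to the grid tolerance).
#' Spacing is unchanged, so cropping is idempotent and commutes with sample
#' subsetting.
#'
#' @param s A [spectra_set()].
#' @param high,low Band edges in cm^-1 (`low < high`).
#' @return A cropped [spectra_set()].
#' @examples
#' # the preliminary selected band of the study grid holds 886 variables
#' g <- instrument_grid()
#' @export
band_crop <- function(s, high, low) {
  if (low >= high) abort("`low` must be below `high`.", class = "nirselect_range_error")
  keep <- s$grid$points <= high + GRID_TOL & s$grid$points >= low - GRID_TOL
  if (!any(keep)) {
    abort("Crop window does not intersect the wavenumber grid.",
          class = "nirselect_range_error")
  }
  grid <- new_wavenumber_grid(s$grid$points[keep], s$grid$spacing)
  spectra_set(s$absorbance[, keep, drop = FALSE], grid, s$meta)
}

#' @export
tidy.spectra_set <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$meta$sample_id, times = ncol(x$absorbance)),
    tissue = rep(x$meta$tissue, times = ncol(x$absorbance)),
    region_class = rep(x$meta$region_class, times = ncol(x$absorbance)),
    wavenumber = rep(x$grid$points, each = nrow(x$absorbance)),
    absorbance = as.vector(x$absorbance))
}

#' @export
glance.spectra_set <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$absorbance), n_variables = ncol(x$absorbance),
    wn_high = x$grid$start, wn_low = x$grid$end, spacing = x$grid$spacing,
    n_classes = length(unique(x$meta$region_class)))
}
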