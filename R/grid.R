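#' Uniform wavenumber grid
#'
#' NIR spectrometers report absorbance on a uniform wavenumber grid, stored
#' here in instrument convention: descending from the high-wavenumber end of
#' the scan. All indexing elsewhere in the package is by wavenumber value, not
#' column position, so cropped spectra stay addressable.
#'
#' @param start Highest wavenumber (cm^-1).
#' @param end Lowest wavenumber (cm^-1); `end < start`.
#' @param spacing Grid spacing (cm^-1), positive.
#' @return A `wavenumber_grid`: list with `start`, `end`, `spacing` and the
#'   descending `points` vector.
#' @examples
#' g <- wavenumber_grid(5000, 4000, 4)
#' length(g$points)
#' @export
wavenumber_grid <- function(start, end, spacing) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(spacing))
  if (spacing <= 0) abort("`spacing` must be positive.", class = "nirselect_grid_error")
  if (end >= start) abort("`end` must be below `start`.", class = "nirselect_grid_error")
  n <- round((start - end) / spacing) + 1
  points <- start - spacing * (seq_len(n) - 1)
  new_wavenumber_grid(points, spacing)
}

new_wavenumber_grid <- function(points, spacing) {
  structure(
    list(start = points[1], end = points[length(points)],
         spacing = spacing, points = points),
    class = "wavenumber_grid")
}

# Grid uniformity tolerance, cm^-1. Headers are printed with >= 2 decimals so
# anything larger than this indicates a malformed or hand-edited file.
GRID_TOL <- 1e-6

#' Build a grid from a vector of points, validating uniformity
#'
#' @param points Descending wavenumbers.
#' @return A `wavenumber_grid`.
#' @export
grid_from_points <- function(points) {
  if (length(points) < 2) {
    return(new_wavenumber_grid(points, spacing = NA_real_))
  }
  d <- -diff(points)
  spacing <- mean(d)
  if (any(d <= 0) || max(abs(d - spacing)) >= GRID_TOL) {
    abort("Wavenumber header is not a uniform descending grid.",
          class = "nirselect_format_error")
  }
  new_wavenumber_grid(points, spacing)
}

#' The emulated instrument grid
#'
#' A full-range 10000 to 4000 cm^-1 scan whose spacing is fixed by the
#' preliminary selected band: 886 points span 7501.74 down to 4088.35 cm^-1,
#' giving a spacing of (7501.74 - 4088.35)/885 = 3.8569 cm^-1 (3.857 to
#' printed precision). The grid is anchored so that both band edges are exact
#' grid members.
#'
#' @return A `wavenumber_grid` covering approximately 10000 to 4000 cm^-1.
#' @examples
#' g <- instrument_grid()
#' sum(g$points <= 7501.74 + 1e-6 & g$points >= 4088.35 - 1e-6) # 886
#' @export
instrument_grid <- function() {
  anchor <- 4088.35
  spacing <- (7501.74 - 4088.35) / 885
  k_hi <- floor((10000 - anchor) / spacing)
  k_lo <- ceiling((4000 - anchor) / spacing)
  points <- anchor + spacing * (k_hi:k_lo)
  new_wavenumber_grid(points, spacing)
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %d points, %.4f to %.4f cm^-1, spacing %.6f\n",
              length(x$points), x$start, x$end, x$spacing))
  invisible(x)
}
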