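#' Norris gap-segment filter
#'
#' Segment smoothing (boxcar mean over `segment` points, window shrinking at
#' the edges) optionally followed by a gap difference, the classic Norris
#' derivative used by instrument software. The default chain uses the
#' smoothing step only and leaves differentiation to the Savitzky-Golay second
#' derivative.
#'
#' @param s A [spectra_set()].
#' @param segment Odd segment length in points (>= 1).
#' @param gap Gap in points (>= 1); used only when `derivative = TRUE`.
#' @param derivative Apply the gap first-difference after smoothing.
#' @return A [spectra_set()] of the same shape.
#' @export
norris_filter <- function(s, segment = 5, gap = 5, derivative = FALSE) {
  p <- ncol(s$absorbance)
  if (segment < 1 || segment %% 2 == 0) {
    abort("`segment` must be a positive odd integer.",
          class = "nirselect_parameter_error")
  }
  if (gap < 1) abort("`gap` must be >= 1.", class = "nirselect_parameter_error")
  if (segment + gap > p) {
    abort("Norris window exceeds the number of spectral variables.",
          class = "nirselect_parameter_error")
  }
  half <- (segment - 1) / 2
  smooth_row <- function(x) {
    vapply(seq_along(x), function(i) {
      lo <- max(1, i - half); hi <- min(length(x), i + half)
      mean(x[lo:hi])
    }, numeric(1))
  }
  X <- t(apply(s$absorbance, 1, smooth_row))
  if (derivative) {
    X <- t(apply(X, 1, function(x) {
      n <- length(x)
      i <- seq_len(n)
      lo <- pmax(1, i - gap); hi <- pmin(n, i + gap)
      (x[hi] - x[lo]) / (hi - lo)
    }))
  }
  spectra_set(X, s$grid, s$meta)
}

#' Savitzky-Golay second derivative
#'
#' Second derivative with respect to the grid index, exact for polynomials up
#' to `polyorder`. Edge points use the asymmetric fits of the Savitzky-Golay
#' projection matrix.
#'
#' @param s A [spectra_set()].
#' @param window Odd window length (>= `polyorder + 1`).
#' @param polyorder Polynomial order (>= 2).
#' @return A [spectra_set()] of the same shape.
#' @export
second_derivative <- function(s, window = 11, polyorder = 2) {
  if (polyorder < 2) abort("`polyorder` must be >= 2 for a second derivative.",
                           class = "nirselect_parameter_error")
  if (window %% 2 == 0 || window < polyorder + 1) {
    abort("`window` must be odd and at least `polyorder + 1`.",
          class = "nirselect_parameter_error")
  }
  if (window > ncol(s$absorbance)) {
    abort("`window` exceeds the number of spectral variables.",
          class = "nirselect_parameter_error")
  }
  X <- t(apply(s$absorbance, 1, signal::sgolayfilt,
               p = polyorder, n = window, m = 2, ts = 1))
  spectra_set(X, s$grid, s$meta)
}

#' Mean-center each spectral variable
#'
#' @param s A [spectra_set()] with at least two samples.
#' @return A [spectra_set()] whose columns have mean zero.
#' @export
mean_center <- function(s) {
  if (nrow(s$absorbance) < 2) abort("Need at least 2 samples.",
                                    class = "nirselect_parameter_error")
  X <- scale(s$absorbance, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  spectra_set(X, s$grid, s$meta)
}

#' Autoscale each spectral variable to unit variance
#'
#' Centers, then divides by the per-variable standard deviation.
#' Zero-variance variables are left centered only, with a warning.
#'
#' @param s A [spectra_set()] with at least two samples.
#' @return A [spectra_set()] whose columns have mean 0 and sd 1.
#' @export
standardize <- function(s) {
  if (nrow(s$absorbance) < 2) abort("Need at least 2 samples.",
                                    class = "nirselect_parameter_error")
  X <- scale(s$absorbance, center = TRUE, scale = FALSE)
  sds <- apply(X, 2, sd)
  zero <- sds <= 0
  if (any(zero)) {
    warn(sprintf("%d zero-variance variable(s) left centered only.", sum(zero)))
    sds[zero] <- 1
  }
  X <- sweep(X, 2, sds, "/")
  attr(X, "scaled:center") <- NULL
  spectra_set(X, s$grid, s$meta)
}

#' Apply the study pretreatment chain
#'
#' Applies, in order, the steps of the pretreatment chain: Norris smoothing,
#' mean centering, autoscaling, Savitzky-Golay second derivative. Steps are
#' order-sensitive and the chain has no hidden state.
#'
#' @param s A [spectra_set()].
#' @param steps Character vector drawn from `"norris"`, `"mean_center"`,
#'   `"standardize"`, `"second_derivative"`, applied in the given order.
#' @param segment,gap Norris parameters.
#' @param window,polyorder Savitzky-Golay parameters.
#' @return A pretreated [spectra_set()].
#' @export
pretreat <- function(s, steps = c("norris", "mean_center", "standardize",
                                  "second_derivative"),
                     segment = 5, gap = 5, window = 11, polyorder = 2) {
  for (step in steps) {
    s <- switch(step,
      norris = norris_filter(s, segment = segment, gap = gap),
      mean_center = mean_center(s),
      standardize = standardize(s),
      second_derivative = second_derivative(s, window = window,
                                            polyorder = polyorder),
      abort(sprintf("Unknown pretreatment step '%s'.", step),
            class = "nirselect_parameter_error"))
  }
  s
}

#' Standard-deviation band selection
#'
#' Computes the per-variable standard deviation across samples and returns the
#' longest contiguous wavenumber run whose SD reaches the given quantile of
#' the SD distribution. High-SD regions carry the between-sample contrast that
#' classification feeds on; flat high-frequency regions are dropped.
#'
#' @param s A [spectra_set()].
#' @param quantile SD quantile threshold in (0, 1) (0 keeps the full grid).
#' @param min_run Minimum run length, points.
#' @return A list of class `sdd_window`: `high`, `low`, `n_points`, and an
#'   `sd` tibble (`wavenumber`, `sd`, `selected`).
#' @export
sdd_band_select <- function(s, quantile = 0.25, min_run = 50) {
  if (quantile < 0 || quantile >= 1) {
    abort("`quantile` must be in [0, 1).", class = "nirselect_parameter_error")
  }
  sds <- apply(s$absorbance, 2, sd)
  thr <- stats::quantile(sds, quantile, names = FALSE)
  mask <- sds >= thr
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- which(runs$values & runs$lengths >= min_run)
  if (length(ok) == 0) {
    abort("No contiguous run reaches `min_run`; try a lower `quantile`.",
          class = "nirselect_selection_error")
  }
  best <- ok[which.max(runs$lengths[ok])]
  idx <- starts[best]:ends[best]
  wn <- s$grid$points
  structure(list(high = wn[idx[1]], low = wn[idx[length(idx)]],
                 n_points = length(idx),
                 sd = tibble::tibble(wavenumber = wn, sd = sds,
                                     selected = seq_along(wn) %in% idx)),
            class = "sdd_window")
}

#' @export
print.sdd_window <- function(x, ...) {
  cat(sprintf("<sdd_window> %.2f to %.2f cm^-1 (%d points)\n",
              x$high, x$low, x$n_points))
  invisible(x)
}
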