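#' Describe one synthetic absorption band
#'
#' Gaussian band on the absorbance scale. A band is class-informative when its
#' per-class amplitudes differ; `shared = TRUE` marks class-invariant
#' background chemistry.
#'
#' @param center Band center, cm^-1.
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param amplitude Either a single amplitude (recycled over the 5 region
#'   classes) or a vector of 5 nonnegative per-class amplitudes.
#' @param shared Logical; class-invariant band.
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, width, amplitude, shared = FALSE) {
  if (width <= 0) abort("`width` must be positive.", class = "nirselect_config_error")
  amplitude <- rep_len(amplitude, 5)
  if (any(amplitude < 0)) abort("Amplitudes must be nonnegative.",
                                class = "nirselect_config_error")
  if (!shared && length(unique(amplitude)) < 2) {
    abort("A non-shared band must differ between at least one class pair.",
          class = "nirselect_config_error")
  }
  structure(list(center = center, width = width,
                 amplitude = amplitude, shared = shared),
            class = "band_spec")
}

#' Configuration for the synthetic spectra generator
#'
#' @param n_per_class Integer vector of 5 class sizes.
#' @param tissue `"BFL"` or `"FLP"`.
#' @param grid A [wavenumber_grid()].
#' @param bands List of [band_spec()] objects.
#' @param baseline_offset,baseline_slope,baseline_curvature Mean coefficients
#'   of the per-sample quadratic baseline (absorbance units over the scan).
#' @param baseline_jitter_sd Standard deviation of the per-sample i.i.d.
#'   perturbation of each baseline coefficient.
#' @param amplitude_jitter_sd Relative standard deviation of the per-sample,
#'   per-band amplitude perturbation (within-region concentration
#'   variability); amplitudes are truncated at zero.
#' @param noise_sd I.i.d. measurement noise, absorbance units.
#' @param outlier_count,outlier_scale Number of planted outliers and the
#'   factor applied to their baseline perturbation and noise.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class, tissue, grid, bands,
                             baseline_offset = 0.40, baseline_slope = 0.15,
                             baseline_curvature = 0.10,
                             baseline_jitter_sd = 0.02,
                             amplitude_jitter_sd = 0.05, noise_sd = 0.005,
                             outlier_count = 0L, outlier_scale = 10,
                             seed = 1L) {
  if (length(n_per_class) != 5 || any(n_per_class < 1)) {
    abort("`n_per_class` must give 5 classes with at least one sample each.",
          class = "nirselect_config_error")
  }
  rng <- range(grid$points)
  for (b in bands) {
    if (b$center < rng[1] - GRID_TOL || b$center > rng[2] + GRID_TOL) {
      abort(sprintf("Band center %.2f lies outside the grid range.", b$center),
            class = "nirselect_config_error")
    }
  }
  structure(list(n_per_class = as.integer(n_per_class), tissue = tissue,
                 grid = grid, bands = bands,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope,
                 baseline_curvature = baseline_curvature,
                 baseline_jitter_sd = baseline_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 noise_sd = noise_sd,
                 outlier_count = as.integer(outlier_count),
                 outlier_scale = outlier_scale, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Characteristic marker wavenumbers used as informative band centers; the two
# tissues carry disjoint sets so pooled spectra separate in a PCA score plot.
bfl_informative_centers <- c(4096.06, 4308.19, 4439.33, 4597.46, 5079.58, 5866.40)
flp_informative_centers <- c(4508.75, 4952.30, 5233.86, 5303.28, 5685.12, 5928.11)

# Per-class amplitude patterns for the six informative bands. Each band's
# concentration tracks the regional gradient (so it correlates with the class
# code), but the shapes differ - linear trends, plateaus and late drops -
# the way distinct constituents respond differently to geography. The
# diversity keeps the bands from being mutually redundant for prediction.
informative_amplitudes <- function() {
  list(c(0.10, 0.13, 0.16, 0.19, 0.22),   # linear increase
       c(0.24, 0.20, 0.16, 0.12, 0.08),   # linear decrease
       c(0.08, 0.08, 0.20, 0.22, 0.24),   # step up after class 2
       c(0.22, 0.20, 0.18, 0.06, 0.06),   # step down after class 3
       c(0.06, 0.16, 0.20, 0.22, 0.23),   # saturating increase
       c(0.24, 0.22, 0.20, 0.16, 0.04))   # late drop
}

shared_band_table <- function() {
  # class-invariant background chemistry: broad water/OH and C-H combination
  # envelopes plus sharper matrix features that survive derivative
  # pretreatment - the crowded, uninformative structure a full-spectrum
  # model has to contend with
  tibble::tibble(
    center = c(4255, 4760, 5155, 5800, 6850, 8300,
               4400, 5000, 5450, 6100),
    width = c(60, 90, 80, 70, 90, 150,
              12, 10, 14, 18),
    amplitude = c(0.30, 0.18, 0.35, 0.20, 0.28, 0.10,
                  0.20, 0.25, 0.18, 0.15))
}

#' Default synthetic study configuration for one tissue
#'
#' Emulates the study conditions: 60 samples split 19/12/5/10/14 over five
#' region classes, the full instrument grid, six informative bands planted at
#' tissue-specific marker wavenumbers plus ten shared background bands, and
#' 0.005 absorbance units of i.i.d. noise. The two tissues carry disjoint
#' informative centers and the peel (FLP) sits on a higher diffuse-reflectance
#' baseline than the inner part, so a PCA of pooled tissues separates them in
#' the leading score plane.
#'
#' @param tissue `"BFL"` or `"FLP"`.
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @examples
#' cfg <- default_study_config("BFL")
#' sum(cfg$n_per_class) # 60
#' @export
default_study_config <- function(tissue = c("BFL", "FLP"), seed = 1L) {
  tissue <- match.arg(tissue)
  centers <- if (tissue == "BFL") bfl_informative_centers else flp_informative_centers
  amps <- informative_amplitudes()
  informative <- purrr::map2(centers, amps,
                             function(ctr, a) band_spec(ctr, width = 7, amplitude = a))
  shared <- purrr::pmap(shared_band_table(),
                        function(center, width, amplitude)
                          band_spec(center, width, amplitude, shared = TRUE))
  synthetic_config(n_per_class = c(19L, 12L, 5L, 10L, 14L), tissue = tissue,
                   grid = instrument_grid(), bands = c(informative, shared),
                   baseline_offset = if (tissue == "FLP") 0.55 else 0.40,
                   seed = seed)
}

#' Generate a synthetic spectra set with known ground truth
#'
#' Absorbance is a per-sample random quadratic baseline, plus Gaussian bands
#' whose amplitudes depend on the region class (perturbed per sample by the
#' relative `amplitude_jitter_sd`, emulating within-region concentration
#' variability), plus i.i.d. noise. Planted outliers have their baseline
#' perturbation and noise inflated by `outlier_scale`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `nir_sim` with elements `spectra` (a
#'   [spectra_set()]), `informative` (tibble of non-shared band centers snapped
#'   to the grid) and `outlier_ids`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  classes <- rep(1:5, times = cfg$n_per_class)
  n <- length(classes)
  wn <- cfg$grid$points
  p <- length(wn)
  u <- (wn - min(wn)) / (max(wn) - min(wn))  # scan coordinate in [0, 1]

  ids <- sprintf("%s-%02d", cfg$tissue, seq_len(n))
  outlier_ids <- character(0)
  scale_vec <- rep(1, n)
  if (cfg$outlier_count > 0) {
    idx <- sort(sample.int(n, cfg$outlier_count))
    scale_vec[idx] <- cfg$outlier_scale
    outlier_ids <- ids[idx]
  }

  shapes <- vapply(cfg$bands,
                   function(b) exp(-(wn - b$center)^2 / (2 * b$width^2)),
                   numeric(p))  # p x n_bands
  amp_by_class <- vapply(cfg$bands, function(b) b$amplitude,
                         numeric(5))      # 5 x n_bands

  X <- matrix(0, n, p)
  for (i in seq_len(n)) {
    coef_dev <- rnorm(3, 0, cfg$baseline_jitter_sd) * scale_vec[i]
    base <- (cfg$baseline_offset + coef_dev[1]) +
      (cfg$baseline_slope + coef_dev[2]) * u +
      (cfg$baseline_curvature + coef_dev[3]) * u^2
    amps <- amp_by_class[classes[i], ] *
      pmax(0, 1 + rnorm(length(cfg$bands), 0, cfg$amplitude_jitter_sd))
    noise <- rnorm(p, 0, cfg$noise_sd) * scale_vec[i]
    X[i, ] <- base + drop(shapes %*% amps) + noise
  }

  meta <- tibble::tibble(sample_id = ids, tissue = cfg$tissue,
                         region_class = classes)
  informative <- purrr::keep(cfg$bands, ~ !.x$shared)
  truth <- tibble::tibble(
    center = purrr::map_dbl(informative, "center"),
    width = purrr::map_dbl(informative, "width"))
  truth$grid_wavenumber <- purrr::map_dbl(truth$center,
                                          ~ wn[which.min(abs(wn - .x))])
  structure(list(spectra = spectra_set(X, cfg$grid, meta),
                 informative = truth, outlier_ids = outlier_ids,
                 config = cfg),
            class = "nir_sim")
}

#' Hit rate of a selection against the planted informative bands
#'
#' A planted band is "hit" when some selected wavenumber lies within
#' `tol_steps` grid steps of its center.
#'
#' @param selected Numeric vector of selected wavenumbers.
#' @param sim A `nir_sim` from [generate_dataset()] (or a numeric vector of
#'   true centers).
#' @param spacing Grid spacing; taken from `sim` when available.
#' @param tol_steps Tolerance in grid steps (default 2).
#' @return Fraction of planted bands hit, in `[0, 1]`.
#' @export
hit_rate <- function(selected, sim, spacing = NULL, tol_steps = 2) {
  centers <- if (inherits(sim, "nir_sim")) sim$informative$grid_wavenumber else sim
  if (is.null(spacing)) {
    spacing <- if (inherits(sim, "nir_sim")) sim$spectra$grid$spacing else
      abort("`spacing` required when `sim` is a plain vector.")
  }
  if (length(centers) == 0) return(NA_real_)
  if (length(selected) == 0) return(0)
  hits <- vapply(centers,
                 function(ctr) any(abs(selected - ctr) <= tol_steps * spacing + GRID_TOL),
                 logical(1))
  mean(hits)
}
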