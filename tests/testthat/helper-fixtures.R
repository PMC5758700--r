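# Small in-code fixtures shared across test files.

# tiny spectra set on an arbitrary uniform grid
toy_spectra <- function(n = 3, p = 5, start = 5000, spacing = 4, seed = 1,
                        classes = NULL) {
  set.seed(seed)
  grid <- wavenumber_grid(start, start - spacing * (p - 1), spacing)
  X <- matrix(rnorm(n * p, mean = 0.5, sd = 0.1), n, p)
  if (is.null(classes)) classes <- rep_len(1:2, n)
  meta <- tibble::tibble(sample_id = sprintf("S%02d", seq_len(n)),
                         tissue = "BFL", region_class = classes)
  spectra_set(X, grid, meta)
}

# a small planted-band configuration for fast selection tests:
# p variables, a few informative centers, light noise
small_band_config <- function(seed, p = 60, informative = c(15, 40),
                              contrast = c(0.08, 0.14, 0.20, 0.26, 0.32),
                              noise_sd = 0.01, n_per_class = c(8, 8, 8, 8, 8)) {
  grid <- wavenumber_grid(6000, 6000 - 4 * (p - 1), 4)
  bands <- lapply(informative, function(idx)
    band_spec(grid$points[idx], width = 6, amplitude = contrast))
  shared <- list(band_spec(grid$points[round(p / 2)], width = 40,
                           amplitude = 0.2, shared = TRUE))
  synthetic_config(n_per_class = n_per_class, tissue = "BFL", grid = grid,
                   bands = c(bands, shared), noise_sd = noise_sd, seed = seed)
}

# pretreated training matrix + metadata from the default study conditions
study_training_set <- function(seed, tissue = "BFL") {
  sim <- generate_dataset(default_study_config(tissue, seed = seed))
  pre <- pretreat(band_crop(sim$spectra, 7501.74, 4088.35))
  split <- kennard_stone_split(pre)
  list(sim = sim, train = subset_split(split, "training"),
       valid = subset_split(split, "validation"))
}

expect_no_difference <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
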