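test_that("a noiseless class-contrast band produces exactly its amplitude difference", {
  grid <- wavenumber_grid(5000, 4800, 4)
  band <- band_spec(4900, width = 10,
                    amplitude = c(0.1, 0.3, 0.1, 0.1, 0.1))
  cfg <- synthetic_config(n_per_class = c(3, 3, 1, 1, 1), tissue = "BFL",
                          grid = grid, bands = list(band),
                          baseline_jitter_sd = 0, amplitude_jitter_sd = 0,
                          noise_sd = 0, seed = 9)
  sim <- generate_dataset(cfg)
  j <- which.min(abs(grid$points - 4900))
  m1 <- mean(sim$spectra$absorbance[sim$spectra$meta$region_class == 1, j])
  m2 <- mean(sim$spectra$absorbance[sim$spectra$meta$region_class == 2, j])
  expect_equal(m2 - m1, 0.2, tolerance = 1e-12)
})

test_that("generation is bit-identical for a fixed seed", {
  a <- generate_dataset(default_study_config("BFL", seed = 42))
  b <- generate_dataset(default_study_config("BFL", seed = 42))
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$informative, b$informative)
})

test_that("the default study config matches the study sample structure", {
  cfg <- default_study_config("BFL")
  expect_equal(sum(cfg$n_per_class), 60)
  expect_equal(cfg$n_per_class, c(19L, 12L, 5L, 10L, 14L))
  bfl <- default_study_config("BFL")
  flp <- default_study_config("FLP")
  centers <- function(cfg) vapply(purrr::keep(cfg$bands, ~ !.x$shared),
                                  "[[", numeric(1), "center")
  expect_length(intersect(centers(bfl), centers(flp)), 0)
  expect_length(centers(bfl), 6)
})

test_that("a planted outlier is the unique extreme in score space", {
  cfg <- default_study_config("BFL", seed = 5)
  cfg$outlier_count <- 1L
  sim <- generate_dataset(cfg)
  expect_length(sim$outlier_ids, 1)
  pre <- pretreat(band_crop(sim$spectra, 7501.74, 4088.35))
  pc <- prcomp(pre$absorbance)
  t2 <- hotelling_t2(pc$x[, 1:5])
  expect_identical(sim$spectra$meta$sample_id[which.max(t2)], sim$outlier_ids)
  expect_gt(max(t2), t2_limit(nrow(pre$absorbance), 5, 0.99))
})

test_that("pooled tissues separate linearly in the leading PCA score plane", {
  b <- generate_dataset(default_study_config("BFL", seed = 11))$spectra
  f <- generate_dataset(default_study_config("FLP", seed = 12))$spectra
  pool <- spectra_set(rbind(b$absorbance, f$absorbance), b$grid,
                      dplyr::bind_rows(b$meta, f$meta))
  pc <- pca_kaiser(pool$absorbance)
  Z <- pc$scores[, 1:2]
  lab <- ifelse(pool$meta$tissue == "BFL", 1, -1)
  w <- c(0, 0); b0 <- 0; converged <- FALSE
  for (ep in 1:200) {
    errs <- 0
    for (i in seq_along(lab)) {
      if (lab[i] * (sum(w * Z[i, ]) + b0) <= 0) {
        w <- w + lab[i] * Z[i, ]; b0 <- b0 + lab[i]; errs <- errs + 1
      }
    }
    if (errs == 0) { converged <- TRUE; break }
  }
  expect_true(converged)
})

test_that("stronger amplitude contrast raises the MC-UVE reliability index", {
  # property over 20 seeds on a small grid: the informative variable's |RI|
  # grows with the planted between-class contrast
  ri_at <- function(seed, spread) {
    cfg <- small_band_config(seed, p = 30, informative = 12,
                             contrast = 0.2 + spread * (-2:2) / 2)
    sim <- generate_dataset(cfg)
    res <- mcuve_select(sim$spectra, A = 3, n_mc = 60, max_add = 5,
                        seed = seed)
    j <- which.min(abs(res$scores$wavenumber - sim$informative$grid_wavenumber))
    abs(res$scores$ri[j])
  }
  lo <- vapply(1:20, ri_at, numeric(1), spread = 0.05)
  hi <- vapply(1:20, ri_at, numeric(1), spread = 0.20)
  expect_gt(mean(hi), mean(lo))
})

test_that("off-grid band centers are rejected", {
  grid <- wavenumber_grid(5000, 4900, 4)
  expect_error(
    synthetic_config(n_per_class = rep(2, 5), tissue = "BFL", grid = grid,
                     bands = list(band_spec(8000, 10, amplitude = 1:5 / 10))),
    class = "nirselect_config_error")
  expect_error(band_spec(4950, width = -1, amplitude = 1:5 / 10),
               class = "nirselect_config_error")
  expect_error(band_spec(4950, width = 5, amplitude = 0.2),
               class = "nirselect_config_error")
})
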