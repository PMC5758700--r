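fake_result <- function(selected) {
  nirselect:::new_selection_result("X", selected, tibble::tibble(),
                                   NA_real_, NA_real_, 1L)
}

test_that("the CARS retention schedule spans all-variables down to two", {
  p <- 50; n_iter <- 50
  k_const <- log(p / 2) / (n_iter - 1)
  ratios <- exp(-k_const * (seq_len(n_iter) - 1))
  expect_equal(round(ratios[1] * p), p)
  expect_equal(round(ratios[n_iter] * p), 2)
})

test_that("CARS recovers planted variables with high selection frequency", {
  # 2 informative bands among ~48 noise variables, averaged over seeds
  stats <- sapply(1:8, function(sd) {
    cfg <- small_band_config(sd)
    sim <- generate_dataset(cfg)
    res <- cars_select(sim$spectra, A = 3, n_runs = 40, n_iter = 30, seed = sd)
    sp <- sim$spectra$grid$spacing
    freqs <- vapply(sim$informative$grid_wavenumber, function(cc)
      max(res$scores$frequency[abs(res$scores$wavenumber - cc) <= 2 * sp]),
      numeric(1))
    c(hit = hit_rate(res$selected, sim), freq = mean(freqs))
  })
  expect_gte(mean(stats["hit", ]), 0.9)
  expect_gte(mean(stats["freq", ]), 0.9)
})

test_that("the CARS answer improves on the full-variable model on its own folds", {
  cfg <- small_band_config(21)
  sim <- generate_dataset(cfg)
  y <- sim$spectra$meta$region_class
  res <- cars_select(sim$spectra, A = 3, n_runs = 40, n_iter = 30, seed = 21)
  fold <- nirselect:::make_folds(y, 10, 21 + 7L)
  full <- cross_validate(sim$spectra$absorbance, y, A = 3, fold_id = fold)
  expect_lte(min(res$rmsecv_path, na.rm = TRUE), full$rmsecv)
})

test_that("MC-UVE ranks planted variables above the noise median", {
  over <- sapply(1:8, function(sd) {
    cfg <- small_band_config(sd)
    sim <- generate_dataset(cfg)
    res <- mcuve_select(sim$spectra, A = 3, n_mc = 150, max_add = 20, seed = sd)
    sp <- sim$spectra$grid$spacing
    is_inform <- vapply(res$scores$wavenumber, function(w)
      any(abs(sim$informative$grid_wavenumber - w) <= 2 * sp), logical(1))
    inform_ri <- vapply(sim$informative$grid_wavenumber, function(cc)
      max(abs(res$scores$ri)[abs(res$scores$wavenumber - cc) <= 2 * sp]),
      numeric(1))
    c(above = all(inform_ri > median(abs(res$scores$ri[!is_inform]))),
      hit = hit_rate(res$selected, sim))
  })
  expect_gte(mean(over["above", ]), 0.9)
  expect_gte(mean(over["hit", ]), 0.9)
})

test_that("under permuted labels the RI calibrates against a permutation null", {
  # with labels independent of X, the observed |RI| must be exchangeable
  # with |RI| recomputed under fresh label permutations, so about 5% of
  # variables exceed the null's 95th percentile
  set.seed(77)
  X <- matrix(rnorm(40 * 100), 40, 100)
  y0 <- rep(1:5, 8)
  ri_of <- function(y, seed) {
    abs(mcuve_select(X, y, A = 3, n_mc = 80, max_add = 2,
                     seed = seed)$scores$ri)
  }
  fracs <- vapply(1:6, function(rep_i) {
    set.seed(1000 + rep_i)
    obs <- ri_of(sample(y0), 100 + rep_i)
    null <- unlist(lapply(1:15, function(k)
      ri_of(sample(y0), 300 + 20 * rep_i + k)))
    mean(obs > quantile(null, 0.95))
  }, numeric(1))
  expect_gt(mean(fracs), 0.03)
  expect_lt(mean(fracs), 0.07)
})

test_that("duplicated informative columns receive equal reliability", {
  set.seed(3)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- rep(1:5, 8)
  X[, 5] <- y + rnorm(40, 0, 0.3)
  X[, 12] <- X[, 5]
  res <- mcuve_select(X, y, A = 3, n_mc = 300, max_add = 5, seed = 4)
  expect_equal(res$scores$ri[5], res$scores$ri[12], tolerance = 0.15)
})

test_that("SPA scores strong variables above COSS 2 and noise below 1", {
  res <- sapply(1:10, function(sd) {
    cfg <- small_band_config(sd, noise_sd = 0.005)
    sim <- generate_dataset(cfg)
    sel <- spa_select(sim$spectra, A = 3, N = 400, Q = 8, seed = sd)
    sp <- sim$spectra$grid$spacing
    is_inform <- vapply(sel$scores$wavenumber, function(w)
      any(abs(sim$informative$grid_wavenumber - w) <= 2 * sp), logical(1))
    inform_coss <- vapply(sim$informative$grid_wavenumber, function(cc)
      max(sel$scores$coss[abs(sel$scores$wavenumber - cc) <= 2 * sp]),
      numeric(1))
    c(found = all(inform_coss > 2),
      noise_median = median(sel$scores$coss[!is_inform]))
  })
  expect_gte(mean(res["found", ]), 0.9)
  expect_lt(median(res["noise_median", ]), 1)
})

test_that("LPG geometry: collinear middles are dropped, hulls kept", {
  # engineer the loading plane: X = scores %*% t(L) so that the PCA loading
  # coordinates are an invertible linear image of L (collinearity and hull
  # membership are affine-invariant)
  set.seed(4)
  L <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 3), c(3, 0))
  Tm <- scale(matrix(rnorm(40), 20, 2), scale = FALSE)
  X <- Tm %*% t(L)
  colnames(X) <- sprintf("%.2f", 5000 - 4 * (1:5))
  res <- lpg_select(X, angle_min = 15)
  expect_false((5000 - 4 * 2) %in% res$selected)        # middle of the line
  expect_true(all(c(5000 - 4, 5000 - 16, 5000 - 20) %in% res$selected))

  L3 <- rbind(c(0, 0), c(2, 0), c(1, 2))                # triangle: all hull
  X3 <- Tm %*% t(L3)
  colnames(X3) <- sprintf("%.2f", 5000 - 4 * (1:3))
  expect_length(lpg_select(X3)$selected, 3)

  X0 <- matrix(0.7, 10, 5)
  colnames(X0) <- sprintf("%.2f", 5000 - 4 * (1:5))
  expect_warning(r0 <- lpg_select(X0), "Degenerate")
  expect_length(r0$selected, 0)
})

test_that("consensus voting counts memberships", {
  rs <- list(fake_result(c(1, 2)), fake_result(c(2, 3)),
             fake_result(3), fake_result(4))
  expect_equal(consensus_vote(rs, min_votes = 2), c(3, 2))
  expect_equal(sort(consensus_vote(rs, min_votes = 1)), 1:4)
  same <- replicate(4, fake_result(c(7, 9)), simplify = FALSE)
  for (mv in 1:4) expect_equal(consensus_vote(same, min_votes = mv), c(9, 7))
  expect_error(consensus_vote(rs[1]), class = "nirselect_parameter_error")
})

test_that("every selector is reproducible bit-for-bit from its seed", {
  cfg <- small_band_config(13)
  sim <- generate_dataset(cfg)
  s <- sim$spectra
  expect_identical(cars_select(s, A = 3, n_runs = 10, n_iter = 20, seed = 5)$selected,
                   cars_select(s, A = 3, n_runs = 10, n_iter = 20, seed = 5)$selected)
  expect_identical(mcuve_select(s, A = 3, n_mc = 50, max_add = 10, seed = 5)$selected,
                   mcuve_select(s, A = 3, n_mc = 50, max_add = 10, seed = 5)$selected)
  expect_identical(spa_select(s, A = 3, N = 150, Q = 6, seed = 5)$selected,
                   spa_select(s, A = 3, N = 150, Q = 6, seed = 5)$selected)
  expect_identical(lpg_select(s)$selected, lpg_select(s)$selected)
})
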