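test_that("Norris smoothing preserves constants and lines", {
  s <- toy_spectra(n = 2, p = 7)
  s$absorbance[1, ] <- 0.7                  # constant
  s$absorbance[2, ] <- 0.1 * (1:7) + 0.2    # linear ramp
  sm <- norris_filter(s, segment = 3, gap = 1)
  expect_no_difference(sm$absorbance[1, ], rep(0.7, 7))
  # interior of a line is invariant under a centered boxcar mean
  expect_no_difference(sm$absorbance[2, 2:6], s$absorbance[2, 2:6])

  expect_no_difference(norris_filter(s, segment = 1, gap = 1)$absorbance,
                       s$absorbance)
  expect_error(norris_filter(s, segment = 4), class = "nirselect_parameter_error")
  expect_error(norris_filter(s, segment = 7, gap = 3),
               class = "nirselect_parameter_error")
})

test_that("the Savitzky-Golay second derivative is exact on polynomials", {
  s <- toy_spectra(n = 3, p = 31)
  i <- seq_len(31)
  a <- 0.03
  s$absorbance[1, ] <- a * i^2
  s$absorbance[2, ] <- 0.5 * i + 1
  s$absorbance[3, ] <- exp(-(i - 16)^2 / (2 * 4^2))
  d2 <- second_derivative(s, window = 11, polyorder = 2)
  expect_no_difference(d2$absorbance[1, ], rep(2 * a, 31), tol = 1e-9)
  expect_no_difference(d2$absorbance[2, ], rep(0, 31), tol = 1e-9)
  # Gaussian band: negative extremum at the band center
  expect_equal(unname(which.min(d2$absorbance[3, ])), 16L)
  expect_lt(d2$absorbance[3, 16], 0)

  expect_error(second_derivative(s, window = 10),
               class = "nirselect_parameter_error")
  expect_error(second_derivative(s, window = 11, polyorder = 1),
               class = "nirselect_parameter_error")
})

test_that("the second derivative is linear", {
  sa <- toy_spectra(n = 2, p = 25, seed = 3)
  sb <- toy_spectra(n = 2, p = 25, seed = 4)
  lhs <- second_derivative(
    spectra_set(2 * sa$absorbance - 3 * sb$absorbance, sa$grid, sa$meta))
  rhs <- 2 * second_derivative(sa)$absorbance -
    3 * second_derivative(sb)$absorbance
  expect_no_difference(lhs$absorbance, rhs, tol = 1e-10)
})

test_that("centering and autoscaling hit their moments exactly", {
  s <- toy_spectra(n = 6, p = 4, classes = rep(1:2, 3))
  expect_lt(max(abs(colMeans(mean_center(s)$absorbance))), 1e-12)
  st <- standardize(s)
  expect_lt(max(abs(colMeans(st$absorbance))), 1e-12)
  expect_lt(max(abs(apply(st$absorbance, 2, sd) - 1)), 1e-12)

  s2 <- spectra_set(matrix(c(0, 2, 1, 3), 2, 2), wavenumber_grid(5000, 4996, 4),
                    tibble::tibble(sample_id = c("a", "b"), tissue = "BFL",
                                   region_class = c(1, 2)))
  expect_no_difference(mean_center(s2)$absorbance,
                       matrix(c(-1, 1, -1, 1), 2, 2))

  s$absorbance[, 2] <- 0.4  # zero variance
  expect_warning(st0 <- standardize(s), "zero-variance")
  expect_lt(max(abs(st0$absorbance[, 2])), 1e-12)
})

test_that("the pretreatment chain is deterministic and order-sensitive", {
  s <- toy_spectra(n = 8, p = 40, classes = rep(1:4, 2))
  a <- pretreat(s)
  b <- pretreat(s)
  expect_identical(a$absorbance, b$absorbance)
  swapped <- pretreat(s, steps = c("second_derivative", "norris",
                                   "mean_center", "standardize"))
  expect_gt(max(abs(a$absorbance - swapped$absorbance)), 1e-6)
})

test_that("SDD band selection finds the variable-rich window", {
  grid <- wavenumber_grid(9000, 4000, 10)
  p <- length(grid$points)
  set.seed(42)
  X <- matrix(rnorm(30 * p, 0.5, 0.002), 30, p)
  # planted high-variability band region inside [4100, 7500]; supports
  # overlap so the high-SD region is one contiguous run
  centers <- c(4900, 5600, 6300)
  for (ctr in centers) {
    shape <- exp(-(grid$points - ctr)^2 / (2 * 250^2))
    X <- X + outer(rnorm(30, 0, 0.1), shape)
  }
  meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:30), tissue = "BFL",
                         region_class = rep(1:5, 6))
  s <- spectra_set(X, grid, meta)
  w <- sdd_band_select(s, quantile = 0.3, min_run = 20)
  expect_lte(w$high, 7550)
  expect_gte(w$low, 4050)
  expect_true(all(centers <= w$high & centers >= w$low))

  # single high-variance variable, min_run = 1
  X0 <- matrix(rnorm(200, 0.5, 0.001), 10, 20)
  X0[, 7] <- rnorm(10, 0.5, 0.2)
  s0 <- spectra_set(X0, wavenumber_grid(5000, 5000 - 19 * 4, 4),
                    tibble::tibble(sample_id = sprintf("t%02d", 1:10),
                                   tissue = "BFL", region_class = rep(1:5, 2)))
  w0 <- sdd_band_select(s0, quantile = 0.95, min_run = 1)
  expect_equal(w0$n_points, 1)
  expect_equal(w0$high, s0$grid$points[7])

  # quantile 0 keeps the whole grid
  wq <- sdd_band_select(s, quantile = 0, min_run = 1)
  expect_equal(wq$n_points, p)

  expect_error(sdd_band_select(s, quantile = 0.99, min_run = 500),
               class = "nirselect_selection_error")
})
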