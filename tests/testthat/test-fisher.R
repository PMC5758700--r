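named_matrix <- function(X) {
  colnames(X) <- sprintf("%.2f", 5000 - 4 * seq_len(ncol(X)))
  X
}

test_that("stepwise screening enters a perfect separator first", {
  set.seed(1)
  n <- 50
  labels <- rep(1:5, each = 10)
  X <- named_matrix(cbind(labels + rnorm(n, 0, 0.05),
                          matrix(rnorm(n * 6), n, 6)))
  res <- stepwise_select(X, labels)
  expect_equal(res$retained[1], as.numeric(colnames(X)[1]))
  expect_equal(res$trace$action[1], "enter")
  # Wilks lambda never increases along entry steps
  ent <- res$trace[res$trace$action == "enter", ]
  expect_true(all(diff(ent$wilks) <= 1e-12))

  expect_warning(empty <- stepwise_select(X, labels, f_enter = Inf),
                 "empty retention")
  expect_length(empty$retained, 0)
})

test_that("two symmetric 1-D classes split at zero", {
  set.seed(2)
  X <- named_matrix(matrix(c(rnorm(30, -1, 1), rnorm(30, 1, 1)), ncol = 1))
  labels <- rep(1:2, each = 30)
  m <- fisher_fit(X, labels)
  # scores are equal at the midpoint of the centroids
  mid <- mean(m$centroids)
  sc <- drop(mid * m$coefficients + m$constants)
  expect_equal(sc[1], sc[2], tolerance = 1e-10)
})

test_that("the score argmax equals the Mahalanobis nearest centroid", {
  set.seed(3)
  X <- named_matrix(matrix(rnorm(120), 30, 4))
  labels <- rep(1:3, each = 10)
  X[labels == 2, 1] <- X[labels == 2, 1] + 2
  X[labels == 3, 3] <- X[labels == 3, 3] - 2
  m <- fisher_fit(X, labels)
  newx <- named_matrix(matrix(rnorm(200 * 4), 200, 4))
  pred <- fisher_classify(m, newx)
  Winv <- solve(m$pooled_cov)
  oracle <- apply(newx, 1, function(x) {
    d2 <- apply(m$centroids, 1, function(mu)
      drop(t(x - mu) %*% Winv %*% (x - mu)))
    m$classes[which.min(d2)]
  })
  expect_identical(pred, oracle)
})

test_that("classification agrees with the reference LDA implementation", {
  set.seed(9)
  X <- named_matrix(matrix(rnorm(250), 50, 5))
  labels <- rep(1:5, each = 10)
  for (k in 1:5) X[labels == k, k] <- X[labels == k, k] + 2.5
  m <- fisher_fit(X, labels)
  lda <- MASS::lda(X, grouping = labels, prior = rep(0.2, 5))
  newx <- named_matrix(matrix(rnorm(100 * 5), 100, 5))
  expect_identical(fisher_classify(m, newx),
                   as.integer(as.character(predict(lda, newx)$class)))
})

test_that("shifting every feature moves constants but not assignments", {
  set.seed(4)
  X <- named_matrix(matrix(rnorm(90), 30, 3))
  labels <- rep(1:3, each = 10)
  X[labels == 1, 1] <- X[labels == 1, 1] + 2
  m1 <- fisher_fit(X, labels)
  m2 <- fisher_fit(X + 5, labels)
  expect_gt(max(abs(m1$constants - m2$constants)), 1e-8)
  newx <- named_matrix(matrix(rnorm(60), 20, 3))
  expect_identical(fisher_classify(m1, newx), fisher_classify(m2, newx + 5))
})

test_that("centroids classify to their own class and ties break low", {
  set.seed(5)
  X <- named_matrix(matrix(rnorm(80), 20, 4))
  labels <- rep(1:4, each = 5)
  for (k in 1:4) X[labels == k, k] <- X[labels == k, k] + 3
  m <- fisher_fit(X, labels)
  expect_identical(fisher_classify(m, m$centroids), m$classes)

  # exact two-class symmetric tie
  Xs <- named_matrix(matrix(c(-1, -1, 1, 1), ncol = 1))
  ms <- fisher_fit(Xs, c(1, 1, 2, 2))
  expect_identical(fisher_classify(ms, matrix(0)), 1L)

  expect_error(fisher_classify(m, matrix(0, 1, 2)),
               class = "nirselect_input_error")
  expect_error(fisher_fit(X[c(1, 6, 11, 16), ], labels[c(1, 6, 11, 16)]),
               class = "nirselect_fit_error")
})

test_that("leave-one-out validation conserves counts and detects separation", {
  set.seed(6)
  labels <- rep(1:5, each = 6)
  X <- named_matrix(matrix(rnorm(30 * 3, sd = 0.05), 30, 3))
  for (k in 1:5) X[labels == k, ] <- X[labels == k, ] + 3 * k
  res <- loo_cross_validate(X, labels)
  expect_equal(res$accuracy, 100)
  expect_equal(as.integer(rowSums(res$confusion)),
               as.integer(table(labels)))

  # permuted labels: chance level for 5 balanced classes
  acc <- vapply(1:10, function(sd) {
    set.seed(sd)
    loo_cross_validate(named_matrix(matrix(rnorm(40 * 3), 40, 3)),
                       sample(rep(1:5, 8)))$accuracy
  }, numeric(1))
  expect_gt(mean(acc), 10)
  expect_lt(mean(acc), 30)
})

test_that("resubstitution is at least as optimistic as leave-one-out", {
  comp <- sapply(1:20, function(sd) {
    sim <- generate_dataset(default_study_config("BFL", seed = sd))
    pre <- pretreat(band_crop(sim$spectra, 7501.74, 4088.35))
    wn <- pre$grid$points
    sel <- unique(unlist(lapply(sim$informative$grid_wavenumber, function(cc)
      wn[abs(wn - cc) <= pre$grid$spacing + 1e-6])))
    cols <- match(sprintf("%.2f", sel), colnames(pre$absorbance))
    X <- pre$absorbance[, cols]
    y <- pre$meta$region_class
    m <- fisher_fit(X, y)
    resub <- round(100 * mean(fisher_classify(m, X) == y), 2)
    c(resub = resub, loo = suppressWarnings(loo_cross_validate(X, y)$accuracy))
  })
  expect_gte(mean(comp["resub", ] >= comp["loo", ]), 0.95)
})

test_that("model serialization round-trips classifications", {
  set.seed(7)
  X <- named_matrix(matrix(rnorm(120), 30, 4))
  labels <- rep(1:3, each = 10)
  X[labels == 2, 2] <- X[labels == 2, 2] + 2
  m <- fisher_fit(X, labels)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fisher_json(m, tmp)
  m2 <- read_fisher_json(tmp)
  newx <- named_matrix(matrix(rnorm(80), 20, 4))
  expect_identical(fisher_classify(m, newx), fisher_classify(m2, newx))
})

test_that("tidy lays the coefficient table out per class and wavenumber", {
  set.seed(8)
  X <- named_matrix(matrix(rnorm(60), 20, 3))
  labels <- rep(1:2, each = 10)
  X[labels == 2, ] <- X[labels == 2, ] + 1
  td <- tidy(fisher_fit(X, labels))
  expect_named(td, c("class", "constant", "wavenumber", "coefficient"))
  expect_equal(nrow(td), 2 * 3)
})
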